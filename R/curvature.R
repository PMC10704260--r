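# Radius-of-curvature estimation from 2-D cross-section points via Taubin's
# algebraic circle fit, solved through a singular value decomposition of the
# centered design matrix.  Taubin's estimator minimizes an algebraic distance
# normalized by the gradient and has substantially lower bias than the
# plain Kasa fit on short arcs.

#' Taubin circle fit (SVD form)
#'
#' Fits a circle `(x - cx)^2 + (y - cy)^2 = r^2` to 2-D points.  The points
#' are centroid-centered, the design matrix `[z - mean(z), x, y]` with
#' `z = x^2 + y^2` is scaled and decomposed by SVD, and the singular vector
#' of the smallest singular value gives the circle parameters.
#'
#' @param points Numeric matrix (or data.frame) with two columns (x, y), in
#'   consistent length units (e.g. mm); at least 3 non-collinear points.
#' @return A list with `center` (length-2), `radius` (> 0) and `rms_residual`
#'   (root-mean-square radial misfit), all in the input units.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 25)[-25]
#' taubin_circle_fit(cbind(3 + 5 * cos(th), -1 + 5 * sin(th)))
taubin_circle_fit <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 3 || !all(is.finite(pts))) {
    stop_invalid("`points` must be a finite n x 2 matrix with n >= 3")
  }
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]
  y <- pts[, 2] - ctr[2]
  z <- x^2 + y^2
  zbar <- mean(z)
  if (zbar < .Machine$double.eps) {
    stop(degenerate_geometry("all points coincide"))
  }
  Z <- cbind((z - zbar) / (2 * sqrt(zbar)), x, y)
  sv <- svd(Z)
  v <- sv$v[, 3]
  A <- v[1] / (2 * sqrt(zbar))
  B <- v[2]
  C <- v[3]
  Dd <- -zbar * A
  if (abs(A) < 1e-12 * max(abs(c(B, C)), 1)) {
    stop(degenerate_geometry("points are collinear; no finite circle"))
  }
  cx <- -B / (2 * A)
  cy <- -C / (2 * A)
  r2 <- cx^2 + cy^2 - Dd / A
  if (!is.finite(r2) || r2 <= 0) {
    stop(degenerate_geometry("degenerate circle geometry"))
  }
  center <- c(cx + ctr[1], cy + ctr[2])
  radius <- sqrt(r2)
  d <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) - radius
  list(center = center, radius = radius, rms_residual = sqrt(mean(d^2)))
}

degenerate_geometry <- function(msg) {
  structure(class = c("muellerpli_degenerate_geometry", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read a planar point set from delimited text
#'
#' Expects two numeric columns (x, y) per line; lines starting with `#` are
#' treated as header/comment (units declaration).
#'
#' @param file Path to the text file.
#' @param sep Field separator (default: any whitespace).
#' @return Numeric matrix with columns `x`, `y`.
#' @export
read_point_set <- function(file, sep = "") {
  tab <- utils::read.table(file, sep = sep, comment.char = "#",
                           col.names = c("x", "y"))
  as.matrix(tab)
}
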