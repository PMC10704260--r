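# Container I/O and the pipeline orchestrator.
#
# A Mueller stack is stored as a multi-page 32-bit float TIFF (per
# wavelength, 16 planes ordered m00, m01, ..., m33) plus a JSON metadata
# sidecar (<file>.json) and a companion validity TIFF (one 0/1 page per
# wavelength).  The TIFF writer's float domain is [0, 1], so planes are
# stored through a recorded affine map value = offset + scale * stored,
# written to the sidecar; the round trip is exact to 32-bit float
# precision.  Undefined (NA) entries are stored as a recorded sentinel.

config_error <- function(field, msg = "missing or invalid") {
  structure(class = c("muellerpli_config_error", "error", "condition"),
            list(message = paste0("config field `", field, "`: ", msg),
                 call = NULL))
}

malformed_container <- function(msg) {
  structure(class = c("muellerpli_malformed_container", "error", "condition"),
            list(message = msg, call = NULL))
}

NA_SENTINEL_FRACTION <- -0.05  # stored-domain sentinel for NA entries

write_float_planes <- function(planes_list, file) {
  finite_vals <- unlist(lapply(planes_list, function(p) p[is.finite(p)]))
  lo <- if (length(finite_vals)) min(finite_vals) else 0
  hi <- if (length(finite_vals)) max(finite_vals) else 1
  if (hi <= lo) hi <- lo + 1
  scale <- (hi - lo) / 0.9  # keep stored data in [0.05, 0.95], sentinel below
  stored <- lapply(planes_list, function(p) {
    s <- (p - lo) / scale + 0.05
    s[!is.finite(p)] <- 0.05 + NA_SENTINEL_FRACTION
    s
  })
  suppressWarnings(tiff::writeTIFF(stored, file, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  list(offset = lo, scale = scale)
}

read_float_planes <- function(file, offset, scale) {
  pages <- tiff::readTIFF(file, all = TRUE)
  lapply(pages, function(s) {
    v <- offset + (s - 0.05) * scale
    v[s < 0.05 + NA_SENTINEL_FRACTION / 2] <- NA_real_
    v
  })
}

#' Write a Mueller stack container
#'
#' @param stack A `mueller_stack`.
#' @param file Destination path (`.tif`); a JSON sidecar `<file>.json` and a
#'   validity image `<file>.validity.tif` are written alongside.
#' @return Invisibly, the main file path.
#' @export
write_stack <- function(stack, file) {
  stopifnot(inherits(stack, "mueller_stack"))
  d <- stack_dim(stack)
  planes_list <- list()
  for (k in seq_len(d[3])) {
    for (e in 1:16) {
      planes_list[[length(planes_list) + 1]] <- stack$planes[, , e, k]
    }
  }
  affine <- write_float_planes(planes_list, file)
  vfile <- paste0(file, ".validity.tif")
  suppressWarnings(tiff::writeTIFF(
    lapply(seq_len(d[3]), function(k) stack$validity[, , k] * 1),
    vfile, bits.per.sample = 32L, compression = "none", reduce = FALSE))
  meta <- list(
    format = "muellerpli-stack-v1",
    wavelengths_nm = stack$wavelengths,
    pixel_pitch_um = stack$pixel_pitch,
    plane_order = "per wavelength: m00 m01 m02 m03 m10 ... m33",
    angle_convention = mueller_convention(),
    corrected = isTRUE(stack$metadata$corrected),
    seed = stack$metadata$seed,
    creation_log = stack$metadata$creation_log %||%
      paste0("muellerpli ", as.character(utils::packageVersion("muellerpli"))),
    affine = affine,
    na_sentinel_stored = 0.05 + NA_SENTINEL_FRACTION,
    validity_file = basename(vfile))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a Mueller stack container
#'
#' @param file Path written by [write_stack()].
#' @return A `mueller_stack`.
#' @export
read_stack <- function(file) {
  sidecar <- paste0(file, ".json")
  if (!file.exists(sidecar)) {
    stop(structure(class = c("muellerpli_metadata_error", "error", "condition"),
                   list(message = "metadata sidecar missing", call = NULL)))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (fld in c("wavelengths_nm", "pixel_pitch_um", "affine")) {
    if (is.null(meta[[fld]])) {
      stop(structure(class = c("muellerpli_metadata_error", "error",
                               "condition"),
                     list(message = paste0("metadata field `", fld,
                                           "` missing"), call = NULL)))
    }
  }
  pages <- read_float_planes(file, meta$affine$offset, meta$affine$scale)
  nw <- length(meta$wavelengths_nm)
  if (length(pages) != 16 * nw) {
    stop(malformed_container(sprintf(
      "expected %d planes (16 per wavelength), found %d", 16 * nw,
      length(pages))))
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  planes <- array(NA_real_, c(h, w, 16, nw))
  for (k in seq_len(nw)) {
    for (e in 1:16) planes[, , e, k] <- pages[[(k - 1) * 16 + e]]
  }
  vfile <- file.path(dirname(file), meta$validity_file)
  validity <- if (file.exists(vfile)) {
    vp <- tiff::readTIFF(vfile, all = TRUE)
    array(unlist(vp) > 0.5, c(h, w, nw))
  } else {
    NULL
  }
  mueller_stack(planes, meta$wavelengths_nm, meta$pixel_pitch_um,
                validity = validity,
                metadata = list(seed = meta$seed,
                                corrected = isTRUE(meta$corrected),
                                creation_log = meta$creation_log))
}

#' Export polarization maps to per-quantity float TIFFs
#'
#' Writes one 32-bit float TIFF per quantity (retardance, retardance angle,
#' diattenuation, diattenuation angle, depolarization) per wavelength, plus
#' a metadata sidecar naming units, the angle convention and the NA
#' (undefined / invalid) sentinel handling.
#'
#' @param maps A `polarization_maps` or a list of them (one per wavelength).
#' @param dir Output directory (created if needed).
#' @param basename File-name stem (default `"maps"`).
#' @return Invisibly, a character vector of written files.
#' @export
export_maps <- function(maps, dir, basename = "maps") {
  if (inherits(maps, "polarization_maps")) maps <- list(maps)
  if (!length(maps)) stop_invalid("`maps` is empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  quantities <- c(retardance = "radians", retardance_angle = "degrees",
                  diattenuation = "dimensionless",
                  diattenuation_angle = "degrees",
                  depolarization = "dimensionless")
  files <- character(0)
  affines <- list()
  for (m in maps) {
    stopifnot(inherits(m, "polarization_maps"))
    for (q in names(quantities)) {
      pl <- m[[q]]
      pl[!m$validity] <- NA_real_
      f <- file.path(dir, sprintf("%s_%s_%gnm.tif", basename, q, m$wavelength))
      affines[[basename(f)]] <- write_float_planes(list(pl), f)
      files <- c(files, f)
    }
  }
  meta <- list(format = "muellerpli-maps-v1",
               units = as.list(quantities),
               angle_convention = mueller_convention(),
               corrected = isTRUE(maps[[1]]$corrected),
               na_handling = paste("invalid pixels and undefined angles are",
                                   "NA in memory, stored as the sentinel",
                                   "value recorded per file"),
               na_sentinel_stored = 0.05 + NA_SENTINEL_FRACTION,
               affine = affines)
  mf <- file.path(dir, paste0(basename, "_metadata.json"))
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, mf))
}

#' Re-import one exported map plane
#'
#' @param file A TIFF written by [export_maps()].
#' @param metadata_file The accompanying `*_metadata.json`.
#' @return A numeric matrix with `NA` restored.
#' @export
import_map_plane <- function(file, metadata_file) {
  meta <- jsonlite::read_json(metadata_file, simplifyVector = TRUE)
  af <- meta$affine[[basename(file)]]
  if (is.null(af)) stop(malformed_container("no affine recorded for plane"))
  read_float_planes(file, af$offset, af$scale)[[1]]
}

#' Write / read a single-channel mask image
#'
#' Masks (ROI or wrap masks) are stored as single-page TIFFs of 0/1 values
#' aligned to the map geometry.
#'
#' @param flags Logical matrix.
#' @param file Path.
#' @return `write_mask`: invisibly the path; `read_mask`: a logical matrix.
#' @export
write_mask <- function(flags, file) {
  suppressWarnings(tiff::writeTIFF(flags * 1, file, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  invisible(file)
}

#' @rdname write_mask
#' @export
read_mask <- function(file) {
  tiff::readTIFF(file) > 0.5
}

# ---- pipeline orchestrator ----------------------------------------------

#' Run the full analysis pipeline from a structured-text config
#'
#' Orchestrates simulate/ingest -> decompose -> smooth -> unwrap -> analyze
#' -> export.  The config (YAML file or named list) must provide either
#' `preset` (+ optional `preset_params`) or `input` (a stack container
#' path), plus `wavelengths`, `seed` and `output_dir`.  Optional fields:
#' `smoothing_sigma` (pixels, default 0), `unwrap` (`"none"` or `"auto"`,
#' default `"none"`), `rois` (`"from_truth"`, the default for simulated
#' scenes, or a list of `[row_min, row_max, col_min, col_max]` rectangles).
#'
#' Outputs under `output_dir`: exported map TIFFs, `summary.tsv` (per
#' wavelength x ROI: pixel count, mean retardance, circular-mean retardance
#' angle, dominant histogram angle, mean diattenuation, mean
#' depolarization) and `pipeline_log.json` (parameters, failure counts,
#' seed).  Runs are deterministic under a fixed seed.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Invisibly, a list with `summary` (data.frame), `maps`, `files`
#'   and `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop(config_error("(root)", "config must be a mapping"))
  if (is.null(cfg$preset) && is.null(cfg$input)) {
    stop(config_error("preset/input", "one of the two is required"))
  }
  if (is.null(cfg$wavelengths)) stop(config_error("wavelengths"))
  if (is.null(cfg$seed)) stop(config_error("seed"))
  if (is.null(cfg$output_dir)) stop(config_error("output_dir"))
  sigma <- cfg$smoothing_sigma %||% 0
  unwrap <- cfg$unwrap %||% "none"
  if (!unwrap %in% c("none", "auto")) stop(config_error("unwrap"))

  log <- list(seed = cfg$seed, smoothing_sigma = sigma, unwrap = unwrap,
              angle_convention = mueller_convention())
  truth <- NULL
  if (!is.null(cfg$preset)) {
    pp <- cfg$preset_params %||% list()
    pp$wavelengths <- as.numeric(cfg$wavelengths)
    pp$seed <- cfg$seed
    scene <- preset_phantom(cfg$preset, pp)
    if (!inherits(scene, "phantom_scene")) {
      stop(config_error("preset", "series presets are not runnable directly"))
    }
    rendered <- scene_to_mueller(scene)
    stack <- rendered$stack
    truth <- rendered$truth
    log$stage_simulate <- list(preset = cfg$preset,
                               size = scene$size, noise = scene$noise)
  } else {
    stack <- read_stack(cfg$input)
    log$stage_ingest <- list(input = cfg$input)
  }

  maps <- decompose_stack(stack)
  log$stage_decompose <- list(n_failed = as.integer(attr(maps, "n_failed")))

  if (sigma > 0) maps <- lapply(maps, smooth_maps, sigma = sigma)

  if (unwrap == "auto") {
    masks <- lapply(maps, function(m) {
      tryCatch(detect_wrapped_regions(m$retardance_angle),
               error = function(e) NULL)
    })
    n_flagged <- vapply(masks, function(mk) {
      if (is.null(mk)) 0L else sum(mk$flags)
    }, integer(1))
    if (any(n_flagged > 0)) {
      # a 1-D scan cannot tell which side of a discontinuity is the wrapped
      # one, so the detected mask and its complement (over rows that contain
      # a jump) are both candidates, under either mirroring branch; the
      # wavelength-monotonicity convention picks among the four.
      complement_mask <- function(k) {
        mk <- masks[[k]]
        if (is.null(mk) || !any(mk$flags)) return(mk)
        f <- mk$flags
        defined <- !is.na(maps[[k]]$retardance_angle)
        if (is.matrix(f)) {
          jump_rows <- rowSums(f) > 0
          f[jump_rows, ] <- !f[jump_rows, ] & defined[jump_rows, ]
          f[!jump_rows, ] <- FALSE
        } else {
          f <- !f & defined
        }
        wrap_mask(f, provenance = "auto")
      }
      mask_sets <- list(detected = masks,
                        complement = lapply(seq_along(maps), complement_mask))
      wls <- vapply(maps, `[[`, numeric(1), "wavelength")
      mean_for <- function(msk, branch) {
        vapply(seq_along(maps), function(k) {
          if (is.null(msk[[k]])) return(NA_real_)
          u <- apply_unwrap(maps[[k]]$retardance, maps[[k]]$retardance_angle,
                            msk[[k]], branch = branch)
          mean(u$retardance[maps[[k]]$validity] *
                 u$sign[maps[[k]]$validity], na.rm = TRUE)
        }, numeric(1))
      }
      cand <- expand.grid(side = c("detected", "complement"),
                          branch = c("around_pi", "around_zero"),
                          stringsAsFactors = FALSE)
      cand$violations <- vapply(seq_len(nrow(cand)), function(i) {
        m <- mean_for(mask_sets[[cand$side[i]]], cand$branch[i])
        ok <- !is.na(m)
        if (sum(ok) < 2) return(NA_integer_)
        sum(diff(m[ok][order(wls[ok])]) >= 0)
      }, integer(1))
      monotone <- which(!is.na(cand$violations) & cand$violations == 0)
      sel <- list(branch = NA_character_, side = NA_character_,
                  ambiguous = TRUE)
      if (length(monotone) >= 1) {
        pick <- monotone[1]  # priority: detected/around_pi first
        sel <- list(branch = cand$branch[pick], side = cand$side[pick],
                    ambiguous = length(monotone) > 1)
      }
      log$stage_unwrap <- list(branch = sel$branch, mask_side = sel$side,
                               ambiguous = sel$ambiguous,
                               n_flagged = as.integer(n_flagged))
      if (!is.na(sel$branch)) {
        chosen <- mask_sets[[sel$side]]
        maps <- lapply(seq_along(maps), function(k) {
          if (is.null(chosen[[k]]) || !any(chosen[[k]]$flags)) return(maps[[k]])
          unwrap_polarization_maps(maps[[k]], chosen[[k]], sel$branch)
        })
      }
    } else {
      log$stage_unwrap <- list(branch = NA, ambiguous = FALSE, n_flagged = 0L)
    }
  }

  rois <- list()
  if (identical(cfg$rois %||% "from_truth", "from_truth") && !is.null(truth)) {
    for (fid in sort(unique(truth$fiber_id[truth$fiber_id > 0]))) {
      rois[[paste0("fiber", fid)]] <- truth$fiber_id == fid
    }
    if (any(truth$overlap)) rois[["overlap"]] <- truth$overlap
  } else if (is.list(cfg$rois)) {
    for (i in seq_along(cfg$rois)) {
      rc <- as.integer(cfg$rois[[i]])
      if (length(rc) != 4) stop(config_error(paste0("rois[", i, "]")))
      f <- matrix(FALSE, nrow(maps[[1]]$retardance), ncol(maps[[1]]$retardance))
      f[rc[1]:rc[2], rc[3]:rc[4]] <- TRUE
      rois[[paste0("roi", i)]] <- f
    }
  }

  rows <- list()
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    for (rn in names(rois)) {
      sel <- rois[[rn]] & m$validity
      hist <- tryCatch(angular_distribution(m$retardance_angle, rois[[rn]]),
                       error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        wavelength_nm = m$wavelength, roi = rn, n_pixels = sum(sel),
        mean_retardance_rad = mean(m$retardance[sel], na.rm = TRUE),
        mean_retardance_angle_deg = axial_mean(m$retardance_angle[sel]),
        dominant_angle_deg = if (is.null(hist)) NA_real_ else hist$dominant_angle,
        mean_diattenuation = mean(m$diattenuation[sel], na.rm = TRUE),
        mean_depolarization = mean(m$depolarization[sel], na.rm = TRUE))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else data.frame()

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- export_maps(maps, cfg$output_dir)
  sfile <- file.path(cfg$output_dir, "summary.tsv")
  num <- vapply(summary, is.numeric, logical(1))
  fmt <- summary
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.9g", x))
  utils::write.table(fmt, sfile, sep = "\t", row.names = FALSE, quote = FALSE)
  lfile <- file.path(cfg$output_dir, "pipeline_log.json")
  jsonlite::write_json(log, lfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(summary = summary, maps = maps,
                 files = c(files, sfile, lfile), log = log))
}
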