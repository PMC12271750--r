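#' Multi-frame speckle stack
#'
#' Container for an ordered sequence of raw speckle intensity frames with
#' the acquisition metadata needed by the temporal models: exposure time `T`
#' and inter-frame dead time `delta`. Frames are stored as a numeric
#' `height x width x L` array (frame index along the third dimension).
#'
#' @param frames Numeric 3-D array `height x width x L` of non-negative
#'   intensities.
#' @param exposure Exposure time `T` per frame (seconds, `> 0`).
#' @param delta Dead time between consecutive frames (seconds, `>= 0`).
#' @param meta Optional named list of extra metadata (e.g. simulator ground
#'   truth).
#' @return An object of class `"speckle_stack"`.
#' @export
speckle_stack <- function(frames, exposure, delta = 0, meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L || !is.numeric(frames))
    stop("`frames` must be a numeric height x width x L array", call. = FALSE)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and non-negative", call. = FALSE)
  check_scalar(exposure, "exposure", lower = 0, strict_lower = TRUE)
  check_scalar(delta, "delta", lower = 0)
  structure(list(frames = frames, exposure = exposure, delta = delta,
                 meta = meta),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_stack: %d frames of %d x %d px, T = %g s, delta = %g s\n",
              d[3], d[1], d[2], x$exposure, x$delta))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [speckle_stack()].
#' @return Integer frame count `L`.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "speckle_stack"))
  dim(stack$frames)[3]
}

# Validate and normalize a rectangular ROI given as c(r1, r2, c1, c2),
# 1-based inclusive bounds. NULL means the full frame.
resolve_roi <- function(roi, dims) {
  if (is.null(roi)) return(c(1L, dims[1], 1L, dims[2]))
  if (length(roi) != 4L || any(roi != round(roi)))
    stop("`roi` must be c(row_min, row_max, col_min, col_max)", call. = FALSE)
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[2] > dims[1] || roi[3] < 1L || roi[4] > dims[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("`roi` is outside the frame bounds", call. = FALSE)
  roi
}

#' Write a speckle stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are written as 32-bit float TIFF pages. TIFF sample values are
#' constrained to `[0, 1]`, so intensities are divided by a scale factor
#' (the stack maximum) that is recorded, together with `exposure`, `delta`
#' and any metadata, in a JSON sidecar `<path>.json`. [read_stack()]
#' restores the original intensities.
#'
#' @param stack A [speckle_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "speckle_stack"))
  scale <- max(stack$frames, 1e-300)
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) stack$frames[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- c(list(exposure = stack$exposure, delta = stack$delta,
                    scale = scale), stack$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a speckle stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must be present
#'   (it carries the exposure, dead time and intensity scale).
#' @return A [speckle_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing JSON sidecar: ", sidecar_path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frames <- frames * meta$scale
  extra <- meta[setdiff(names(meta), c("exposure", "delta", "scale"))]
  speckle_stack(frames, exposure = meta$exposure, delta = meta$delta,
                meta = extra)
}
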