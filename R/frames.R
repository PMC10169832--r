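#' OCTA frame sequence
#'
#' Container for a sequence of co-located 2D en-face OCT angiograms. Frames
#' are stored as an `H x W x T` numeric array; non-finite values mark
#' invalid (e.g. out-of-field) pixels. A sequence is created unaligned;
#' [align_sequence()] returns an aligned copy carrying one transform record
#' per frame.
#'
#' @param frames numeric `H x W x T` array, or a list of `T` equally sized
#'   matrices.
#' @param px_per_mm pixel scale; the default corresponds to a 304-pixel scan
#'   of a 3 mm field.
#' @param aligned logical, whether the frames are already in a common
#'   reference geometry.
#' @param upscale_factor integer upscaling factor already applied (1 = raw).
#' @param transforms optional list of per-frame transform records (see
#'   [align_sequence()]); required when `aligned = TRUE`.
#' @return an object of class `octa_frames`.
#' @export
octa_frames <- function(frames, px_per_mm = 304 / 3, aligned = FALSE,
                        upscale_factor = 1L, transforms = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop_octa("all frames must share one shape; found %d distinct shapes", length(dims))
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop_octa("frames must be an H x W x T array or a list of matrices")
  if (dim(frames)[3] < 2L)
    stop_octa("a frame sequence needs at least 2 frames, got %d", dim(frames)[3])
  if (isTRUE(aligned) && (is.null(transforms) || length(transforms) != dim(frames)[3]))
    stop_octa("aligned sequences must carry one transform record per frame")
  structure(list(frames = frames, px_per_mm = px_per_mm,
                 aligned = isTRUE(aligned),
                 upscale_factor = as.integer(upscale_factor),
                 transforms = transforms),
            class = "octa_frames")
}

#' @export
dim.octa_frames <- function(x) dim(x$frames)

n_frames <- function(fs) dim(fs$frames)[3]

#' @export
print.octa_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<octa_frames> %d frames of %d x %d px (%.1f px/mm), %s, upscale x%d\n",
              d[3], d[1], d[2], x$px_per_mm,
              if (x$aligned) "aligned" else "unaligned", x$upscale_factor))
  invisible(x)
}

# Temporal mean over finite samples only.
temporal_mean <- function(fs) {
  f <- fs$frames
  apply(f, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
}

#' Read and write frame sequences
#'
#' Multi-page TIFF is the primary on-disk format (float samples, one page
#' per frame). Headerless raw float32 frames are supported through a JSON
#' sidecar declaring `height`, `width`, `n_frames` and `byte_order`; the
#' vendor raw layout is deliberately not guessed. A series of grayscale PNG
#' files (one frame each) is also accepted.
#'
#' @param path file path (TIFF or raw; for PNG, a character vector of frame
#'   paths).
#' @param fs an `octa_frames` object.
#' @param ... passed to [octa_frames()] (e.g. `px_per_mm`).
#' @return `read_frames_*` return an `octa_frames`; `write_frames_tiff`
#'   returns `path` invisibly.
#' @name frames_io
NULL

#' @rdname frames_io
#' @export
write_frames_tiff <- function(fs, path) {
  fr <- lapply(seq_len(n_frames(fs)), function(t) {
    m <- fs$frames[, , t]
    m[!is.finite(m)] <- NaN
    m
  })
  tiff::writeTIFF(fr, path, bits.per.sample = 32L, compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname frames_io
#' @export
read_frames_tiff <- function(path, ...) {
  fr <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  fr <- lapply(fr, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  octa_frames(fr, ...)
}

#' @rdname frames_io
#' @export
read_frames_raw <- function(path, ...) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_octa("raw frame file requires a JSON sidecar at %s declaring height, width, n_frames, byte_order", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  need <- c("height", "width", "n_frames")
  if (!all(need %in% names(meta)))
    stop_octa("sidecar must declare %s", paste(need, collapse = ", "))
  n <- meta$height * meta$width * meta$n_frames
  v <- readBin(path, what = "numeric", n = n, size = 4L,
               endian = meta$byte_order %||% "little")
  if (length(v) != n)
    stop_octa("raw file holds %d values but sidecar promises %d", length(v), n)
  octa_frames(array(v, dim = c(meta$height, meta$width, meta$n_frames)), ...)
}

#' @rdname frames_io
#' @export
read_frames_png <- function(path, ...) {
  fr <- lapply(path, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  octa_frames(fr, ...)
}

# Labeled integer masks as 16-bit TIFF (values scaled by 1/65535 on disk).
write_mask_tiff <- function(mask, path) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask)) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none", reduce = FALSE)
  invisible(path)
}

read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}
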