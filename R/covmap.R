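#' Pixel-wise coefficient-of-variation map
#'
#' Computes, for every pixel with all `T` temporal samples valid and a
#' temporal mean above `mean_floor`, the sample standard deviation over
#' time divided by the temporal mean, expressed as a percentage. The sample
#' (n-1) SD is the estimator of choice for the short (typically 20-frame)
#' series involved. Pixels failing the validity conditions are `NA` and are
#' excluded from all downstream statistics rather than clamped.
#'
#' @param fs an aligned [octa_frames()] sequence.
#' @param mean_floor smallest admissible temporal mean; default 1% of the
#'   global mean intensity of the stack, guarding against division
#'   blow-ups in near-empty background.
#' @param require_aligned set `FALSE` to allow computing on an unaligned
#'   sequence (e.g. motion-free simulations).
#' @return object of class `cov_map`: list with `values` (matrix, percent,
#'   `NA` where invalid), `valid` (logical matrix) and `n_frames`.
#' @export
compute_cov_map <- function(fs, mean_floor = NULL, require_aligned = TRUE) {
  if (!inherits(fs, "octa_frames")) stop_octa("fs must be an octa_frames sequence")
  tt <- n_frames(fs)
  if (tt < 2) stop_octa("CoV needs at least 2 frames")
  if (require_aligned && !isTRUE(fs$aligned))
    stop_octa("sequence is not aligned; run align_sequence() first (or set require_aligned = FALSE)")
  f <- fs$frames
  h <- dim(f)[1]; w <- dim(f)[2]
  fin <- is.finite(f)
  all_valid <- matrix(rowSums(fin, dims = 2) == tt, h, w)
  fz <- f; fz[!fin] <- 0
  s1 <- rowSums(fz, dims = 2)
  s2 <- rowSums(fz^2, dims = 2)
  mu <- s1 / tt
  if (is.null(mean_floor)) mean_floor <- 0.01 * mean(f[fin])
  valid <- all_valid & mu > mean_floor
  var_s <- pmax((s2 - tt * mu^2) / (tt - 1), 0)
  vals <- sqrt(var_s) / mu * 100
  vals[!valid] <- NA_real_
  out <- structure(list(values = matrix(vals, h, w), valid = valid,
                        n_frames = tt, mean_floor = mean_floor),
                   class = "cov_map")
  if (!any(valid)) warn_octa("CoV map has no valid pixels")
  out
}

#' @export
print.cov_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<cov_map> %d x %d px over %d frames; %d valid pixels, median %.2f%%\n",
              nrow(x$values), ncol(x$values), x$n_frames, length(v),
              if (length(v)) median(v) else NA))
  invisible(x)
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1) * 100`, with quartiles by linear interpolation
#' between order statistics (the quartile rule used throughout the
#' package). An outlier-resistant alternative to the CoV; returns `NA` with
#' a warning when `Q3 + Q1 = 0`.
#'
#' @param series numeric vector of length >= 4.
#' @return percent (scalar).
#' @export
quartile_coefficient_of_dispersion <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 4) stop_octa("QCD needs a series of at least 4 values")
  q <- q7(series, c(0.25, 0.75))
  if (q[1] + q[2] == 0) {
    warn_octa("QCD undefined: Q1 + Q3 = 0")
    return(NA_real_)
  }
  (q[2] - q[1]) / (q[2] + q[1]) * 100
}

#' Pixel-wise QCD map over an aligned sequence
#'
#' @inheritParams compute_cov_map
#' @return matrix of per-pixel QCD (percent), `NA` where undefined.
#' @export
compute_qcd_map <- function(fs, mean_floor = NULL, require_aligned = TRUE) {
  cm <- compute_cov_map(fs, mean_floor, require_aligned)  # reuse validity rules
  f <- fs$frames
  h <- dim(f)[1]; w <- dim(f)[2]
  out <- matrix(NA_real_, h, w)
  idx <- which(cm$valid)
  if (length(idx)) {
    tt <- dim(f)[3]
    series <- matrix(f[rep(idx, tt) + (rep(seq_len(tt), each = length(idx)) - 1) * h * w],
                     length(idx), tt)
    q1 <- apply(series, 1, function(v) q7(v, 0.25))
    q3 <- apply(series, 1, function(v) q7(v, 0.75))
    qq <- (q3 - q1) / (q3 + q1) * 100
    qq[(q3 + q1) == 0] <- NA_real_
    out[idx] <- qq
  }
  out
}
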