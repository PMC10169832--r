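# Shared low-level helpers. Quantiles everywhere use the linear-interpolation
# rule (R type 7); stated once here and used by QCD, IQR and ROI summaries.

q7 <- function(x, probs) as.numeric(quantile(x, probs, type = 7, names = FALSE, na.rm = TRUE))

iqr7 <- function(x) {
  q <- q7(x, c(0.25, 0.75))
  q[2] - q[1]
}

#' Bilinear sampling of a matrix at real-valued coordinates
#'
#' Samples `img` at (row, col) positions `r`, `c` using bilinear
#' interpolation. Positions outside the image domain, or positions whose
#' interpolation stencil touches a non-finite pixel, yield `NA` — resampled
#' out-of-field pixels are flagged invalid rather than zero-filled so that
#' they can be excluded from temporal statistics.
#'
#' @param img numeric matrix
#' @param r,c numeric vectors of equal length, 1-based pixel coordinates
#' @return numeric vector of sampled values (with `NA` where undefined)
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(r))
  inside <- is.finite(r) & is.finite(c) & r >= 1 & r <= h & c >= 1 & c <= w
  if (!any(inside)) return(out)
  r <- r[inside]; c <- c[inside]
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  out[inside] <- v
  out
}

# Resample a whole image under a rigid transform (rotation theta about the
# image centre, then translation by dx columns / dy rows). The returned image
# satisfies out(o) = img(R_theta (o - centre) + centre + (dy, dx)).
resample_rigid <- function(img, dx = 0, dy = 0, theta = 0, centre = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(centre)) centre <- c((h + 1) / 2, (w + 1) / 2)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  rr <- g$r - centre[1]; cc <- g$c - centre[2]
  rs <- cos(theta) * rr - sin(theta) * cc + centre[1] + dy
  cs <- sin(theta) * rr + cos(theta) * cc + centre[2] + dx
  matrix(bilinear_sample(img, rs, cs), h, w)
}

# 3x3 neighbour count of a logical/0-1 matrix (8-connectivity), zero-padded.
neighbour_count8 <- function(m) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  p <- rbind(0, cbind(0, m, 0), 0)
  h <- nrow(m); w <- ncol(m)
  s <- p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
    p[2:(h + 1), 1:w] + p[2:(h + 1), 3:(w + 2)] +
    p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
  s
}

# Shift a matrix by integer (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Normalized cross-correlation over jointly finite pixels of two images.
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(NA_real_)
  x <- a[ok]; y <- b[ok]
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy) * length(x) / (length(x) - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_octa <- function(...) stop(sprintf(...), call. = FALSE)
warn_octa <- function(...) warning(sprintf(...), call. = FALSE)
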