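#' Upscale a frame by an integer factor (bilinear)
#'
#' Output pixel `(i, j)` samples the input at `((i-1)/factor + 1,
#' (j-1)/factor + 1)`, so input grid points are preserved exactly at output
#' positions `factor*(i-1)+1`. Samples beyond the last input row/column
#' replicate the edge.
#'
#' @param frame numeric matrix.
#' @param factor integer >= 1.
#' @return matrix of size `factor * dim(frame)`.
#' @export
upscale <- function(frame, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_octa("upscale factor must be an integer >= 1")
  if (factor == 1L) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  ri <- pmin((seq_len(h * factor) - 1) / factor + 1, h)
  ci <- pmin((seq_len(w * factor) - 1) / factor + 1, w)
  g <- expand.grid(r = ri, c = ci)
  matrix(bilinear_sample(frame, g$r, g$c), h * factor, w * factor)
}

#' Nearest-neighbour upscaling for masks and label maps
#'
#' Geometrically matched to [upscale()]: output pixel `(i, j)` takes input
#' pixel `round((i-1)/factor + 1)`, so masks stay aligned with bilinearly
#' upscaled frames.
#'
#' @param mask logical or integer matrix.
#' @param factor integer >= 1.
#' @return upscaled matrix.
#' @export
upscale_mask <- function(mask, factor = 2L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(pmax(round((seq_len(h * factor) - 1) / factor + 1), 1), h)
  ci <- pmin(pmax(round((seq_len(w * factor) - 1) / factor + 1), 1), w)
  mask[ri, ci, drop = FALSE]
}

# Map a coordinate from the original grid to the upscaled grid.
upscale_coord <- function(x, factor) factor * (x - 1) + 1

# Integer-pixel translation estimate by FFT phase correlation; returns
# c(dr, dc) such that moving approx equals reference shifted content by it.
phase_correlation <- function(reference, moving) {
  a <- reference; b <- moving
  a[!is.finite(a)] <- mean(a[is.finite(a)])
  b[!is.finite(b)] <- mean(b[is.finite(b)])
  fa <- fft(a - mean(a)); fb <- fft(b - mean(b))
  cp <- fa * Conj(fb)
  den <- Mod(cp); den[den < 1e-12] <- 1e-12
  r <- Re(fft(cp / den, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  d <- pk - 1L
  h <- nrow(a); w <- ncol(a)
  if (d[1] > h / 2) d[1] <- d[1] - h
  if (d[2] > w / 2) d[2] <- d[2] - w
  c(dr = -unname(d[1]), dc = -unname(d[2]))
}

#' Rigid registration of a frame to a reference
#'
#' Estimates translation and rotation maximizing the normalized
#' cross-correlation (NCC) between the resampled moving frame and the
#' reference. Translation is initialized by FFT phase correlation and the
#' three parameters are refined by Nelder-Mead on the NCC objective
#' evaluated on a subsampled pixel grid. The recovered parameters are the
#' motion of the moving frame's content relative to the reference, i.e.
#' applying [apply_motion()] with them to the reference reproduces the
#' moving frame (up to interpolation).
#'
#' @param moving,reference numeric matrices of the same shape, non-constant.
#' @param subsample integer stride of the pixel grid used in the objective.
#' @param maxit Nelder-Mead iteration cap.
#' @return list with `rigid = c(dx, dy, theta)`, `aligned` (resampled moving
#'   frame, `NA` outside the field), `ncc_before`, `ncc_after` and
#'   `converged`.
#' @export
register_rigid <- function(moving, reference, subsample = 2L, maxit = 500) {
  if (!all(dim(moving) == dim(reference)))
    stop_octa("moving and reference must share one shape")
  if (sd(reference[is.finite(reference)]) == 0 || sd(moving[is.finite(moving)]) == 0)
    stop_octa("rigid registration needs non-constant frames")
  h <- nrow(reference); w <- ncol(reference)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  g <- expand.grid(r = seq(1, h, by = subsample), c = seq(1, w, by = subsample))
  ref_s <- reference[cbind(g$r, g$c)]

  objective <- function(p) {
    rr <- g$r - ctr[1]; cc <- g$c - ctr[2]
    rs <- cos(p[3]) * rr - sin(p[3]) * cc + ctr[1] + p[2]
    cs <- sin(p[3]) * rr + cos(p[3]) * cc + ctr[2] + p[1]
    v <- bilinear_sample(moving, rs, cs)
    nc <- ncc(v, ref_s)
    if (is.na(nc)) 2 else 1 - nc
  }

  init <- phase_correlation(reference, moving)
  p0 <- c(init["dc"], init["dr"], 0)
  opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8,
                                     parscale = c(1, 1, 0.02)))
  p <- unname(opt$par)
  # a near-identity estimate needs no resampling (and no interpolation loss)
  if (max(abs(p[1:2])) < 1e-3 && abs(p[3]) * max(h, w) < 1e-3) {
    p <- c(0, 0, 0)
    aligned <- moving
  } else {
    aligned <- resample_rigid(moving, dx = p[1], dy = p[2], theta = p[3], centre = ctr)
  }
  nb <- ncc(moving, reference); na_ <- ncc(aligned, reference)
  # interpolation of fine structure may cost a little correlation even at
  # the correct parameters; only a material drop counts as failure
  converged <- opt$convergence == 0 && is.finite(na_) && na_ >= nb - 0.01
  if (!converged)
    warn_octa("rigid registration did not converge cleanly (optim code %d, NCC %.4f -> %.4f)",
              opt$convergence, nb, na_)
  list(rigid = c(dx = p[1], dy = p[2], theta = p[3]), aligned = aligned,
       ncc_before = nb, ncc_after = na_, converged = converged)
}

#' Non-linear (smooth displacement) registration
#'
#' Estimates a smooth dense displacement field on top of an already
#' rigid-aligned frame pair with a diffusion-regularized (demons-style)
#' iteration: at each step the intensity residual drives a per-pixel force
#' along the mean image gradient, and the accumulated field is smoothed
#' with a Gaussian whose width follows a coarse-to-fine schedule derived
#' from `grid_spacing` (the regularization scale, in pixels). Identical
#' frames yield an exactly zero field; if the warped result does not
#' improve global NCC the zero field is returned, so the stage never
#' degrades the alignment.
#'
#' @param moving,reference numeric matrices, same shape; rigid stage
#'   already applied.
#' @param grid_spacing regularization scale in pixels (>= 8); the field is
#'   smoothed at Gaussian sigmas `grid_spacing`, `grid_spacing/2`,
#'   `grid_spacing/4`.
#' @param iters iterations per smoothing level.
#' @return list with `field` (list `ur`, `uc`), `aligned`, `ncc_before`,
#'   `ncc_after`.
#' @export
register_nonlinear <- function(moving, reference, grid_spacing = 8, iters = 30) {
  if (!all(dim(moving) == dim(reference)))
    stop_octa("moving and reference must share one shape")
  if (grid_spacing < 8) stop_octa("grid_spacing must be at least 8 px")
  h <- nrow(reference); w <- ncol(reference)
  ref <- reference; ref[!is.finite(ref)] <- mean(reference[is.finite(reference)])
  mov <- moving; mov[!is.finite(mov)] <- mean(moving[is.finite(moving)])
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  grad <- function(m) list(gr = (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2,
                           gc = (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2)
  gref <- grad(ref)
  ur <- matrix(0, h, w); uc <- matrix(0, h, w)
  for (sig in c(grid_spacing, grid_spacing / 2, grid_spacing / 4)) {
    for (it in seq_len(iters)) {
      cur <- matrix(bilinear_sample(mov, g$r + as.vector(ur), g$c + as.vector(uc)), h, w)
      cur[!is.finite(cur)] <- 0
      d <- ref - cur; d[!is.finite(d)] <- 0
      gcur <- grad(cur)
      gr_ <- (gref$gr + gcur$gr) / 2; gc_ <- (gref$gc + gcur$gc) / 2
      den <- gr_^2 + gc_^2 + d^2
      den[den < 1e-6] <- Inf
      ur <- as.matrix(EBImage::gblur(ur + d * gr_ / den, sigma = sig))
      uc <- as.matrix(EBImage::gblur(uc + d * gc_ / den, sigma = sig))
    }
  }
  if (any(!is.finite(ur)) || any(!is.finite(uc)))
    stop_octa("non-linear registration produced a non-finite displacement field")
  aligned <- matrix(bilinear_sample(moving, g$r + as.vector(ur), g$c + as.vector(uc)), h, w)
  nb <- ncc(moving, reference); na_ <- ncc(aligned, reference)
  if (!is.finite(na_) || na_ < nb) {   # never degrade the alignment
    ur[] <- 0; uc[] <- 0
    aligned <- moving
    na_ <- nb
  }
  list(field = list(ur = ur, uc = uc), aligned = aligned,
       ncc_before = nb, ncc_after = na_)
}

#' Align a frame sequence
#'
#' Upscales every frame (bilinear, factor 2 by default), then registers each
#' frame to the reference with a rigid stage followed optionally by a
#' non-linear stage. The reference is the first frame by default, or the
#' temporal mean template. Out-of-field pixels after resampling are `NA`
#' and excluded from downstream temporal statistics.
#'
#' @param fs an [octa_frames()] sequence.
#' @param reference `"first"` or `"mean"`.
#' @param upscale_factor integer upscaling applied before registration.
#' @param nonlinear logical, run the non-linear stage after the rigid one.
#' @param grid_spacing regularization scale of the non-linear stage
#'   (upscaled px).
#' @param subsample stride of the rigid NCC objective grid.
#' @return an aligned `octa_frames` with per-frame transform records
#'   (`rigid`, `ncc_before`, `ncc_after`; `field` when non-linear ran).
#' @export
align_sequence <- function(fs, reference = c("first", "mean"),
                           upscale_factor = 2L, nonlinear = TRUE,
                           grid_spacing = 8, subsample = 2L) {
  reference <- match.arg(reference)
  tt <- n_frames(fs)
  d <- dim(fs$frames)
  frames_up <- lapply(seq_len(tt), function(t) upscale(fs$frames[, , t], upscale_factor))
  ref <- if (reference == "first") frames_up[[1]] else {
    Reduce(`+`, lapply(frames_up, function(m) { m[!is.finite(m)] <- 0; m })) / tt
  }
  out <- vector("list", tt)
  recs <- vector("list", tt)
  for (t in seq_len(tt)) {
    if (reference == "first" && t == 1L) {
      out[[t]] <- frames_up[[t]]
      recs[[t]] <- list(rigid = c(dx = 0, dy = 0, theta = 0), field = NULL,
                        ncc_before = 1, ncc_after = 1)
      next
    }
    rg <- tryCatch(register_rigid(frames_up[[t]], ref, subsample = subsample),
                   error = function(e) stop_octa("frame %d: rigid registration failed: %s", t, conditionMessage(e)))
    rec <- list(rigid = rg$rigid, field = NULL,
                ncc_before = rg$ncc_before, ncc_after = rg$ncc_after)
    aligned <- rg$aligned
    if (nonlinear) {
      nl <- register_nonlinear(aligned, ref, grid_spacing = grid_spacing)
      aligned <- nl$aligned
      rec$field <- nl$field
      rec$ncc_after <- nl$ncc_after
    }
    out[[t]] <- aligned
    recs[[t]] <- rec
  }
  octa_frames(out, px_per_mm = fs$px_per_mm * upscale_factor,
              aligned = TRUE, upscale_factor = fs$upscale_factor * upscale_factor,
              transforms = recs)
}

# Serialize per-frame transform records to JSON.
write_transforms_json <- function(fs, path) {
  if (!isTRUE(fs$aligned)) stop_octa("sequence is not aligned")
  recs <- lapply(fs$transforms, function(r) {
    list(rigid = as.list(r$rigid),
         ncc_before = r$ncc_before, ncc_after = r$ncc_after,
         has_field = !is.null(r$field))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
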