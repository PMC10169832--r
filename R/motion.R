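#' Apply known motion to a frame
#'
#' Warps a frame by a rigid transform (rotation `theta` about the image
#' centre, then translation by `dx` columns and `dy` rows) optionally
#' followed by a smooth non-linear displacement field. Content at pixel
#' `(r, c)` moves to `(r + dy, c + dx)` (plus the field); resampling is
#' bilinear and pixels pulled from outside the field of view become `NA`.
#' The inverse of a small smooth field is approximated to first order,
#' which is accurate for the bandlimited, few-pixel fields used to
#' exercise registration.
#'
#' @param frame numeric matrix.
#' @param dx,dy translation in pixels (columns / rows).
#' @param theta rotation in radians about the image centre.
#' @param field optional displacement field, a list with matrices `ur`,
#'   `uc` (row/col displacement per pixel) the same size as `frame`.
#' @param centre rotation centre, default the image centre.
#' @return warped matrix (`NA` outside the field of view).
#' @export
apply_motion <- function(frame, dx = 0, dy = 0, theta = 0, field = NULL,
                         centre = NULL) {
  if (!all(is.finite(c(dx, dy, theta)))) stop_octa("motion parameters must be finite")
  h <- nrow(frame); w <- ncol(frame)
  if (max(abs(c(dx, dy))) > 0.1 * min(h, w))
    stop_octa("displacement (%g, %g) exceeds 10%% of the frame size", dx, dy)
  if (is.null(centre)) centre <- c((h + 1) / 2, (w + 1) / 2)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  rq <- g$r; cq <- g$c
  if (!is.null(field)) {           # first-order inverse of the smooth field
    rq <- rq - as.vector(field$ur)
    cq <- cq - as.vector(field$uc)
  }
  rr <- rq - dy - centre[1]; cc <- cq - dx - centre[2]
  rs <- cos(theta) * rr + sin(theta) * cc + centre[1]
  cs <- -sin(theta) * rr + cos(theta) * cc + centre[2]
  matrix(bilinear_sample(frame, rs, cs), h, w)
}

#' Bandlimited smooth displacement field
#'
#' A low-frequency separable sinusoidal displacement field scaled so its
#' largest displacement magnitude equals `max_disp`. Used to inject known
#' smooth deformation for registration tests.
#'
#' @param shape image shape (rows, cols).
#' @param max_disp maximum displacement magnitude in pixels.
#' @param seed integer seed.
#' @return list with matrices `ur`, `uc`.
#' @export
make_smooth_field <- function(shape, max_disp = 2, seed = 1) {
  with_seed(seed, {
    h <- shape[1]; w <- shape[2]
    rr <- matrix(seq_len(h), h, w) / h
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) / w
    comp <- function() {
      k1 <- sample(1:2, 1); k2 <- sample(1:2, 1)
      sin(2 * pi * k1 * rr + runif(1, 0, 2 * pi)) *
        sin(2 * pi * k2 * cc + runif(1, 0, 2 * pi))
    }
    ur <- comp() + 0.5 * comp()
    uc <- comp() + 0.5 * comp()
    mag <- sqrt(ur^2 + uc^2)
    s <- max_disp / max(mag)
    list(ur = ur * s, uc = uc * s)
  })
}

#' Inject random rigid motion into a frame sequence
#'
#' Applies an independent random rigid transform to every frame after the
#' first (the first frame stays fixed as the natural reference). The
#' ground-truth parameters are attached for recovery tests.
#'
#' @param fs an [octa_frames()] sequence.
#' @param max_shift maximum |dx|, |dy| in pixels.
#' @param max_rot_deg maximum |rotation| in degrees.
#' @param seed integer seed.
#' @return `fs` with motion applied and a `motion_truth` attribute (list of
#'   per-frame `c(dx, dy, theta)`).
#' @export
inject_motion <- function(fs, max_shift = 3, max_rot_deg = 1, seed = 1) {
  with_seed(seed, {
    tt <- n_frames(fs)
    truth <- vector("list", tt)
    truth[[1]] <- c(dx = 0, dy = 0, theta = 0)
    for (t in 2:tt) {
      p <- c(dx = runif(1, -max_shift, max_shift),
             dy = runif(1, -max_shift, max_shift),
             theta = runif(1, -1, 1) * max_rot_deg * pi / 180)
      fs$frames[, , t] <- apply_motion(fs$frames[, , t], p["dx"], p["dy"], p["theta"])
      truth[[t]] <- p
    }
    attr(fs, "motion_truth") <- truth
    fs
  })
}
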