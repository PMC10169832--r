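#' Generate a synthetic macular OCTA phantom
#'
#' Builds a 2D macular vasculature phantom with full ground truth: radially
#' arranged arteriole and venule trees alternating around the fovea centre
#' (each with a small number of thinner branches, emulating the order-2 to
#' order-4 vessels selected as major-vessel ROIs), an avascular FAZ disc
#' bounded by a terminal capillary ring, and an interstitial capillary mesh
#' (edges between blue-noise points) filling the annulus between the ring
#' and the field edge. The returned object carries the vessel label map,
#' per-vessel class, the exact single-pixel centreline, per-vessel masks,
#' the FAZ mask, and ground-truth ROI masks for all seven categories.
#'
#' @param shape image height/width in pixels (two integers, each >= 64).
#' @param n_arterioles,n_venules number of major radial arterioles/venules
#'   (>= 1 each; the macular field typically shows about eight pairs).
#' @param faz_radius radius of the foveal avascular zone in pixels (> 0 and
#'   < `min(shape)/4`).
#' @param seed integer seed; the phantom is a pure function of its
#'   arguments.
#' @param mesh_spacing capillary mesh point spacing in pixels.
#' @param px_per_mm pixel scale carried through to downstream geometry.
#' @return an object of class `octa_phantom` with fields `shape`,
#'   `fovea_centre`, `faz_radius`, `vessel_label_map`, `vessel_class`
#'   (character vector indexed by vessel id), `centreline_truth`,
#'   `vessel_masks`, `faz_mask`, `roi_truth`, `cov_true_class`
#'   and `px_per_mm`.
#' @export
generate_phantom <- function(shape = c(304, 304), n_arterioles = 8,
                             n_venules = 8, faz_radius = 30, seed = 1,
                             mesh_spacing = 7, px_per_mm = shape[1] / 3) {
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  if (any(shape < 64)) stop_octa("phantom shape must be at least 64 px a side, got %dx%d", shape[1], shape[2])
  if (n_arterioles < 1 || n_venules < 1) stop_octa("need at least one arteriole and one venule")
  if (faz_radius <= 0) stop_octa("faz_radius must be positive (the terminal capillary ring is undefined otherwise)")
  if (faz_radius >= min(shape) / 4) stop_octa("faz_radius %g too large for a %dx%d field", faz_radius, shape[1], shape[2])

  with_seed(seed, {
    h <- shape[1]; w <- shape[2]
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    label <- matrix(0L, h, w)
    centreline <- matrix(FALSE, h, w)
    vclass <- character(0)
    vparent <- integer(0)       # major-vessel index each id belongs to (0 = none)
    next_id <- 0L
    new_id <- function(class, parent = 0L) {
      next_id <<- next_id + 1L
      vclass[next_id] <<- class
      vparent[next_id] <<- parent
      next_id
    }

    draw <- function(pts, id, width) {
      px <- rasterize_path(pts, c(h, w))
      if (!nrow(px)) return(invisible(NULL))
      centreline[px] <<- TRUE
      if (width > 1) px <- thicken(px, width, c(h, w))
      label[px] <<- id
      invisible(NULL)
    }

    # --- major radial vessels, alternating arteriole / venule -------------
    n_major <- n_arterioles + n_venules
    classes <- rep(c("arteriole", "venule"), length.out = n_major)
    # interleave as evenly as the two counts allow
    if (n_arterioles != n_venules)
      classes <- sample(rep(c("arteriole", "venule"), c(n_arterioles, n_venules)))
    angles <- 2 * pi * (seq_len(n_major) - 1) / n_major + runif(1, 0, 2 * pi / n_major)
    r_out <- 0.48 * min(h, w)
    majors <- list()
    for (i in seq_len(n_major)) {
      gap <- runif(1, 6, 14)
      r_in <- faz_radius + gap
      radii <- seq(r_out, r_in, by = -2)
      curve <- runif(1, -0.0025, 0.0025)
      wob <- cumsum(rnorm(length(radii), 0, 0.008))
      th <- angles[i] + curve * (r_out - radii) + wob
      pts <- cbind(ctr[1] + radii * sin(th), ctr[2] + radii * cos(th))
      id <- new_id(classes[i], i)
      draw(pts, id, width = 5)
      majors[[i]] <- list(id = id, class = classes[i], angle = angles[i],
                          radii = radii, theta = th)
      # branches: thinner offshoots (lower-order vessels of the same tree)
      n_br <- sample(2:3, 1)
      for (b in seq_len(n_br)) {
        k <- sample(seq(5, length(radii) - 3), 1)
        p0 <- pts[k, ]
        side <- sample(c(-1, 1), 1)
        bang <- th[k] + side * runif(1, pi / 5, pi / 2.6)
        blen <- runif(1, 15, 40)
        bl <- seq(0, blen, by = 2)
        bth <- bang + cumsum(rnorm(length(bl), 0, 0.02))
        bpts <- cbind(p0[1] + bl * sin(bth), p0[2] + bl * cos(bth))
        bid <- new_id(classes[i], i)
        draw(bpts, bid, width = 2)
      }
    }

    # --- terminal capillary ring around the FAZ ---------------------------
    ring_id <- new_id("capillary")
    tt <- seq(0, 2 * pi, length.out = ceiling(2 * pi * faz_radius * 3))
    draw(cbind(ctr[1] + faz_radius * sin(tt), ctr[2] + faz_radius * cos(tt)),
         ring_id, width = 1)

    # --- capillary mesh: kNN edges between jittered-grid (blue-noise) points
    gr <- seq(3, h - 2, by = mesh_spacing)
    gc <- seq(3, w - 2, by = mesh_spacing)
    pts <- as.matrix(expand.grid(r = gr, c = gc))
    pts <- pts + matrix(runif(length(pts), -mesh_spacing / 3, mesh_spacing / 3), nrow(pts), 2)
    d_ctr <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    pts <- pts[d_ctr > faz_radius + 3 & pts[, 1] > 2 & pts[, 1] < h - 1 &
                 pts[, 2] > 2 & pts[, 2] < w - 1, , drop = FALSE]
    nd <- nrow(pts)
    if (nd > 3) {
      dm <- as.matrix(stats::dist(pts))
      diag(dm) <- Inf
      k <- 3L
      edges <- do.call(rbind, lapply(seq_len(nd), function(i) {
        nb <- order(dm[i, ])[seq_len(k)]
        cbind(pmin(i, nb), pmax(i, nb))
      }))
      edges <- unique(edges)
      elen <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] - pts[edges[, 2], , drop = FALSE])^2))
      mid <- (pts[edges[, 1], , drop = FALSE] + pts[edges[, 2], , drop = FALSE]) / 2
      mid_d <- sqrt((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2)
      edges <- edges[elen < 2.5 * mesh_spacing & mid_d > faz_radius + 1.5, , drop = FALSE]
      for (e in seq_len(nrow(edges))) {
        eid <- new_id("capillary")
        draw(pts[edges[e, ], , drop = FALSE], eid, width = 1)
      }
      # spokes joining the terminal ring to the mesh
      ring_th <- seq(0, 2 * pi, by = pi / 9)
      for (a in ring_th) {
        p0 <- c(ctr[1] + faz_radius * sin(a), ctr[2] + faz_radius * cos(a))
        dd <- (pts[, 1] - p0[1])^2 + (pts[, 2] - p0[2])^2
        j <- which.min(dd)
        if (dd[j] < (2.5 * mesh_spacing)^2) {
          eid <- new_id("capillary")
          draw(rbind(p0, pts[j, ]), eid, width = 1)
        }
      }
    }

    # --- enforce the avascular FAZ interior -------------------------------
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    d2ctr <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    inside <- d2ctr < faz_radius - 0.8
    label[inside] <- 0L
    centreline[inside] <- FALSE
    centreline <- centreline & label > 0L

    # --- per-major-vessel masks and names ---------------------------------
    a_i <- 0L; v_i <- 0L
    vessel_masks <- list()
    for (i in seq_len(n_major)) {
      ids <- which(vparent == i)
      m <- matrix(label %in% ids, h, w)
      if (classes[i] == "arteriole") {
        a_i <- a_i + 1L; nm <- paste0("a", a_i)
      } else {
        v_i <- v_i + 1L; nm <- paste0("v", v_i)
      }
      vessel_masks[[nm]] <- m
    }
    faz_mask <- d2ctr <= faz_radius

    phantom <- structure(list(
      shape = c(h, w), fovea_centre = ctr, faz_radius = faz_radius,
      vessel_label_map = label, vessel_class = vclass,
      centreline_truth = centreline, vessel_masks = vessel_masks,
      faz_mask = faz_mask, px_per_mm = px_per_mm,
      n_arterioles = n_arterioles, n_venules = n_venules, seed = seed
    ), class = "octa_phantom")
    phantom$roi_truth <- phantom_rois(phantom)
    phantom
  })
}

# Ground-truth ROI set for a phantom: major-vessel masks + FAZ as Voronoi
# seeds, quadrants through the fovea centre, and the F-cp annulus.
phantom_rois <- function(phantom, fcp_width = 6) {
  rs <- roi_set(
    arterioles = phantom$vessel_masks[grep("^a", names(phantom$vessel_masks))],
    venules = phantom$vessel_masks[grep("^v", names(phantom$vessel_masks))],
    faz = phantom$faz_mask,
    foveola_centre = phantom$fovea_centre
  )
  rs <- build_influence_rois(rs)
  rs <- add_quadrants(rs)
  rs <- add_fcp_band(rs, width = fcp_width)
  rs
}

#' @export
print.octa_phantom <- function(x, ...) {
  cat(sprintf("<octa_phantom> %d x %d px, %d vessels (%d major masks), FAZ radius %g px\n",
              x$shape[1], x$shape[2], length(x$vessel_class),
              length(x$vessel_masks), x$faz_radius))
  invisible(x)
}

#' Temporal intensity model for phantom sequences
#'
#' Class-specific temporal modulation of the OCTA signal. Large vessels
#' carry a low-amplitude sinusoidal modulation; capillaries carry a
#' two-state random telegraph ("blinking") modulation whose on/off switching
#' emulates intermittent capillary perfusion. Amplitudes are calibrated
#' analytically to the target population CoV of each class: a sinusoid of
#' relative amplitude `a` sampled over whole periods has population CoV
#' `a/sqrt(2)`, and a symmetric two-state telegraph of relative amplitude
#' `a` has population CoV `a`. The defaults target 16% CoV in major vessels
#' and 33% in capillaries, the pooled levels characteristic of healthy
#' macular OCTA.
#'
#' @param vessel_cov,capillary_cov target population CoV (percent) for the
#'   major-vessel and capillary classes.
#' @param noise_sd additive Gaussian sensor noise SD (intensity units;
#'   intensities are floored at 0).
#' @param n_frames number of frames (>= 2; 20 matches a standard repeated
#'   acquisition).
#' @param switch_prob per-frame state-switch probability of the telegraph
#'   process.
#' @param rng_seed integer seed used by [simulate_sequence()].
#' @return a list of class `temporal_model`.
#' @export
temporal_model <- function(vessel_cov = 16, capillary_cov = 33,
                           noise_sd = 5, n_frames = 20, switch_prob = 0.3,
                           rng_seed = 1) {
  if (n_frames < 2) stop_octa("n_frames must be at least 2")
  if (noise_sd < 0 || vessel_cov < 0 || capillary_cov < 0)
    stop_octa("amplitudes and noise_sd must be non-negative")
  structure(list(
    classes = list(
      arteriole = list(baseline = 200, amplitude = vessel_cov / 100 * sqrt(2), form = "sinusoid"),
      venule    = list(baseline = 190, amplitude = vessel_cov / 100 * sqrt(2), form = "sinusoid"),
      capillary = list(baseline = 150, amplitude = capillary_cov / 100, form = "telegraph")
    ),
    background = 20, noise_sd = noise_sd, n_frames = as.integer(n_frames),
    switch_prob = switch_prob, rng_seed = rng_seed
  ), class = "temporal_model")
}

#' Simulate an OCTA frame sequence from a phantom
#'
#' Every pixel of a vessel follows its vessel's modulation time course
#' (shared along the vessel segment) scaled by the class baseline, plus
#' independent additive Gaussian sensor noise floored at zero. The returned
#' ground-truth CoV map is the population CoV of the noiseless generative
#' process: `a/sqrt(2)` for sinusoidal vessels, `a` for telegraph vessels,
#' 0 for constant modulation and background.
#'
#' @param phantom an `octa_phantom`.
#' @param model a [temporal_model()].
#' @param seed optional seed overriding `model$rng_seed`.
#' @return a list with `frames` (an unaligned [octa_frames()]) and
#'   `cov_true` (matrix, percent).
#' @export
simulate_sequence <- function(phantom, model = temporal_model(), seed = NULL) {
  if (!inherits(phantom, "octa_phantom")) stop_octa("phantom must be an octa_phantom")
  tt <- model$n_frames
  if (is.null(tt) || tt < 2) stop_octa("temporal model must have n_frames >= 2")
  seed <- seed %||% model$rng_seed
  with_seed(seed, {
    h <- phantom$shape[1]; w <- phantom$shape[2]
    label <- phantom$vessel_label_map
    n_id <- length(phantom$vessel_class)
    cls <- phantom$vessel_class
    amp <- vapply(cls, function(k) model$classes[[k]]$amplitude, 0)
    base <- vapply(cls, function(k) model$classes[[k]]$baseline, 0)
    form <- vapply(cls, function(k) model$classes[[k]]$form, "")

    # per-vessel modulation time courses, in [-1, 1]
    m <- matrix(0, n_id, tt)
    for (i in seq_len(n_id)) {
      m[i, ] <- switch(form[i],
        sinusoid = sin(2 * pi * (seq_len(tt) - 1) / tt + runif(1, 0, 2 * pi)),
        telegraph = {
          s <- numeric(tt)
          s[1] <- sample(c(-1, 1), 1)
          flips <- runif(tt - 1) < model$switch_prob
          for (t in seq_len(tt - 1)) s[t + 1] <- if (flips[t]) -s[t] else s[t]
          s
        },
        constant = rep(0, tt),
        stop_octa("unknown modulation form '%s'", form[i])
      )
    }

    vess_idx <- which(label > 0L)
    id_of_px <- label[vess_idx]
    frames <- array(model$background, dim = c(h, w, tt))
    for (t in seq_len(tt)) {
      f <- matrix(model$background, h, w)
      f[vess_idx] <- base[id_of_px] * (1 + amp[id_of_px] * m[id_of_px, t])
      frames[, , t] <- f
    }
    if (model$noise_sd > 0) {
      frames <- frames + array(rnorm(length(frames), 0, model$noise_sd), dim = dim(frames))
      frames[frames < 0] <- 0
    }

    cov_px <- ifelse(form == "sinusoid", amp / sqrt(2),
                     ifelse(form == "telegraph", amp, 0)) * 100
    cov_true <- matrix(0, h, w)
    cov_true[vess_idx] <- cov_px[id_of_px]

    list(frames = octa_frames(frames, px_per_mm = phantom$px_per_mm),
         cov_true = cov_true)
  })
}

# --- internal geometry helpers ------------------------------------------

# Dense integer pixels along a polyline given as a k x 2 matrix of (row, col).
rasterize_path <- function(pts, shape) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (nrow(pts) < 1) return(cbind(integer(0), integer(0)))
  rs <- cs <- list()
  for (i in seq_len(max(1, nrow(pts) - 1))) {
    p <- pts[i, ]; q <- pts[min(i + 1, nrow(pts)), ]
    n <- max(2L, ceiling(max(abs(q - p)) / 0.3))
    s <- seq(0, 1, length.out = n)
    rs[[i]] <- p[1] + s * (q[1] - p[1])
    cs[[i]] <- p[2] + s * (q[2] - p[2])
  }
  r <- round(unlist(rs)); c <- round(unlist(cs))
  ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
  unique(cbind(r[ok], c[ok]))
}

# Expand a set of pixels to a stroke of the given width (disc stamping).
thicken <- function(px, width, shape) {
  rad <- width / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad), dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  r <- outer(px[, 1], off$dr, `+`); c <- outer(px[, 2], off$dc, `+`)
  r <- as.vector(r); c <- as.vector(c)
  ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
  unique(cbind(r[ok], c[ok]))
}

# Evaluate thunk with a temporary RNG state; generators are pure in `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
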