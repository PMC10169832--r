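#' ROI set for the seven macular categories
#'
#' Holds the user-supplied (or phantom ground-truth) masks — major radial
#' arteriole ROIs, major radial venule ROIs, the FAZ — and the derived
#' masks: per-vessel capillary influence zones ("a1-net", "v2-net", ...,
#' "F-net"), the pure-capillary band "F-cp", and the four quadrants.
#' Arteriole, venule and FAZ masks must be pairwise disjoint.
#'
#' @param arterioles,venules named lists of logical masks ("a1", "a2", ...;
#'   "v1", ...). Unnamed lists are named automatically.
#' @param faz logical FAZ mask.
#' @param foveola_centre (row, col) of the foveola centre; required for the
#'   quadrant category.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(arterioles, venules, faz, foveola_centre = NULL) {
  if (!length(arterioles) || !length(venules)) stop_octa("need at least one arteriole and one venule mask")
  if (is.null(names(arterioles)) || any(names(arterioles) == ""))
    names(arterioles) <- paste0("a", seq_along(arterioles))
  if (is.null(names(venules)) || any(names(venules) == ""))
    names(venules) <- paste0("v", seq_along(venules))
  masks <- c(arterioles, venules, list(FAZ = faz))
  shapes <- unique(lapply(masks, dim))
  if (length(shapes) != 1L) stop_octa("all ROI masks must share one shape")
  shape <- shapes[[1]]
  nm <- names(masks)
  for (i in seq_along(masks)) {
    if (!any(masks[[i]])) stop_octa("ROI mask '%s' is empty", nm[i])
    for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]]))
        stop_octa("ROI masks '%s' and '%s' overlap", nm[j], nm[i])
    }
  }
  structure(list(arterioles = arterioles, venules = venules, faz = faz,
                 foveola_centre = foveola_centre, shape = shape,
                 nets = NULL, fcp = NULL, quadrants = NULL),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d x %d px: %d arterioles, %d venules, FAZ%s%s%s\n",
              x$shape[1], x$shape[2], length(x$arterioles), length(x$venules),
              if (!is.null(x$nets)) sprintf(", %d influence zones", length(x$nets)) else "",
              if (!is.null(x$fcp)) ", F-cp" else "",
              if (!is.null(x$quadrants)) ", quadrants" else ""))
  invisible(x)
}

#' Load vessel and FAZ masks from image files
#'
#' Reads binary masks (any non-zero pixel is foreground) from TIFF or PNG
#' files and validates them into a [roi_set()]. Masks must match the
#' working frame geometry (i.e. the upscaled grid if frames are upscaled).
#'
#' @param arteriole_files,venule_files character vectors of mask paths; the
#'   ROI names are derived from the file base names, or default to
#'   "a1"..., "v1"....
#' @param faz_file path of the FAZ mask.
#' @param foveola_centre optional (row, col).
#' @param shape expected mask shape; checked when given.
#' @return a `roi_set`.
#' @export
load_roi_masks <- function(arteriole_files, venule_files, faz_file,
                           foveola_centre = NULL, shape = NULL) {
  read1 <- function(p) {
    m <- if (grepl("\\.png$", p, ignore.case = TRUE)) {
      im <- png::readPNG(p); if (length(dim(im)) == 3L) im <- im[, , 1]; im
    } else read_mask_tiff(p)
    if (!is.null(shape) && !all(dim(m) == shape))
      stop_octa("mask %s is %dx%d, expected %dx%d", p, nrow(m), ncol(m), shape[1], shape[2])
    m > 0
  }
  a <- lapply(arteriole_files, read1)
  v <- lapply(venule_files, read1)
  names(a) <- if (!is.null(names(arteriole_files))) names(arteriole_files) else paste0("a", seq_along(a))
  names(v) <- if (!is.null(names(venule_files))) names(venule_files) else paste0("v", seq_along(v))
  roi_set(a, v, read1(faz_file), foveola_centre = foveola_centre)
}

#' Euclidean influence zones (generalized Voronoi partition)
#'
#' Labels every pixel of `domain` with the index of the seed mask at
#' minimum Euclidean distance, so each seed receives the portion of the
#' domain closest to it. Distances are exact (squared distances compared as
#' integers); ties are broken toward the lowest seed index, which makes the
#' partition deterministic across platforms.
#'
#' @param seeds named list of >= 1 logical seed masks (non-empty).
#' @param domain logical mask of pixels to label; must exclude all seed
#'   pixels. Default: everything outside the seeds.
#' @return integer matrix, 0 outside the domain, otherwise the seed index;
#'   seed names attached as the `seeds` attribute.
#' @export
influence_zones <- function(seeds, domain = NULL) {
  if (!length(seeds)) stop_octa("need at least one seed mask")
  for (nm in names(seeds)) if (!any(seeds[[nm]])) stop_octa("seed '%s' is empty", nm)
  shape <- dim(seeds[[1]])
  any_seed <- Reduce(`|`, seeds)
  if (is.null(domain)) domain <- !any_seed
  if (any(domain & any_seed)) stop_octa("domain must exclude all seed pixels")
  best_d2 <- matrix(Inf, shape[1], shape[2])
  label <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(seeds)) {
    d <- EBImage::distmap(matrix(as.numeric(!seeds[[i]]), shape[1], shape[2]))
    d2 <- round(as.matrix(d)^2)          # exact integer squared distances
    upd <- domain & d2 < best_d2         # strict: ties keep the lower index
    best_d2[upd] <- d2[upd]
    label[upd] <- i
  }
  attr(label, "seeds") <- names(seeds)
  label
}

#' Build the capillary influence-zone ROIs of a set
#'
#' Computes the generalized Voronoi partition of the capillary domain
#' (everything outside the major vessels and the FAZ) with the arterioles,
#' venules and FAZ as seeds, and stores the zones as "a1-net", ...,
#' "v1-net", ..., and "F-net". "-net" masks exclude their parent vessel by
#' construction.
#'
#' @param rs a [roi_set()].
#' @return `rs` with `$nets` filled.
#' @export
build_influence_rois <- function(rs) {
  seeds <- c(rs$arterioles, rs$venules, list(FAZ = rs$faz))
  lab <- influence_zones(seeds)
  nets <- lapply(seq_along(seeds), function(i) lab == i)
  names(nets) <- ifelse(names(seeds) == "FAZ", "F-net", paste0(names(seeds), "-net"))
  rs$nets <- nets
  rs
}

#' Quadrant ROIs through the foveola centre
#'
#' Splits the field into four axis-aligned quadrants through the foveola
#' centre (Q1 upper-right, Q2 upper-left, Q3 lower-left, Q4 lower-right;
#' pixels exactly on a split line go to the lower/right side), then removes
#' the exclusion masks. Together with the exclusions the quadrants
#' partition the field.
#'
#' @param shape image shape (rows, cols).
#' @param foveola_centre (row, col), must lie inside the image.
#' @param exclusions list of logical masks to subtract (major vessels, FAZ).
#' @return named list of four logical masks.
#' @export
quadrant_rois <- function(shape, foveola_centre, exclusions = list()) {
  fr <- foveola_centre[1]; fc <- foveola_centre[2]
  if (fr < 1 || fr > shape[1] || fc < 1 || fc > shape[2])
    stop_octa("foveola centre (%g, %g) lies outside the %dx%d image", fr, fc, shape[1], shape[2])
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  upper <- rr < fr; lower <- !upper
  left <- cc < fc; right <- !left
  q <- list(Q1 = upper & right, Q2 = upper & left, Q3 = lower & left, Q4 = lower & right)
  if (length(exclusions)) {
    ex <- Reduce(`|`, exclusions)
    q <- lapply(q, function(m) m & !ex)
  }
  q
}

#' @rdname quadrant_rois
#' @param rs a [roi_set()] with a foveola centre.
#' @export
add_quadrants <- function(rs) {
  if (is.null(rs$foveola_centre))
    stop_octa("quadrant ROIs need a foveola centre; none is set")
  rs$quadrants <- quadrant_rois(rs$shape, rs$foveola_centre,
                                exclusions = c(rs$arterioles, rs$venules, list(rs$faz)))
  rs
}

#' Pure-capillary band around the FAZ
#'
#' Builds the "F-cp" ROI as an annulus of the given width extending outward
#' from the FAZ boundary — a helper for the interactively drawn
#' pure-capillary band; a hand-drawn mask can be assigned to `rs$fcp`
#' instead.
#'
#' @param rs a [roi_set()].
#' @param width band width in pixels (default 6).
#' @return `rs` with `$fcp` filled.
#' @export
add_fcp_band <- function(rs, width = 6) {
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!rs$faz), rs$shape[1], rs$shape[2])))
  rs$fcp <- d > 0 & d <= width
  rs
}

# The seven category names in canonical order.
roi_categories <- function() {
  c("Arteriole", "Arteriole-net", "Venule", "Venule-net",
    "FAZ-net", "FAZ-cp", "Quadrant")
}

# Named list of per-category mask lists for an roi_set with all derived
# masks built.
category_masks <- function(rs) {
  if (is.null(rs$nets) || is.null(rs$fcp) || is.null(rs$quadrants))
    stop_octa("roi_set is missing derived masks; run build_influence_rois(), add_quadrants(), add_fcp_band()")
  a_nets <- rs$nets[grep("^a", names(rs$nets))]
  v_nets <- rs$nets[grep("^v", names(rs$nets))]
  list(
    "Arteriole" = rs$arterioles,
    "Arteriole-net" = a_nets,
    "Venule" = rs$venules,
    "Venule-net" = v_nets,
    "FAZ-net" = rs$nets["F-net"],
    "FAZ-cp" = list("F-cp" = rs$fcp),
    "Quadrant" = rs$quadrants
  )
}

#' Assign vessel segments to ROIs
#'
#' For every category, each segment is assigned to at most one ROI by the
#' majority-of-pixels rule: the ROI of the category covering the largest
#' number of the segment's pixels, provided at least half of the segment
#' lies inside the category; ties are broken toward the ROI containing the
#' segment midpoint, then toward the lowest ROI index. Segments flagged
#' `excluded` (no valid CoV pixel) are dropped.
#'
#' @param segments a `vessel_segments` list with mean CoV attached.
#' @param rs a [roi_set()] with derived masks built.
#' @return data.frame: one row per retained segment, columns `id`,
#'   `mean_cov`, `length`, and one column per category holding the assigned
#'   ROI name (`NA` when unassigned).
#' @export
assign_segments <- function(segments, rs) {
  cm <- category_masks(rs)
  tab <- segments_table(segments)
  tab <- tab[!tab$excluded & is.finite(tab$mean_cov), , drop = FALSE]
  keep <- segments[tab$id]
  for (cat in names(cm)) {
    masks <- cm[[cat]]
    lab <- matrix(0L, rs$shape[1], rs$shape[2])
    for (i in seq_along(masks)) lab[masks[[i]]] <- i
    assigned <- rep(NA_character_, nrow(tab))
    for (k in seq_along(keep)) {
      p <- keep[[k]]$path
      if (max(p[, 1]) > nrow(lab) || max(p[, 2]) > ncol(lab))
        stop_octa("segment geometry does not match ROI mask geometry (%dx%d vs %dx%d)",
                  max(p[, 1]), max(p[, 2]), nrow(lab), ncol(lab))
      l <- lab[p]
      n_in <- sum(l > 0L)
      if (n_in * 2 < nrow(p)) next
      cnt <- tabulate(l[l > 0L], nbins = length(masks))
      best <- which(cnt == max(cnt))
      if (length(best) > 1L) {
        mid <- p[ceiling(nrow(p) / 2), , drop = FALSE]
        lm <- lab[mid]
        best <- if (lm %in% best) lm else min(best)
      }
      assigned[k] <- names(masks)[best]
    }
    tab[[cat]] <- assigned
  }
  tab
}

#' Summarize vessel-segment mean CoV per ROI
#'
#' The median of the vessel-segment mean CoV values of an ROI measures its
#' temporal variation; the IQR measures its spatial variation. Quartiles
#' use linear interpolation between order statistics.
#'
#' @param assignments the data.frame from [assign_segments()].
#' @param category one of the seven category names, or `NULL` for all.
#' @return data.frame with `category`, `roi`, `n_segments`,
#'   `median_mean_cov`, `iqr_mean_cov` (empty ROIs report `n_segments = 0`
#'   and `NA` statistics).
#' @export
summarize_roi <- function(assignments, category = NULL) {
  cats <- intersect(roi_categories(), names(assignments))
  if (!is.null(category)) cats <- intersect(cats, category)
  out <- list()
  for (cat in cats) {
    a <- assignments[[cat]]
    rois <- sort(unique(a[!is.na(a)]))
    if (!length(rois)) {
      out[[cat]] <- data.frame(category = cat, roi = NA_character_, n_segments = 0L,
                               median_mean_cov = NA_real_, iqr_mean_cov = NA_real_,
                               q1_mean_cov = NA_real_, q3_mean_cov = NA_real_)
      next
    }
    out[[cat]] <- do.call(rbind, lapply(rois, function(r) {
      v <- assignments$mean_cov[!is.na(a) & a == r]
      q <- q7(v, c(0.25, 0.75))
      data.frame(category = cat, roi = r, n_segments = length(v),
                 median_mean_cov = median(v), iqr_mean_cov = q[2] - q[1],
                 q1_mean_cov = q[1], q3_mean_cov = q[2])
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
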