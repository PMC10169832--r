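# Vessel centreline extraction and junction-to-junction segment
# decomposition. Detection runs on the temporal mean of the aligned
# sequence: multi-scale Hessian (Frangi-style) vesselness, hysteresis
# thresholding, small-component removal, then topological thinning to a
# single-pixel skeleton.

# Frangi-style vesselness for bright curvilinear structures on a dark
# background. Scales are Gaussian sigmas covering vessel radii of roughly
# 1-8 px on the upscaled grid.
frangi_vesselness <- function(img, scales = c(1, 2, 4), beta = 0.5) {
  img[!is.finite(img)] <- 0
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(img, sigma = s))
    hxx <- shift_mat(sm, -1, 0) - 2 * sm + shift_mat(sm, 1, 0)
    hyy <- shift_mat(sm, 0, -1) - 2 * sm + shift_mat(sm, 0, 1)
    hxy <- (shift_mat(sm, -1, -1) + shift_mat(sm, 1, 1) -
              shift_mat(sm, -1, 1) - shift_mat(sm, 1, -1)) / 4
    hxx <- hxx * s^2; hyy <- hyy * s^2; hxy <- hxy * s^2   # scale normalization
    tmp <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    l1 <- (hxx + hyy + tmp) / 2
    l2 <- (hxx + hyy - tmp) / 2
    big <- ifelse(abs(l1) >= abs(l2), l1, l2)
    small <- ifelse(abs(l1) >= abs(l2), l2, l1)
    rb2 <- (small / pmin(big, -1e-12))^2
    s2 <- hxx^2 + hyy^2 + 2 * hxy^2
    # structureness scale from a robust high quantile of the Hessian norm
    # over ridge candidates; the raw maximum is dominated by single bright
    # blobs and then suppresses every thinner structure
    ridge <- big < 0
    ref <- if (any(ridge)) quantile(s2[ridge], 0.999, names = FALSE) else max(s2)
    cpar <- max(sqrt(ref), 1e-12) / 2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[big >= 0] <- 0                    # bright ridges have negative big eigenvalue
    if (max(v) > 0) v <- v / max(v)     # balance thin and thick structures
    best <- pmax(best, v)
  }
  best
}

# Hysteresis threshold: keep connected components of (v >= lo) that contain
# at least one pixel with v >= hi.
hysteresis_threshold <- function(v, lo, hi) {
  weak <- v >= lo
  if (!any(weak)) return(weak)
  lbl <- EBImage::bwlabel(matrix(as.numeric(weak), nrow(v), ncol(v)))
  keep <- unique(lbl[v >= hi])
  keep <- keep[keep > 0]
  matrix(lbl %in% keep, nrow(v), ncol(v))
}

# Zhang-Suen thinning to a 1-px skeleton, with a final pass removing
# redundant pixels of any remaining 2x2 block when deletion preserves local
# 8-connectivity.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  get_nb <- function(m) {
    list(p2 = shift_mat(m, 1, 0), p3 = shift_mat(m, 1, -1),
         p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
         p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
         p8 = shift_mat(m, 0, 1), p9 = shift_mat(m, 1, 1))
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- get_nb(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (pass == 1) {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1L &
          nb$p2 * nb$p4 * nb$p6 == 0L & nb$p4 * nb$p6 * nb$p8 == 0L
      } else {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1L &
          nb$p2 * nb$p4 * nb$p8 == 0L & nb$p2 * nb$p6 * nb$p8 == 0L
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # clear leftover 2x2 blocks: drop a corner whose removal keeps its
  # neighbours mutually 8-connected (always true inside a 2x2 block)
  repeat {
    blk <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1]
    idx <- which(blk, arr.ind = TRUE)
    if (!nrow(idx)) break
    # remove the top-left pixel of each block only if it is simple here:
    # its 8-neighbourhood keeps one connected foreground component
    removed <- FALSE
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      for (cand in list(c(r, c), c(r + 1, c), c(r, c + 1), c(r + 1, c + 1))) {
        if (m[cand[1], cand[2]] == 1L && is_simple_pixel(m, cand[1], cand[2])) {
          m[cand[1], cand[2]] <- 0L
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }
  m == 1L
}

# A pixel is simple if its foreground neighbours form exactly one
# 8-connected component (so deleting it cannot split the skeleton locally).
is_simple_pixel <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  rr <- r + off[, 1]; cc <- c + off[, 2]
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  fg <- which(ok)[m[cbind(rr[ok], cc[ok])] == 1L]
  n <- length(fg)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  # union-find over the foreground neighbours using true pixel adjacency
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(rr[fg[i]] - rr[fg[j]]), abs(cc[fg[i]] - cc[fg[j]])) <= 1L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, 1L))) == 1L
}

#' Segment single-pixel vessel centrelines
#'
#' Enhances the temporal-mean image with multi-scale vesselness, applies a
#' hysteresis threshold, removes small components, and thins the result to
#' a single-pixel-wide skeleton.
#'
#' @param fs an aligned [octa_frames()] sequence, or a plain matrix taken
#'   as the (mean) intensity image.
#' @param scales vesselness Gaussian scales in pixels.
#' @param lo_frac,hi_frac hysteresis thresholds as fractions of the maximum
#'   vesselness response.
#' @param min_component minimum connected-component size (pixels) kept
#'   before thinning.
#' @return object of class `vessel_skeleton`: list with `mask` (logical),
#'   `node_type` (integer matrix: 0 off-skeleton, 1 endpoint, 2 interior,
#'   3 junction) and the detection parameters. An empty skeleton triggers a
#'   warning.
#' @export
segment_centrelines <- function(fs, scales = c(0.8, 1.5, 3), lo_frac = 0.02,
                                hi_frac = 0.10, min_component = 15) {
  img <- if (inherits(fs, "octa_frames")) temporal_mean(fs) else fs
  v <- frangi_vesselness(img, scales = scales)
  if (max(v) <= 0) {
    warn_octa("no vesselness response; returning an empty skeleton")
    empty <- matrix(FALSE, nrow(img), ncol(img))
    return(structure(list(mask = empty, node_type = matrix(0L, nrow(img), ncol(img)),
                          scales = scales), class = "vessel_skeleton"))
  }
  mask <- hysteresis_threshold(v, lo_frac * max(v), hi_frac * max(v))
  if (any(mask)) {
    lbl <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    sz <- tabulate(lbl[lbl > 0])
    mask <- matrix(lbl %in% which(sz >= min_component), nrow(mask), ncol(mask))
  }
  sk <- thin_mask(mask)
  if (!any(sk)) warn_octa("skeleton is empty")
  structure(list(mask = sk, node_type = classify_skeleton(sk), scales = scales),
            class = "vessel_skeleton")
}

# 0 = background, 1 = endpoint (or isolated), 2 = interior, 3 = junction.
classify_skeleton <- function(sk) {
  nb <- neighbour_count8(sk)
  out <- matrix(0L, nrow(sk), ncol(sk))
  out[sk & nb <= 1] <- 1L
  out[sk & nb == 2] <- 2L
  out[sk & nb >= 3] <- 3L
  out
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d skeleton px (%d junctions, %d endpoints)\n",
              sum(x$mask), sum(x$node_type == 3L), sum(x$node_type == 1L)))
  invisible(x)
}

#' Decompose a skeleton into junction-to-junction vessel segments
#'
#' Skeleton pixels are classified by their 8-neighbour count (1 = endpoint,
#' 2 = interior, >= 3 = junction). Junction pixels terminate paths and are
#' not assigned to any segment; the maximal 8-connected paths of the
#' remaining pixels are the vessel segments, ordered from one terminal to
#' the other. Isolated loops (closed paths without junctions) are returned
#' as one segment. Paths shorter than `min_segment_length` are dropped.
#'
#' @param skeleton a `vessel_skeleton` or a logical 1-px-thin mask.
#' @param min_segment_length minimum path length in pixels (default 3).
#' @return list of class `vessel_segments`; each element has `id`, `path`
#'   (n x 2 matrix of row/col), `length`.
#' @export
decompose_segments <- function(skeleton, min_segment_length = 3) {
  sk <- if (inherits(skeleton, "vessel_skeleton")) skeleton$mask else skeleton
  if (!any(sk)) return(structure(list(), class = "vessel_segments"))
  nt <- classify_skeleton(sk)
  keep <- sk & nt < 3L
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), class = "vessel_segments"))
  h <- nrow(sk); w <- ncol(sk)
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  posvec <- integer(h * w)
  posvec[idx] <- seq_along(idx)

  # 8-neighbour edges among kept pixels
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  el <- vector("list", 8)
  for (o in seq_len(8)) {
    rn <- r + offs[o, 1]; cn <- c + offs[o, 2]
    ok <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
    p2 <- integer(length(idx))
    p2[ok] <- posvec[(cn[ok] - 1L) * h + rn[ok]]
    hit <- p2 > 0L
    if (any(hit)) el[[o]] <- cbind(which(hit), p2[hit])
  }
  edges <- do.call(rbind, el)
  if (is.null(edges) || !nrow(edges)) {
    comps <- as.list(seq_along(idx))             # all pixels isolated
    gdeg <- rep(0L, length(idx))
    adj <- vector("list", length(idx))
  } else {
    edges <- unique(edges[edges[, 1] < edges[, 2], , drop = FALSE])
    g <- igraph::make_undirected_graph(t(edges), n = length(idx))
    comps <- split(seq_along(idx), igraph::components(g)$membership)
    gdeg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(idx))
    adj <- build_adjacency(edges, length(idx))
  }

  out <- list()
  sid <- 0L
  for (cp in comps) {
    if (length(cp) == 1L) {
      path <- cbind(r[cp], c[cp])
    } else {
      ends <- cp[gdeg[cp] <= 1L]
      start <- if (length(ends)) ends[1] else min(cp)  # loop: deterministic start
      ord <- walk_path(adj, start, length(cp))
      path <- cbind(r[ord], c[ord])
    }
    if (nrow(path) < min_segment_length) next
    sid <- sid + 1L
    out[[sid]] <- list(id = sid, path = path, length = nrow(path))
  }
  structure(out, class = "vessel_segments")
}

build_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  sp <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  adj[as.integer(names(sp))] <- sp
  adj
}

# Walk along a simple path (or loop) starting at `start`; path pixels have
# degree <= 2 so there is at most one unvisited neighbour at each step.
walk_path <- function(adj, start, n_total) {
  visited <- logical(length(adj))
  ord <- integer(n_total)
  cur <- start; n <- 0L
  repeat {
    n <- n + 1L
    ord[n] <- cur
    visited[cur] <- TRUE
    nb <- adj[[cur]]
    nb <- nb[!visited[nb]]
    if (!length(nb) || n == n_total) break
    cur <- nb[1]
  }
  ord[seq_len(n)]
}

#' @export
print.vessel_segments <- function(x, ...) {
  mc <- vapply(x, function(s) s$mean_cov %||% NA_real_, 0)
  cat(sprintf("<vessel_segments> %d segments, median length %s px%s\n",
              length(x),
              if (length(x)) format(median(vapply(x, `[[`, 0, "length"))) else "-",
              if (any(is.finite(mc))) sprintf(", median mean CoV %.2f%%", median(mc, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Attach per-segment mean CoV
#'
#' The vessel-segment mean CoV is the arithmetic mean of the per-pixel CoV
#' values along the segment path, restricted to valid pixels. Segments with
#' no valid pixel are flagged (`excluded = TRUE`, `mean_cov = NA`) and are
#' skipped by downstream summaries.
#'
#' @param cov_map a [compute_cov_map()] result.
#' @param segments a `vessel_segments` list.
#' @return `segments` with `mean_cov`, `n_valid` and `excluded` fields set.
#' @export
segment_mean_cov <- function(cov_map, segments) {
  v <- cov_map$values
  for (i in seq_along(segments)) {
    p <- segments[[i]]$path
    if (any(p[, 1] < 1 | p[, 1] > nrow(v) | p[, 2] < 1 | p[, 2] > ncol(v)))
      stop_octa("segment %d lies outside the CoV map domain", segments[[i]]$id)
    px <- v[p]
    px <- px[is.finite(px)]
    segments[[i]]$n_valid <- length(px)
    segments[[i]]$mean_cov <- if (length(px)) mean(px) else NA_real_
    segments[[i]]$excluded <- length(px) == 0L
  }
  segments
}

#' Tabulate vessel segments
#'
#' @param segments a `vessel_segments` list (after [segment_mean_cov()]).
#' @return data.frame with one row per segment: `id`, `length`, `n_valid`,
#'   `mean_cov`, `excluded`, and midpoint coordinates.
#' @export
segments_table <- function(segments) {
  if (!length(segments))
    return(data.frame(id = integer(0), length = integer(0), n_valid = integer(0),
                      mean_cov = numeric(0), excluded = logical(0),
                      mid_r = integer(0), mid_c = integer(0)))
  do.call(rbind, lapply(segments, function(s) {
    mid <- s$path[ceiling(nrow(s$path) / 2), ]
    data.frame(id = s$id, length = s$length,
               n_valid = s$n_valid %||% NA_integer_,
               mean_cov = s$mean_cov %||% NA_real_,
               excluded = s$excluded %||% FALSE,
               mid_r = mid[1], mid_c = mid[2])
  }))
}
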