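# Rendering of the centreline CoV heat maps and the comparative box plots.
# The colormap is a fixed monotone dark-blue -> red ramp; its name and the
# clamp range are recorded in the returned object so rendered figures are
# reproducible.

cov_colormap <- function(n = 256) {
  colorRampPalette(c("#00008B", "#0000FF", "#00BFFF", "#00FF7F",
                     "#FFFF00", "#FF7F00", "#FF0000"))(n)
}

#' Render a centreline CoV heat map
#'
#' Colours each vessel-segment pixel by CoV, clamped either at a global cap
#' (pixel CoV capped at `cap_value`, default 50%) or to the category range
#' `[min over ROIs of Q1, max over ROIs of Q3]` of segment mean CoV (the
#' per-category accentuation used for per-ROI figures). The colour ramp is
#' monotone from dark blue (least variation) to red (most variation).
#'
#' @param cov_map a [compute_cov_map()] result.
#' @param segments a `vessel_segments` list with mean CoV attached; segment
#'   pixels are painted with their segment's mean CoV. Pass `NULL` with a
#'   `skeleton` instead to paint per-pixel CoV.
#' @param skeleton optional `vessel_skeleton` used when `segments` is NULL.
#' @param mode `"global_cap"` or `"category_percentile"`.
#' @param cap_value global cap in percent (global mode).
#' @param summaries [summarize_roi()] output (category-percentile mode).
#' @param path optional PNG output path.
#' @return invisible list: `rgb` (H x W x 3 array), `clamp` (lo, hi),
#'   `colormap` name.
#' @export
render_centreline_map <- function(cov_map, segments = NULL, skeleton = NULL,
                                  mode = c("global_cap", "category_percentile"),
                                  cap_value = 50, summaries = NULL, path = NULL) {
  mode <- match.arg(mode)
  if (!any(cov_map$valid)) stop_octa("cannot render an all-invalid CoV map")
  if (mode == "global_cap") {
    clamp <- c(0, cap_value)
  } else {
    if (is.null(summaries)) stop_octa("category_percentile mode needs ROI summaries")
    clamp <- c(min(summaries$q1_mean_cov, na.rm = TRUE),
               max(summaries$q3_mean_cov, na.rm = TRUE))
  }
  if (!all(is.finite(clamp)) || clamp[1] >= clamp[2])
    stop_octa("invalid clamp range [%g, %g]", clamp[1], clamp[2])
  h <- nrow(cov_map$values); w <- ncol(cov_map$values)
  val <- matrix(NA_real_, h, w)
  if (!is.null(segments)) {
    for (s in segments) if (!isTRUE(s$excluded)) val[s$path] <- s$mean_cov
  } else if (!is.null(skeleton)) {
    val[skeleton$mask] <- cov_map$values[skeleton$mask]
  } else stop_octa("provide segments or a skeleton to render")
  pal <- cov_colormap(256)
  idx <- pmin(pmax(round((val - clamp[1]) / (clamp[2] - clamp[1]) * 255) + 1, 1), 256)
  rgb_arr <- array(0, dim = c(h, w, 3))
  on_px <- which(is.finite(val))
  if (length(on_px)) {
    co <- grDevices::col2rgb(pal[idx[on_px]]) / 255
    for (ch in 1:3) {
      plane <- matrix(0, h, w)
      plane[on_px] <- co[ch, ]
      rgb_arr[, , ch] <- plane
    }
  }
  if (!is.null(path)) png::writePNG(rgb_arr, path)
  invisible(list(rgb = rgb_arr, clamp = clamp, colormap = "darkblue-red-256"))
}

#' Comparative box plots of vessel-segment mean CoV
#'
#' Draws one box per group (ROI or category) annotated with its sample
#' size, and always exports the underlying statistics — n, median,
#' quartiles (linear-interpolation rule), whiskers — as a data.frame/CSV so
#' the figure and the numbers share a single source. Empty groups are
#' omitted with a warning.
#'
#' @param values named list of numeric vectors (one per group).
#' @param path optional PNG path for the figure.
#' @param csv_path optional CSV path for the statistics.
#' @param ylab axis label.
#' @return data.frame of per-group statistics.
#' @export
render_boxplots <- function(values, path = NULL, csv_path = NULL,
                            ylab = "Vessel-segment mean CoV (%)") {
  keep <- vapply(values, function(v) sum(is.finite(v)) > 0, TRUE)
  if (any(!keep)) warn_octa("omitting empty group(s): %s",
                            paste(names(values)[!keep], collapse = ", "))
  values <- lapply(values[keep], function(v) v[is.finite(v)])
  if (!length(values)) stop_octa("no non-empty groups to plot")
  stats_df <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    q <- q7(v, c(0.25, 0.5, 0.75))
    iqr <- q[3] - q[1]
    data.frame(group = nm, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  if (!is.null(csv_path)) write.csv(stats_df, csv_path, row.names = FALSE)
  if (!is.null(path)) {
    grDevices::png(path, width = 180 * length(values) + 120, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    boxplot(values, ylab = ylab, col = "lightsteelblue", las = 2)
    text(seq_along(values), stats_df$median, labels = stats_df$n, pos = 1, cex = 0.9)
  }
  stats_df
}
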