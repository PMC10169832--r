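# Repeated-measures statistics for the seven ROI categories: Mauchly's
# sphericity test, Greenhouse-Geisser / Huynh-Feldt epsilon, one-way
# within-subject ANOVA with generalized eta-squared, and Bonferroni
# post-hoc paired comparisons. All quantities are computed from their
# definitions; mainstream implementations (car, base mauchly.test) serve
# as independent cross-checks in the test suite only.

#' Pool per-subject segment values into a subjects x categories table
#'
#' For each subject, the vessel-segment mean CoV values of all ROIs of a
#' category are pooled and reduced to a single per-cell statistic: the
#' median (temporal variation) or the IQR (spatial variation).
#'
#' @param subject_assignments list with one element per subject, each the
#'   [assign_segments()] data.frame of that subject.
#' @param measure `"median"` or `"IQR"`.
#' @return matrix of class `subject_category_table` (n subjects x 7
#'   categories, `measure` attribute set). A subject missing a category is
#'   an error naming the subject.
#' @export
pool_categories <- function(subject_assignments, measure = c("median", "IQR")) {
  measure <- match.arg(measure)
  cats <- roi_categories()
  n <- length(subject_assignments)
  if (!n) stop_octa("no subjects")
  ids <- names(subject_assignments) %||% paste0("S", seq_len(n))
  if (is.null(names(subject_assignments))) names(subject_assignments) <- ids
  tab <- matrix(NA_real_, n, length(cats), dimnames = list(ids, cats))
  for (i in seq_len(n)) {
    a <- subject_assignments[[i]]
    for (j in seq_along(cats)) {
      if (!cats[j] %in% names(a))
        stop_octa("subject %s lacks category '%s'", ids[i], cats[j])
      v <- a$mean_cov[!is.na(a[[cats[j]]])]
      if (!length(v))
        stop_octa("subject %s has no segments in category '%s'", ids[i], cats[j])
      tab[i, j] <- if (measure == "median") median(v) else iqr7(v)
    }
  }
  structure(tab, measure = measure, class = c("subject_category_table", "matrix", "array"))
}

#' Read/write a subject x category table as CSV
#'
#' Rows are subjects, columns the seven category names as printed.
#'
#' @param tab a `subject_category_table` (or plain matrix with the 7
#'   category columns).
#' @param path CSV path.
#' @param measure measure label to attach when reading.
#' @return the table (invisibly for the writer).
#' @export
write_category_table <- function(tab, path) {
  df <- data.frame(subject = rownames(tab) %||% paste0("S", seq_len(nrow(tab))),
                   as.data.frame(unclass(tab), check.names = FALSE), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_category_table
#' @export
read_category_table <- function(path, measure = "median") {
  df <- read.csv(path, check.names = FALSE)
  cats <- roi_categories()
  if (!all(cats %in% names(df)))
    stop_octa("CSV must have the columns: %s", paste(cats, collapse = ", "))
  m <- as.matrix(df[, cats])
  rownames(m) <- if ("subject" %in% names(df)) df$subject else paste0("S", seq_len(nrow(m)))
  structure(m, measure = measure, class = c("subject_category_table", "matrix", "array"))
}

#' Shapiro-Wilk normality check per category
#'
#' @param tab subjects x categories matrix (3 <= n <= 50 subjects).
#' @return data.frame with `category`, `W`, `p`, `degenerate` (constant
#'   samples are flagged rather than tested).
#' @export
shapiro_by_category <- function(tab) {
  n <- nrow(tab)
  if (n < 3 || n > 50) stop_octa("Shapiro-Wilk requires 3 <= n <= 50, got n = %d", n)
  do.call(rbind, lapply(colnames(tab) %||% seq_len(ncol(tab)), function(j) {
    x <- tab[, j]
    if (sd(x) == 0)
      return(data.frame(category = as.character(j), W = NA_real_, p = NA_real_, degenerate = TRUE))
    s <- shapiro.test(x)
    data.frame(category = as.character(j), W = unname(s$statistic), p = s$p.value, degenerate = FALSE)
  }))
}

# Orthonormal contrast matrix spanning the space orthogonal to the grand
# mean (normalized Helmert contrasts), k x (k-1).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  apply(C, 2, function(v) v / sqrt(sum(v^2)))
}

# Covariance of the orthonormalized within-subject contrasts.
contrast_covariance <- function(tab) {
  k <- ncol(tab)
  C <- orthonormal_contrasts(k)
  t(C) %*% cov(tab) %*% C
}

#' Mauchly's test of sphericity
#'
#' W is the ratio of the determinant of the contrast covariance to the
#' determinant under sphericity; the p-value uses the standard chi-square
#' approximation. With k = 2 conditions sphericity is trivial (W = 1).
#'
#' @param tab subjects x categories matrix; needs n >= k subjects for a
#'   nonsingular contrast covariance.
#' @return list with `W`, `p`, `df`.
#' @export
mauchly_test <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  if (k < 2) stop_octa("need at least 2 conditions")
  if (k == 2) return(list(W = 1, p = 1, df = 0))
  if (n < k) stop_octa("Mauchly's test needs n >= k subjects (n = %d, k = %d)", n, k)
  S <- contrast_covariance(tab)
  dtm <- det(S)
  if (!is.finite(dtm) || dtm <= 0)
    stop_octa("contrast covariance is singular; Mauchly's W undefined")
  d <- k - 1
  W <- dtm / (sum(diag(S)) / d)^d
  df <- d * (d + 1) / 2 - 1
  # Box's chi-square approximation with the second-order correction term
  nn <- n - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nn)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * k + 2) /
    (288 * (nn * d * rho)^2)
  z <- -nn * rho * log(W)
  p1 <- pchisq(z, df, lower.tail = FALSE)
  p2 <- pchisq(z, df + 4, lower.tail = FALSE)
  list(W = W, p = p1 + w2 * (p2 - p1), df = df)
}

#' Sphericity correction factors
#'
#' Greenhouse-Geisser epsilon from the contrast covariance, and its
#' Huynh-Feldt correction `((n (k-1) e - 2) / ((k-1) (n - 1 - (k-1) e)))`
#' capped at 1 — the convention of the mainstream repeated-measures ANOVA
#' implementations. The lower bound of epsilon is `1/(k-1)`.
#'
#' @param tab subjects x categories matrix.
#' @return list with `gg`, `hf` (uncapped), `hf_capped`, `lower_bound`.
#' @export
epsilons <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  S <- contrast_covariance(tab)
  d <- k - 1
  gg <- sum(diag(S))^2 / (d * sum(S^2))
  hf <- (n * d * gg - 2) / (d * (n - 1 - d * gg))
  list(gg = gg, hf = hf, hf_capped = min(hf, 1), lower_bound = 1 / d)
}

#' @rdname epsilons
#' @export
huynh_feldt_epsilon <- function(tab) epsilons(tab)$hf_capped

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of the subjects x categories table:
#' `SS_total = SS_subjects + SS_effect + SS_error`, `F = MS_effect /
#' MS_error` on `(k-1, (n-1)(k-1))` degrees of freedom, generalized
#' eta-squared `SS_effect / (SS_effect + SS_subjects + SS_error)`. Mauchly's
#' test is run and, when it rejects sphericity at `sphericity_alpha`, the
#' reported degrees of freedom and p-value are Huynh-Feldt corrected (both
#' corrected and uncorrected values are always returned).
#'
#' @param tab a `subject_category_table` or plain matrix (n >= 2 subjects,
#'   k >= 2 categories, no missing cells).
#' @param sphericity_alpha level of the sphericity gate (default 0.05).
#' @return object of class `rm_anova`.
#' @export
rm_anova <- function(tab, sphericity_alpha = 0.05) {
  tab <- as.matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2 || k < 2) stop_octa("need n >= 2 subjects and k >= 2 categories")
  if (any(!is.finite(tab))) stop_octa("table has missing cells")
  gm <- mean(tab)
  row_m <- rowMeans(tab); col_m <- colMeans(tab)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_eff <- n * sum((col_m - gm)^2)
  ss_tot <- sum((tab - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_eff
  df_eff <- k - 1
  df_err <- (n - 1) * (k - 1)
  F <- if (ss_eff <= 1e-300) 0 else (ss_eff / df_eff) / (ss_err / df_err)
  ges <- ss_eff / (ss_eff + ss_subj + ss_err)
  mau <- if (k >= 3 && n >= k) {
    tryCatch(mauchly_test(tab), error = function(e) list(W = NA, p = NA, df = NA))
  } else list(W = NA, p = NA, df = NA)
  eps <- epsilons(tab)
  corrected <- is.finite(mau$p) && mau$p < sphericity_alpha
  e <- if (corrected) eps$hf_capped else 1
  structure(list(
    F = F, df_effect = df_eff, df_error = df_err,
    df_effect_corr = e * df_eff, df_error_corr = e * df_err,
    p_uncorrected = stats::pf(F, df_eff, df_err, lower.tail = FALSE),
    p_corrected = stats::pf(F, e * df_eff, e * df_err, lower.tail = FALSE),
    epsilon_gg = eps$gg, epsilon_hf = eps$hf_capped,
    mauchly_W = mau$W, mauchly_p = mau$p,
    sphericity_corrected = corrected, ges = ges,
    ss = c(effect = ss_eff, subjects = ss_subj, error = ss_err, total = ss_tot),
    n = n, k = k, measure = attr(tab, "measure")
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 2, ...) {
  cat(sprintf("One-way repeated-measures ANOVA (%d subjects x %d categories%s)\n",
              x$n, x$k, if (!is.null(x$measure)) paste0(", measure = ", x$measure) else ""))
  if (is.finite(x$mauchly_p))
    cat(sprintf("  Mauchly's W = %.3f, p = %.4g%s\n", x$mauchly_W, x$mauchly_p,
                if (x$sphericity_corrected) " (sphericity violated; Huynh-Feldt correction applied)" else ""))
  cat(sprintf("  Huynh-Feldt epsilon = %.*f (Greenhouse-Geisser %.*f)\n",
              digits, x$epsilon_hf, digits, x$epsilon_gg))
  cat(sprintf("  F(%.*f, %.*f) = %.*f, p = %.3g, generalized eta^2 = %.*f\n",
              digits, x$df_effect_corr, digits, x$df_error_corr, digits, x$F,
              x$p_corrected, digits, x$ges))
  invisible(x)
}

#' Bonferroni-corrected post-hoc paired comparisons
#'
#' All `k(k-1)/2` paired t-tests between categories. Adjusted p-values are
#' `min(1, m p)`; confidence intervals are computed at the per-comparison
#' level `1 - alpha/m` so that interval coverage is consistent with the
#' same Bonferroni correction. Pairs with a zero-variance difference vector
#' are flagged (`degenerate`) rather than tested.
#'
#' @param tab subjects x categories matrix.
#' @param alpha family significance level (default 0.05).
#' @return data.frame of class `posthoc_pairwise`: one row per pair with
#'   `cat1`, `cat2`, `estimate` (mean paired difference), `ci_lo`, `ci_hi`,
#'   `p`, `p_adj`, `degenerate`.
#' @export
posthoc_pairwise <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  k <- ncol(tab)
  cats <- colnames(tab) %||% paste0("C", seq_len(k))
  m <- k * (k - 1) / 2
  conf <- 1 - alpha / m
  pairs <- combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    d <- tab[, i] - tab[, j]
    if (sd(d) == 0) {
      return(data.frame(cat1 = cats[i], cat2 = cats[j], estimate = mean(d),
                        ci_lo = mean(d), ci_hi = mean(d), p = NA_real_,
                        p_adj = NA_real_, degenerate = TRUE))
    }
    tt <- t.test(d, conf.level = conf)
    data.frame(cat1 = cats[i], cat2 = cats[j], estimate = unname(tt$estimate),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p = tt$p.value, p_adj = min(1, m * tt$p.value), degenerate = FALSE)
  }))
  attr(out, "m") <- m
  attr(out, "conf_level") <- conf
  class(out) <- c("posthoc_pairwise", "data.frame")
  out
}

#' Lower-triangular p-value matrix of a post-hoc battery
#'
#' @param ph a [posthoc_pairwise()] result.
#' @param digits rounding for display (2 mirrors the printed tables;
#'   `NULL` keeps full precision).
#' @return matrix with categories 2..k as rows and 1..(k-1) as columns.
#' @export
pairwise_matrix <- function(ph, digits = 2) {
  cats <- unique(c(ph$cat1, ph$cat2))
  k <- length(cats)
  m <- matrix(NA_real_, k - 1, k - 1, dimnames = list(cats[-1], cats[-k]))
  for (q in seq_len(nrow(ph))) {
    m[ph$cat2[q], ph$cat1[q]] <- if (is.null(digits)) ph$p_adj[q] else round(ph$p_adj[q], digits)
  }
  m
}
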