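# Influence zones, quadrants, F-cp band, segment assignment, summaries.

point_mask <- function(shape, r, c) {
  m <- matrix(FALSE, shape[1], shape[2]); m[cbind(r, c)] <- TRUE; m
}

test_that("influence zones match exhaustive nearest-seed brute force", {
  for (seed in 1:6) {
    set.seed(seed)
    n_seed <- sample(2:4, 1)
    pts <- cbind(sample(50, n_seed), sample(50, n_seed))
    seeds <- lapply(seq_len(n_seed), function(i) point_mask(c(50, 50), pts[i, 1], pts[i, 2]))
    names(seeds) <- paste0("s", seq_len(n_seed))
    lab <- influence_zones(seeds)
    # brute force with the same tie rule (strictly smaller distance wins)
    bf <- matrix(0L, 50, 50)
    for (r in 1:50) for (c in 1:50) {
      if (any(pts[, 1] == r & pts[, 2] == c)) next
      d2 <- (r - pts[, 1])^2 + (c - pts[, 2])^2
      bf[r, c] <- which.min(d2)          # which.min takes the lowest index on ties
    }
    expect_identical(unname(lab[bf > 0]), bf[bf > 0])
  }
})

test_that("influence zones: symmetric column seeds split the domain in half", {
  sA <- matrix(FALSE, 10, 10); sA[, 1] <- TRUE
  sB <- matrix(FALSE, 10, 10); sB[, 10] <- TRUE
  lab <- influence_zones(list(A = sA, B = sB))
  expect_true(all(lab[, 2:5] == 1L))
  expect_true(all(lab[, 6:9] == 2L))
})

test_that("influence zones: single seed takes the whole domain; empty seed errors", {
  s <- point_mask(c(8, 8), 4, 4)
  lab <- influence_zones(list(only = s))
  expect_true(all(lab[!s] == 1L))
  expect_error(influence_zones(list(a = s, b = matrix(FALSE, 8, 8))), "empty")
  expect_error(influence_zones(list(a = s), domain = matrix(TRUE, 8, 8)), "exclude")
})

test_that("influence-zone masks partition the capillary domain", {
  rs <- small_phantom()$roi_truth
  nets <- rs$nets
  tot <- Reduce(`+`, lapply(nets, function(m) m * 1L))
  expect_lte(max(tot), 1L)                                  # pairwise disjoint
  seeds <- Reduce(`|`, c(rs$arterioles, rs$venules, list(rs$faz)))
  expect_true(all((tot == 1L) == !seeds))                   # zones cover the domain
  # a net never intersects its own or any other major vessel, F-net not the FAZ
  for (nm in names(nets)) expect_equal(sum(nets[[nm]] & seeds), 0L)
})

test_that("roi_set validates disjointness and emptiness", {
  a <- point_mask(c(10, 10), 2, 2)
  v <- point_mask(c(10, 10), 8, 8)
  faz <- point_mask(c(10, 10), 5, 5)
  expect_s3_class(roi_set(list(a), list(v), faz), "roi_set")
  expect_error(roi_set(list(a), list(a), faz), "overlap")
  expect_error(roi_set(list(a), list(v), a), "overlap")
  expect_error(roi_set(list(a, matrix(FALSE, 10, 10)), list(v), faz), "empty")
  rs <- roi_set(list(a), list(v), faz)        # no foveola centre
  expect_error(add_quadrants(rs), "foveola")
})

test_that("quadrants split evenly, respect exclusions and partition the field", {
  q <- quadrant_rois(c(20, 20), c(10.5, 10.5))
  areas <- vapply(q, sum, 0L)
  expect_true(all(areas == 100L))
  tot <- Reduce(`+`, lapply(q, function(m) m * 1L))
  expect_true(all(tot == 1L))                               # exact partition

  ex <- point_mask(c(20, 20), 3, 15)
  q2 <- quadrant_rois(c(20, 20), c(10.5, 10.5), exclusions = list(ex))
  expect_equal(sum(q2$Q1 & ex), 0L)
  tot2 <- Reduce(`+`, lapply(q2, function(m) m * 1L)) + ex
  expect_true(all(tot2 == 1L))                              # quadrants + exclusions

  expect_error(quadrant_rois(c(20, 20), c(30, 5)), "outside")
})

test_that("F-cp band is an annulus hugging the FAZ boundary", {
  rs <- small_phantom()$roi_truth
  expect_equal(sum(rs$fcp & rs$faz), 0L)
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!rs$faz), rs$shape[1], rs$shape[2])))
  expect_true(all(d[rs$fcp] <= 6))
  expect_true(all(d[rs$fcp] > 0))
})

test_that("segments are assigned by majority with midpoint tie-break", {
  # two nets split at column 10; three hand-built segments
  rs <- small_phantom()$roi_truth
  h <- rs$shape[1]
  net1 <- matrix(FALSE, h, h); net1[, 1:10] <- TRUE
  net2 <- matrix(FALSE, h, h); net2[, 11:20] <- TRUE
  rs2 <- rs
  rs2$nets <- list("a1-net" = net1, "v1-net" = net2)
  rs2$quadrants <- list(Q1 = net1, Q2 = net2)      # a two-ROI category for ties
  rs2$fcp <- net2
  mkseg <- function(id, cols) list(id = id, path = cbind(5L, as.integer(cols)),
                                   length = length(cols), n_valid = length(cols),
                                   mean_cov = 10, excluded = FALSE)
  segs <- structure(list(mkseg(1L, 1:10),          # fully inside a1-net
                         mkseg(2L, 6:15),          # 50/50 within-category tie
                         mkseg(3L, 7:16)),         # 40/60 majority
                    class = "vessel_segments")
  asg <- assign_segments(segs, rs2)
  expect_equal(asg[["Arteriole-net"]], c("a1-net", "a1-net", NA))
  expect_equal(asg[["Venule-net"]], c(NA, "v1-net", "v1-net"))
  # tie in the Quadrant category: midpoint (5th of 10 px, col 10) lies in Q1
  expect_equal(asg[["Quadrant"]], c("Q1", "Q1", "Q2"))
  # determinism of the tie-break
  expect_identical(asg, assign_segments(segs, rs2))
})

test_that("ROI summaries use the linear-interpolation quartile rule", {
  asg <- data.frame(id = 1:4, mean_cov = c(10, 20, 30, 40),
                    "Quadrant" = c("Q1", "Q1", "Q1", "Q1"), check.names = FALSE)
  s <- summarize_roi(asg)
  expect_equal(s$median_mean_cov, 25)
  expect_equal(s$iqr_mean_cov, 15)                  # Q3 32.5 - Q1 17.5
  expect_equal(s$n_segments, 4L)

  one <- summarize_roi(data.frame(id = 1L, mean_cov = 12.5,
                                  "FAZ-cp" = "F-cp", check.names = FALSE))
  expect_equal(one$median_mean_cov, 12.5)
  expect_equal(one$iqr_mean_cov, 0)
})

test_that("net medians sit near twice the vessel medians on the phantom", {
  s <- small_subject()$summaries
  med <- function(cat) median(s$median_mean_cov[s$category == cat], na.rm = TRUE)
  ratio <- med("Arteriole-net") / med("Arteriole")
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("mask files round-trip through load_roi_masks with validation", {
  td <- withr::local_tempdir()
  a <- point_mask(c(16, 16), 3, 3); v <- point_mask(c(16, 16), 12, 12)
  faz <- point_mask(c(16, 16), 8, 8)
  fa <- file.path(td, "a1.png"); fv <- file.path(td, "v1.png"); ff <- file.path(td, "faz.png")
  png::writePNG(a * 1, fa); png::writePNG(v * 1, fv); png::writePNG(faz * 1, ff)
  rs <- load_roi_masks(fa, fv, ff)
  expect_equal(sum(rs$arterioles$a1), 1L)
  # overlapping masks rejected
  png::writePNG(a * 1, fv)
  expect_error(load_roi_masks(fa, fv, ff), "overlap")
})
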