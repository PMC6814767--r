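test_that("stack projection matches the elementwise maximum", {
  img <- matrix(runif(100), 10, 10)
  stack1 <- array(img, dim = c(1, 10, 10))
  expect_equal(project_stack(stack1), img)
  # two planes with disjoint bright disks both survive projection
  a <- draw_disk(matrix(0, 30, 30), 10, 10, 4, 5)
  b <- draw_disk(matrix(0, 30, 30), 20, 20, 4, 7)
  st <- array(0, dim = c(2, 30, 30)); st[1, , ] <- a; st[2, , ] <- b
  proj <- project_stack(st)
  expect_equal(proj[10, 10], 5)
  expect_equal(proj[20, 20], 7)
  # exact elementwise oracle on random stacks
  set.seed(3)
  st <- array(rnorm(4 * 12 * 12), dim = c(4, 12, 12))
  expect_equal(project_stack(st), apply(st, c(2, 3), max))
  expect_error(project_stack(array(0, c(0, 4, 4))), "empty")
  # focus-weighted mode returns an image of the right shape
  expect_equal(dim(project_stack(st, "focus")), c(12L, 12L))
})

test_that("nucleus segmentation counts planted disks", {
  blank <- matrix(0, 64, 64)
  m <- segment_nuclei(blank)
  expect_equal(max(m$labels), 0L)
  expect_equal(nrow(m$table), 0L)
  # 12 non-touching disks -> 12 labels
  img <- matrix(0, 200, 200)
  centers <- expand.grid(r = c(30, 80, 130, 180), c = c(40, 100, 160))
  for (i in seq_len(nrow(centers))) {
    img <- draw_disk(img, centers$r[i], centers$c[i], 10, 1000)
  }
  m <- segment_nuclei(img)
  expect_equal(max(m$labels), 12L)
  expect_true(all(m$table$area > 250))
  # two overlapping disks with distinct centers are split into 2
  img <- draw_disk(matrix(0, 80, 80), 40, 30, 12, 1000)
  img <- draw_disk(img, 40, 48, 12, 1000)
  m <- segment_nuclei(img)
  expect_equal(max(m$labels), 2L)
})

test_that("nuclear intensities are mask means", {
  img <- draw_disk(matrix(0, 60, 60), 30, 30, 10, 1000)
  m <- segment_nuclei(img)
  # uniform reporter -> mean equals the value
  rep1 <- matrix(7.5, 60, 60)
  q <- quantify_nuclei(m, rep1)
  expect_equal(q$intensity, 7.5)
  # half at 0, half at 2v (checkerboard) -> mean v
  rep2 <- matrix(0, 60, 60)
  rep2[(row(rep2) + col(rep2)) %% 2L == 0L] <- 24
  rep2[m$labels == 0L] <- 99  # background value must not matter
  q <- quantify_nuclei(m, rep2)
  expect_equal(q$intensity, 12, tolerance = 0.02)  # digital-disk parity
  expect_error(quantify_nuclei(m, matrix(0, 10, 10)), "shapes")
})

test_that("droplet detection separates spots from streaks", {
  nuc <- draw_disk(matrix(0, 80, 80), 40, 40, 25, 1000)
  m <- segment_nuclei(nuc)
  # uniform nucleus: no droplets
  rep0 <- draw_disk(matrix(2, 80, 80), 40, 40, 25, 100)
  expect_equal(nrow(detect_droplets(rep0, m)), 0L)
  # three planted spots at 5x the dilute level
  rep1 <- rep0
  for (p in list(c(30, 40), c(50, 30), c(50, 52))) {
    rep1 <- draw_disk(rep1, p[1], p[2], 3, 500)
  }
  d <- detect_droplets(rep1, m)
  expect_equal(nrow(d), 3L)
  expect_true(all(d$circularity > 0.9))
  expect_equal(sort(round(d$row)), c(30, 50, 50))
  # an elongated streak is rejected by the circularity filter
  rep2 <- rep0
  rep2[40, 30:50] <- 500
  expect_equal(nrow(detect_droplets(rep2, m)), 0L)
})

test_that("classification splits Cond/Diff/Untransfected with bookkeeping", {
  rec <- data.frame(intensity = c(1, 2, 150, 300, 400, 500),
                    n_droplets = c(0L, 0L, 0L, 2L, 0L, 1L))
  control <- rlnorm(400, log(3), 0.3)
  out <- classify_and_filter(rec, control)
  s <- attr(out, "summary")
  expect_equal(out$class[1:2], c("Untransfected", "Untransfected"))
  expect_equal(s$n_cond, 2L)
  expect_equal(s$n_diff, 2L)
  expect_equal(s$pct_cond + s$pct_diff, 100)
  # all intensities below cutoff -> everything untransfected
  low <- classify_and_filter(data.frame(intensity = c(1, 2),
                                        n_droplets = c(0L, 0L)), control)
  expect_true(all(low$class == "Untransfected"))
  expect_error(classify_and_filter(rec, numeric(0)), "empty")
})

test_that("C_sat estimation recovers a separable boundary and flags degeneracy", {
  # perfectly separable population: estimate converges to the boundary
  rec <- data.frame(intensity = c(seq(10, 99, length.out = 200),
                                  seq(101, 400, length.out = 200)),
                    class = rep(c("Diff", "Cond"), each = 200))
  est <- estimate_csat(rec)
  expect_false(est$degenerate)
  expect_equal(est$csat, 100, tolerance = 0.05)
  # single-class population is degenerate, not an error
  rec$class <- "Diff"
  est <- estimate_csat(rec)
  expect_true(est$degenerate)
  expect_true(is.na(est$csat))
  expect_error(estimate_csat(rec[1:10, ]), "at least")
})

test_that("concentration calibration inverts exactly and checks inputs", {
  std <- data.frame(concentration = c(1, 2, 5, 10),
                    intensity = c(10, 20, 50, 100))
  cal <- calibrate_concentration(std)
  expect_equal(cal$slope, 10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(convert_to_concentration(cal, 33), 3.3)
  # round trip on the standards themselves
  expect_equal(convert_to_concentration(cal, std$intensity),
               std$concentration)
  # noisy standards recover the slope within 5%
  set.seed(5)
  noisy <- data.frame(concentration = rep(c(1, 2, 5, 10), each = 5))
  noisy$intensity <- 10 * noisy$concentration + rnorm(20, 0, 1)
  expect_equal(calibrate_concentration(noisy)$slope, 10, tolerance = 0.05)
  expect_error(calibrate_concentration(std[1, ]), "two")
  expect_error(calibrate_concentration(
    data.frame(concentration = 1:3, intensity = c(5, 5, 5))), "identical")
  expect_warning(convert_to_concentration(cal, -5), "clipped")
})

test_that("onset detection honours persistence and group tests work", {
  expect_equal(detect_onset(c(1, 1, 2, 3))$onset, 0)
  expect_equal(detect_onset(c(0, 0, 1, 0, 1, 1, 2))$onset, 4)
  expect_equal(detect_onset(c(0, 0, 1, 0, 1, 1, 2))$initial_foci, 1L)
  expect_true(is.na(detect_onset(c(0, 0, 1, 0))$onset))
  # identical groups give t ~ 0, p ~ 1
  g <- c(3, 4, 5, 6, 7)
  cmp <- compare_groups(g, g)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  cmp <- compare_groups(c(g, NA), g)
  expect_equal(cmp$n_excluded, 1L)
})
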