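toy_events <- function(n = 100, bfp = 5000, gfp = 2000, mch = 1000) {
  data.frame(FSC_A = rep(5e4, n), FSC_H = rep(4.75e4, n),
             SSC_A = rep(3e4, n), BFP = rep(bfp, n), GFP = rep(gfp, n),
             mCherry = rep(mch, n))
}

test_that("compensation inverts the spillover exactly", {
  ev <- toy_events(10)
  m <- default_spillover()
  # identity spillover is a no-op
  ident <- diag(3)
  dimnames(ident) <- list(c("BFP", "GFP", "mCherry"),
                          c("BFP", "GFP", "mCherry"))
  expect_equal(compensate(ev, ident), ev)
  # applying spillover then compensating returns originals
  obs <- ev
  obs[, c("BFP", "GFP", "mCherry")] <-
    as.matrix(ev[, c("BFP", "GFP", "mCherry")]) %*% m
  back <- compensate(obs, m)
  expect_equal(back, ev, tolerance = 1e-10)
  # matrix round trip is numerically identity
  expect_equal(m %*% solve(m), diag(3), ignore_attr = TRUE,
               tolerance = 1e-12)
  sing <- m; sing["GFP", ] <- sing["BFP", ]
  expect_error(compensate(ev, sing), "singular|unit diagonal")
})

test_that("compensation zeroes the mCherry of GFP-only cells", {
  set.seed(4)
  n <- 2000
  gfp <- rlnorm(n, log(2000), 0.5)
  m <- default_spillover(gfp_mcherry = 0.1)
  true_mat <- cbind(BFP = rep(0, n), GFP = gfp, mCherry = rep(0, n))
  obs <- as.data.frame(true_mat %*% m)
  obs$FSC_A <- 5e4; obs$FSC_H <- 4.75e4; obs$SSC_A <- 3e4
  # before compensation there is apparent mCherry signal
  expect_gt(median(obs$mCherry), 100)
  comp <- compensate(obs, m)
  expect_lt(max(abs(comp$mCherry)), 1e-9)
})

test_that("gating is sequential with conserved counts", {
  g <- gen_flow(n_events = 5000, seed = 6)
  ev <- g$events$WT
  res <- gate(ev)
  expect_equal(res$report$n_in[1], nrow(ev))
  # conservation: input n = gated n + sum of losses
  expect_equal(nrow(res$events) + sum(res$report$n_lost), nrow(ev))
  # chained bookkeeping between gates
  expect_equal(res$report$n_kept[1], res$report$n_in[2])
  # everything below the BFP threshold gates to zero with a warning
  dim_ev <- toy_events(50, bfp = 10)
  expect_warning(res0 <- gate(dim_ev), "no events")
  expect_equal(nrow(res0$events), 0L)
  expect_equal(res0$report$n_lost[res0$report$gate == "bfp_positive"], 50L)
})

test_that("the programmed BFP-positive fraction survives gating", {
  g <- gen_flow(n_events = 20000, transfected_frac = 0.7, seed = 7)
  lab <- g$truth$labels$WT
  ev <- g$events$WT
  # threshold far below transfected expression so the BFP gate separates
  # the programmed populations cleanly
  res <- gate(compensate(ev, g$spillover), gating_config(bfp_min = 300))
  cells <- lab$kind == "cell"
  frac <- nrow(res$events) / sum(cells)
  expect_equal(frac, 0.7, tolerance = 0.03)
})

test_that("splicing ratios guard the GFP floor", {
  ev <- toy_events(5, gfp = 1000, mch = 1000)
  r <- splicing_ratio(ev, gfp_floor = 10)
  expect_equal(r$ratio, rep(1, 5))
  expect_equal(attr(r, "n_excluded"), 0L)
  ev$GFP[3] <- 0
  r <- splicing_ratio(ev, gfp_floor = 10)
  expect_equal(nrow(r), 4L)
  expect_equal(attr(r, "n_excluded"), 1L)
})

test_that("a linear reporter yields the programmed median ratio", {
  set.seed(9)
  n <- 5000
  gfp <- rlnorm(n, log(3000), 0.4)
  ev <- data.frame(FSC_A = 5e4, FSC_H = 4.75e4, SSC_A = 3e4,
                   BFP = rlnorm(n, log(5000), 0.5), GFP = gfp,
                   mCherry = 0.6 * gfp * rlnorm(n, 0, 0.1))
  r <- splicing_ratio(ev)
  expect_equal(median(r$ratio), 0.6, tolerance = 0.02)
})

test_that("binned summaries track a saturating dose-response", {
  g <- gen_flow(variants = list(WT = list(r_max = 0.6, K = 2000,
                                          baseline = 0.05)),
                n_events = 40000, seed = 10)
  ev <- splicing_ratio(gate(compensate(g$events$WT, g$spillover)))
  s <- bin_and_summarize(ev, n_bins = 12)
  expect_equal(sum(s$bins$n), nrow(ev))
  expect_error(bin_and_summarize(ev, n_bins = 1), "at least 2")
  occ <- s$bins[s$bins$n >= 200, ]
  # medians rise towards the plateau: first occupied bin well below last
  expect_gt(tail(occ$median, 1), head(occ$median, 1))
  # converging set-point: ratio IQR shrinks at high expression
  expect_lt(tail(occ$iqr, 1), max(occ$iqr))
  top <- tail(occ, 3)
  expect_true(all(diff(top$iqr) < 0))
})

test_that("window comparison ranks variants and flags empty windows", {
  set.seed(12)
  mk <- function(r, n = 3000) {
    data.frame(BFP = rlnorm(n, log(5000), 0.3),
               ratio = r * rlnorm(n, 0, 0.2))
  }
  wc <- window_compare(list(WT = mk(0.6), weak = mk(0.3)),
                       window = c(2000, 20000))
  expect_equal(wc$ranking, c("WT", "weak"))
  expect_lt(wc$pairwise["WT", "weak"], 0.001)
  # identical variants: medians agree within resampling noise
  wc0 <- window_compare(list(a = mk(0.5), b = mk(0.5)),
                        window = c(2000, 20000))
  expect_equal(wc0$table$median[1], wc0$table$median[2], tolerance = 0.05)
  # a variant with no cells in the window is excluded and flagged
  far <- data.frame(BFP = rep(100, 50), ratio = rep(1, 50))
  wc1 <- window_compare(list(WT = mk(0.6), far = far),
                        window = c(2000, 20000))
  expect_equal(wc1$excluded, "far")
  expect_error(window_compare(list(far = far), c(2000, 20000)), "empty")
})
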