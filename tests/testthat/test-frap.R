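make_trace <- function(ratio_post, i_pre = 1, n_pre = 3, dt = 1,
                       unb = 100) {
  n <- n_pre + length(ratio_post)
  frap_trace(time = seq_len(n) * dt,
             bleached = c(rep(i_pre, n_pre), ratio_post) * unb,
             unbleached = rep(unb, n),
             prebleach = c(rep(TRUE, n_pre), rep(FALSE, length(ratio_post))))
}

test_that("half-bleach normalization follows the standard convention", {
  # constant post-bleach ratio: FR identically zero
  cv <- normalize_halfbleach(make_trace(rep(0.4, 10)))
  expect_equal(cv$fr, rep(0, 10))
  expect_equal(cv$time[1], 0)
  # ratio returning to pre-bleach level: FR reaches exactly 1
  cv <- normalize_halfbleach(make_trace(c(0.4, 0.7, 1.0)))
  expect_equal(cv$fr[3], 1)
  # synthetic exponential gives FR(t) = A(1 - exp(-kt)) exactly
  k <- 0.15; A <- 1; t <- 0:29
  ratio <- 0.4 + (1 - 0.4) * A * (1 - exp(-k * t))
  cv <- normalize_halfbleach(make_trace(ratio))
  expect_equal(cv$fr, A * (1 - exp(-k * cv$time)), tolerance = 1e-12)
})

test_that("degenerate bleaches and bad traces are rejected", {
  expect_error(normalize_halfbleach(make_trace(rep(1.2, 5))), "degenerate")
  expect_error(frap_trace(c(1, 1, 2), 1:3, rep(1, 3),
                          c(TRUE, FALSE, FALSE)), "increasing")
  expect_error(frap_trace(1:3, 1:3, c(1, 0, 1), c(TRUE, FALSE, FALSE)),
               "positive")
  expect_error(frap_trace(1:3, 1:3, rep(1, 3), rep(TRUE, 3)), "post-bleach")
})

test_that("normalization is invariant under uniform gain rescaling", {
  ratio <- 0.4 + 0.6 * 0.8 * (1 - exp(-0.1 * (0:19)))
  tr1 <- make_trace(ratio, unb = 100)
  tr2 <- make_trace(ratio, unb = 100)
  g <- 3.7  # same optical gain on both hemispheres
  tr2$bleached <- tr2$bleached * g
  tr2$unbleached <- tr2$unbleached * g
  expect_equal(normalize_halfbleach(tr1)$fr, normalize_halfbleach(tr2)$fr,
               tolerance = 1e-12)
})

test_that("exponential fits recover noise-free parameters", {
  t <- seq(0, 30, by = 0.5)
  curve <- data.frame(time = t, fr = 0.8 * (1 - exp(-0.1 * t)))
  fit <- fit_recovery(curve)
  expect_true(fit$converged)
  expect_equal(fit$A, 0.8, tolerance = 1e-6)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$half_time, log(2) / 0.1, tolerance = 1e-5)
  expect_false(fit$solid_like)
  # flat zero curve: no recovery, solid-like
  flat <- data.frame(time = t, fr = rep(0, length(t)))
  fit <- fit_recovery(flat)
  expect_lt(fit$A, 0.05)
  expect_true(fit$solid_like)
  expect_error(fit_recovery(curve[1:3, ]), "five")
})

test_that("round trip generator -> normalization -> fit recovers (A, k)", {
  g <- gen_frap(n = 4, A = 0.75, k = 0.08, noise_sd = 0, seed = 2)
  for (tr in g$traces) {
    fit <- fit_recovery(normalize_halfbleach(tr))
    expect_equal(fit$A, 0.75, tolerance = 1e-6)
    expect_equal(fit$k, 0.08, tolerance = 1e-6)
  }
})

test_that("fitted rates preserve the programmed dynamics ordering", {
  ks <- c(0.02, 0.05, 0.1)
  for (s in 1:5) {
    g <- gen_frap(n = 3, A = 0.8, k = ks, noise_sd = 0.02, seed = s)
    khat <- vapply(g$traces, function(tr) {
      fit_recovery(normalize_halfbleach(tr))$k
    }, numeric(1))
    expect_true(all(diff(khat) > 0))
  }
})

test_that("replicate aggregation interpolates onto a common grid", {
  t <- 0:10
  c1 <- data.frame(time = t, fr = rep(0, 11))
  c2 <- data.frame(time = t, fr = rep(1, 11))
  agg <- aggregate_replicates(list(c1, c2))
  expect_equal(agg$mean, rep(0.5, 11))
  expect_equal(agg$sd, rep(sqrt(0.5), 11), tolerance = 1e-12)
  expect_equal(agg$n, rep(2L, 11))
  # identical curves: zero SD
  agg <- aggregate_replicates(list(c1, c1, c1))
  expect_true(all(agg$sd == 0))
  # noisy replicates agree with the underlying truth within 2 SE
  set.seed(8)
  truth <- 0.8 * (1 - exp(-0.1 * t))
  curves <- lapply(1:10, function(i) {
    data.frame(time = t, fr = truth + rnorm(11, 0, 0.05))
  })
  agg <- aggregate_replicates(curves)
  se <- agg$sd / sqrt(10)
  expect_true(all(abs(agg$mean - truth) <= 2.5 * se + 1e-9))
  # disjoint ranges error
  c3 <- data.frame(time = 20:25, fr = rep(0, 6))
  expect_error(aggregate_replicates(list(c1, c3)), "disjoint")
})
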