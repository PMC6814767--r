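test_that("generators are byte-deterministic given (seed, config)", {
  a <- gen_homologs(n = 10, seed = 3)
  b <- gen_homologs(n = 10, seed = 3)
  expect_identical(a, b)
  expect_false(identical(gen_homologs(n = 10, seed = 4)$records,
                         a$records))
  expect_identical(gen_nucleus_population(n = 200, seed = 3),
                   gen_nucleus_population(n = 200, seed = 3))
  expect_identical(gen_frap(n = 3, seed = 3), gen_frap(n = 3, seed = 3))
  expect_identical(gen_flow(n_events = 500, seed = 3),
                   gen_flow(n_events = 500, seed = 3))
  g1 <- gen_nuclei_images(n_cells = 5, seed = 3, snr = 5)
  g2 <- gen_nuclei_images(n_cells = 5, seed = 3, snr = 5)
  expect_identical(g1, g2)
})

test_that("zero substitution rates reproduce the template exactly", {
  g <- gen_homologs(n = 6, spacer_rate = 0, class_rate = 0, cr_rate = 0,
                    seed = 1)
  seqs <- vapply(g$records, `[[`, character(1), "sequence")
  expect_true(all(seqs == tdp43_ctd()$sequence))
  dm <- pairwise_distance_matrix(g$records)
  expect_true(all(dm$matrix == 0))
})

test_that("homolog generator rejects invalid rates and keeps the layout", {
  expect_error(gen_homologs(spacer_rate = 1.2), "rates")
  g <- gen_homologs(n = 8, spacer_rate = 0.3, class_rate = 0.02, seed = 2)
  # hydrophobic anchors are class-conserved: per-IDR Phi density is stable
  for (r in g$records) {
    v <- partition_domains(r)
    expect_equal(hydrophobic_density(v$IDR1),
                 hydrophobic_density(partition_domains(tdp43_ctd())$IDR1),
                 tolerance = 1e-9)
  }
})

test_that("two-clade ensembles give a bimodal distance distribution", {
  g <- gen_homologs(n = 30, spacer_rate = 0.05, class_rate = 0.01,
                    n_clades = 2, clade_divergence = 0.4, seed = 5)
  dm <- pairwise_distance_matrix(g$records)$matrix
  clade <- g$truth$clade
  within <- dm[outer(clade, clade, "==") & upper.tri(dm)]
  between <- dm[outer(clade, clade, "!=") & upper.tri(dm)]
  expect_gt(min(between), max(within))
})

test_that("nucleus population generator encodes the stated world", {
  g <- gen_nucleus_population(n = 3000, csat = 100, seed = 7)
  rec <- g$records
  # condensed nuclei all carry droplets; others none
  expect_true(all((rec$n_droplets > 0) == g$truth$cond))
  # condensation is concentrated above the true threshold
  tr <- g$truth$transfected
  expect_gt(mean(rec$intensity[tr & g$truth$cond]), 100)
  frac_below <- mean(g$truth$cond[tr & rec$intensity < 50])
  expect_lt(frac_below, 0.05)
  # default world: csat sits near a third of the mean transfected level
  expect_equal(g$truth$csat / mean(rec$intensity[tr]), 1 / 3,
               tolerance = 0.35)
})

test_that("image generator plants the droplets it reports", {
  g <- gen_nuclei_images(n_cells = 8, snr = Inf, seed = 11)
  expect_equal(sum(g$truth$cells$n_droplets),
               sum(vapply(g$truth$droplet_centers, nrow, integer(1))))
  # all nuclei below csat: no droplets anywhere
  g0 <- gen_nuclei_images(n_cells = 6, csat = 1e9, snr = Inf, seed = 11)
  expect_equal(sum(g0$truth$cells$n_droplets), 0L)
  expect_equal(nrow(detect_droplets(g0$reporter,
                                    segment_nuclei(g0$nuclear))), 0L)
})

test_that("frap generator validates config and encodes A = 0 as solid", {
  expect_error(gen_frap(A = 1.4), "A must")
  expect_error(gen_frap(k = 0), "k must")
  g <- gen_frap(n = 2, A = 0, k = 0.1, noise_sd = 0, seed = 1)
  cv <- normalize_halfbleach(g$traces[[1]])
  expect_true(all(abs(cv$fr) < 1e-12))
  expect_true(fit_recovery(cv)$solid_like)
})

test_that("flow generator honours null effects and spillover checks", {
  sing <- default_spillover()
  sing["GFP", ] <- sing["BFP", ]
  expect_error(gen_flow(spillover = sing), "singular")
  # r_max = 0 puts every bin median at baseline
  g <- gen_flow(variants = list(null = list(r_max = 0, K = 2000,
                                            baseline = 0.07)),
                n_events = 20000, seed = 13)
  ev <- splicing_ratio(gate(compensate(g$events$null, g$spillover)))
  s <- bin_and_summarize(ev, n_bins = 8)
  occ <- s$bins[s$bins$n >= 100, ]
  expect_true(all(abs(occ$median - 0.07) < 0.01))
})
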