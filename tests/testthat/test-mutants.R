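test_that("class substitutions respect region and conserve length", {
  ctd <- tdp43_ctd()
  # F-Y: F count moves to Y, length unchanged
  fy <- apply_mutant(ctd, "F-Y")
  c0 <- composition(ctd); c1 <- composition(fy)
  expect_equal(nchar(fy$sequence), nchar(ctd$sequence))
  expect_equal(c1[["F"]], 0)
  expect_equal(c1[["Y"]], c0[["Y"]] + c0[["F"]])
  # Phi-S: both IDRs lose all hydrophobic residues
  ps <- apply_mutant(ctd, "Phi-S")
  v <- partition_domains(ps)
  expect_equal(hydrophobic_density(v$IDR1), 0)
  expect_equal(hydrophobic_density(v$IDR2), 0)
  # ... but the CR is untouched
  expect_identical(v$CR$sequence, partition_domains(ctd)$CR$sequence)
})

test_that("the W-S mutant removes exactly the two IDR2 tryptophans", {
  ctd <- tdp43_ctd()
  ws <- apply_mutant(ctd, "W-S")
  v0 <- partition_domains(ctd); v1 <- partition_domains(ws)
  expect_equal(sum(record_residues(v0$IDR2) == "W"), 2L)
  expect_equal(sum(record_residues(v1$IDR2) == "W"), 0L)
  expect_identical(v1$CR$sequence, v0$CR$sequence)  # W334 stays
})

test_that("point mutations use full-length numbering with reference check", {
  ctd <- tdp43_ctd()
  m <- apply_mutant(ctd, "W385G")
  aa0 <- record_residues(ctd); aa1 <- record_residues(m)
  i <- which(record_positions(ctd) == 385)
  expect_identical(aa1[i], "G")
  expect_identical(aa1[-i], aa0[-i])
  # wrong reference residue is caught (numbering guard)
  expect_error(apply_mutant(ctd, point_mutations("bad", "A385G")),
               "reference mismatch")
  expect_error(apply_mutant(ctd, point_mutations("oob", "W500G")),
               "outside")
  # the compensatory double mutant swaps hydrophobicity between sites
  dbl <- apply_mutant(ctd, "W385G/G368W")
  aa2 <- record_residues(dbl)
  expect_identical(aa2[record_positions(ctd) == 368], "W")
  expect_identical(aa2[record_positions(ctd) == 385], "G")
  # composition restored relative to WT
  expect_equal(composition(dbl), composition(ctd))
})

test_that("catalog mutants alter hydropathy in the predicted direction", {
  ctd <- tdp43_ctd()
  hp0 <- hydropathy_profile(ctd)
  # W385G lowers the major IDR2 peak; G368W raises the minor 368 peak
  at <- function(hp, p) hp$value[hp$position == p]
  hp_wg <- hydropathy_profile(apply_mutant(ctd, "W385G"))
  expect_lt(at(hp_wg, 385), at(hp0, 385))
  hp_gw <- hydropathy_profile(apply_mutant(ctd, "G368W"))
  expect_gt(at(hp_gw, 368), at(hp0, 368))
  # G309S is hydrophobicity-neutral at its site compared to G309F
  hp_gs <- hydropathy_profile(apply_mutant(ctd, "G309S"))
  hp_gf <- hydropathy_profile(apply_mutant(ctd, "G309F"))
  expect_lt(abs(at(hp_gs, 309) - at(hp0, 309)), 0.01)
  expect_gt(at(hp_gf, 309) - at(hp0, 309), 0.1)
})

test_that("regrouping to the current count is the identity", {
  ctd <- tdp43_ctd()
  m <- regroup_clusters(ctd, 8L)
  expect_identical(m$sequence, ctd$sequence)
  expect_error(regroup_clusters(ctd, 9L), "exceeds")
})

test_that("regrouped mutants preserve composition and hit target counts", {
  ctd <- tdp43_ctd()
  res0 <- sort(record_residues(ctd))
  mean_h0 <- mean(scale_values()[record_residues(ctd)])
  for (tc in c(6L, 4L, 2L)) {
    m <- apply_mutant(ctd, sprintf("%dxPhi", tc))
    expect_identical(sort(record_residues(m)), res0)
    expect_equal(nchar(m$sequence), nchar(ctd$sequence))
    # overall (residue-level) hydrophobicity is exactly conserved
    expect_equal(mean(scale_values()[record_residues(m)]), mean_h0,
                 tolerance = 1e-12)
    expect_equal(nrow(ctd_clusters(m)), tc)
    # the CR is never modified
    expect_identical(partition_domains(m)$CR$sequence,
                     partition_domains(ctd)$CR$sequence)
  }
})

test_that("mutant catalog covers the full named panel", {
  cat_ <- mutant_catalog()
  expect_setequal(
    names(cat_),
    c("Phi-S", "F-S", "FYW-S", "FYW-L", "VLIM-S", "VLIM-F", "R-K", "K-R",
      "KRED-S", "M-S", "M-V", "F-Y", "W-S", "W385G", "G348V", "G348F",
      "G309F", "G309S", "G368W", "W385G/G368W", "6xPhi", "4xPhi", "2xPhi"))
  # every catalog mutant applies cleanly to the packaged CTD
  ctd <- tdp43_ctd()
  for (nm in names(cat_)) {
    m <- apply_mutant(ctd, nm)
    expect_equal(nchar(m$sequence), nchar(ctd$sequence))
  }
})
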