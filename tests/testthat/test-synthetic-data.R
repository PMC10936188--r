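test_that("simulateCommunity is deterministic and respects its law", {
  one <- simulateCommunity(1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(unlist(one[-1]))))
  expect_identical(simulateCommunity(25, seed = 7),
                   simulateCommunity(25, seed = 7))
  # law of large numbers on the abundance law
  big <- simulateCommunity(500, seed = 3,
                           abundance_law = list(dist = "lognormal",
                                                meanlog = 10, sdlog = 2))
  se <- 2 / sqrt(500)
  expect_lt(abs(mean(log(big$n0)) - 10), 3 * se)
  # invariants: rates plausible, eaf consistent with b
  expect_true(all(big$b_true >= 0 & big$d_true <= 0 & abs(big$d_true) <= 1))
  expect_equal(big$r_true, big$b_true + big$d_true)
  expect_true(all(big$gc >= 0.3 & big$gc <= 0.7))
  expect_error(simulateCommunity(10, seed = 1,
                                 abundance_law = list(dist = "zipf")),
               "unsupported")
  expect_error(simulateCommunity(10, seed = 1, abundance_law = "lognormal"),
               "list")
})

test_that("degenerate band width puts one taxon in its nearest fraction", {
  comm <- data.frame(taxon_id = "T1", gc = 0.5, n0 = 1e6, b_true = 0,
                     d_true = -0.1, r_true = -0.1, true_eaf = 0)
  des <- gradientDesign(band_sd = 1e-9, qpcr_cv = 0, n_replicates = 1L)
  qse <- simulateGradient(comm, des, label = "16O", seed = 1, noise = FALSE)
  cnt <- assay(qse, "counts")
  target <- which.min(abs(des@density_grid - densityFromGc(0.5)))
  expect_equal(which(cnt[1, ] > 0), setNames(target, colnames(cnt)[target]))
})

test_that("16O label and zero-enrichment 18O give the same expected profiles", {
  comm <- simulateCommunity(10, seed = 2)
  comm$true_eaf <- 0
  des <- gradientDesign(qpcr_cv = 0)
  a <- simulateGradient(comm, des, label = "16O", seed = 1, noise = FALSE)
  b <- simulateGradient(comm, des, label = "18O", seed = 1, noise = FALSE)
  expect_equal(unname(assay(a, "counts")), unname(assay(b, "counts")))
})

test_that("fully labeled band sits at the maximum-labeling density", {
  # closed-form centroid: W_max = W_light * (m_light + gain/(1 - a_nat)) /
  # m_light, recomputed here from the raw constants
  const <- qsipConstants()
  gc <- 0.4
  W_light <- const$density_intercept + const$density_slope * gc
  m_light <- const$mw_intercept + const$mw_slope * gc
  W_max <- W_light * (m_light + const$mw_gain_18O /
                        (1 - const$natural_abundance_18O)) / m_light
  comm <- data.frame(taxon_id = "T1", gc = gc, n0 = 1e6, b_true = 1,
                     d_true = 0, r_true = 1, true_eaf = 1.0)
  des <- fineDesign()
  qse <- simulateGradient(comm, des, label = "18O", seed = 1, noise = FALSE)
  # sequencing is compositional, so with one taxon the band profile is
  # read from the per-fraction qPCR copies
  cd <- fractionData(qse)
  sel <- cd$sample_id == "soil_18O_r1"
  copies <- cd$qpcr_copies_per_ul[sel] * cd$volume[sel]
  centroid <- sum(des@density_grid * copies) / sum(copies)
  expect_equal(centroid, W_max, tolerance = 1e-5)
})

test_that("expected fraction totals match the unfractionated t_end total", {
  comm <- simulateCommunity(30, seed = 4)
  qse <- simulateGradient(comm, gradientDesign(qpcr_cv = 0), label = "18O",
                          seed = 5, noise = FALSE)
  cd <- fractionData(qse)
  tot <- qsipTotals(qse)
  for (sid in tot$sample_id) {
    sel <- cd$sample_id == sid
    expect_equal(sum(cd$qpcr_copies_per_ul[sel] * cd$volume[sel]),
                 tot$total_tend[match(sid, tot$sample_id)],
                 tolerance = 1e-2)  # only kernel-truncation loss
  }
})

test_that("identical seeds reproduce identical experiments", {
  comm <- simulateCommunity(15, seed = 6)
  a <- simulateQsipExperiment(comm, gradientDesign(), seed = 9)
  b <- simulateQsipExperiment(comm, gradientDesign(), seed = 9)
  expect_identical(assay(a, "counts"), assay(b, "counts"))
  expect_identical(qsipTotals(a), qsipTotals(b))
  expect_identical(t0Counts(a), t0Counts(b))
})

test_that("empty or malformed communities are rejected", {
  expect_error(simulateGradient(data.frame(), gradientDesign(),
                                label = "18O", seed = 1), "empty")
  expect_error(simulateGradient(data.frame(taxon_id = "x"),
                                gradientDesign(), label = "18O", seed = 1),
               "lacks column")
})

test_that("band centers beyond the grid warn about truncated mass", {
  comm <- data.frame(taxon_id = "T1", gc = 0.7, n0 = 1e6, b_true = 1,
                     d_true = 0, r_true = 1, true_eaf = 0.99)
  des <- gradientDesign(n_fractions = 10L,
                        density_grid = seq(1.66, 1.70, length.out = 10))
  expect_warning(simulateGradient(comm, des, label = "18O", seed = 1,
                                  noise = FALSE), "truncated")
})

test_that("noise-free CUE microcosms round-trip through the CUE chain", {
  for (x in c(0, 0.2, 0.35, 0.5, 0.8)) {
    s <- simulateCueMicrocosm(x, seed = 1, noise = FALSE)
    expect_equal(cueFromSample(s)$cue, x, tolerance = 1e-9)
  }
  # no growth -> DNA at natural abundance
  s0 <- simulateCueMicrocosm(0, seed = 1, noise = FALSE)
  expect_equal(s0$a_dna_labeled, s0$a_dna_natural)
  # cue = 0.5 -> growth equals respiration
  s5 <- cueFromSample(simulateCueMicrocosm(0.5, seed = 1, noise = FALSE))
  expect_equal(s5$c_growth, s5$c_respiration, tolerance = 1e-9)
  expect_error(simulateCueMicrocosm(1, seed = 1), "true_cue")
})
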