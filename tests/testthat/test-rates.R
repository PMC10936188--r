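test_that("unlabeledCopies is linear between the labeling extremes", {
  expect_equal(unlabeledCopies(100, 308, 308, 320), 100)  # nothing labeled
  expect_equal(unlabeledCopies(100, 320, 308, 320), 0)    # fully labeled
  expect_equal(unlabeledCopies(100, 314, 308, 320), 50)   # midpoint
  expect_error(unlabeledCopies(100, 308, 308, 308), "degenerate")
  # clamping keeps the pool inside [0, n_t]
  expect_equal(unlabeledCopies(100, 307, 308, 320), 100)
  expect_equal(unlabeledCopies(100, 321, 308, 320), 0)
})

test_that("perCapitaRates reproduces hand-computed exponential rates", {
  stasis <- perCapitaRates(100, 100, 100, t = 1)
  expect_equal(unlist(stasis[c("b", "d", "r")]),
               c(b = 0, d = 0, r = 0))
  hand <- perCapitaRates(100, 200, 50, t = 1)
  expect_equal(hand$b, log(4))
  expect_equal(hand$d, log(0.5))
  expect_equal(hand$r, log(2))
  expect_equal(hand$r, hand$b + hand$d)  # exact identity
  # undefined b when no unlabeled copies remain
  z <- perCapitaRates(100, 200, 0, t = 1)
  expect_true(is.na(z$b) && z$flag == "b=NA")
  expect_error(perCapitaRates(0, 10, 5, 1), "> 0")
  expect_error(perCapitaRates(10, 10, 5, 0), "t must be")
})

test_that("r = b + d holds across randomized inputs", {
  set.seed(9)
  n0 <- runif(200, 10, 1e6)
  n_t <- n0 * exp(runif(200, -1, 1))
  nl <- n_t * runif(200, 0.05, 1)
  rt <- perCapitaRates(n0, n_t, nl, t = 1, clamp = FALSE)
  expect_equal(rt$r, rt$b + rt$d, tolerance = 1e-12)
})

test_that("absolute abundances match brute-force per-taxon summation", {
  expect_equal(absoluteTaxonAbundance(0.01, 1e8), 1e6)
  set.seed(11)
  shares <- prop.table(runif(30))
  expect_equal(sum(absoluteTaxonAbundance(shares, 5e7)), 5e7)  # conservation
  qse <- adjustRecovery(makeSimQse(20))
  ab <- qsip18O:::.taxonAbundances(qse)
  cd <- fractionData(qse)
  cnt <- assay(qse, "counts")
  sid <- ab$sample_id[1]
  sel <- which(cd$sample_id == sid)
  oracle <- vapply(rownames(qse), function(tx) {
    s <- 0
    for (j in sel) {
      ftot <- sum(cnt[, j])
      if (ftot > 0)
        s <- s + cnt[tx, j] / ftot * cd$adjusted_copies[j]
    }
    s
  }, numeric(1))
  got <- ab$n_t[ab$sample_id == sid]
  expect_equal(got, unname(oracle[ab$taxon_id[ab$sample_id == sid]]),
               tolerance = 1e-12)
})

test_that("noise-free simulations recover (b, d, r) to 1e-3", {
  comm <- simulateCommunity(40, seed = 5)
  qse <- simulateQsipExperiment(comm, fineDesign(), seed = 6, noise = FALSE)
  qse <- adjustRecovery(qse)
  rates <- estimateRates(qse)
  m <- merge(rates, groundTruth(qse), by = "taxon_id")
  expect_lt(max(abs(m$b - m$b_true)), 1e-3)
  expect_lt(max(abs(m$d - m$d_true)), 1e-3)
  expect_lt(max(abs(m$r - m$r_true)), 1e-3)
  # the hand case from the exponential model: b .4, d -.3
  comm1 <- data.frame(taxon_id = "T1", gc = 0.5, n0 = 1e6, b_true = 0.4,
                      d_true = -0.3, r_true = 0.1,
                      true_eaf = (1 - exp(-0.4)) *
                        (1 - qsipConstants()$natural_abundance_18O))
  q1 <- adjustRecovery(simulateQsipExperiment(comm1, fineDesign(),
                                              seed = 7, noise = FALSE))
  r1 <- estimateRates(q1)
  expect_equal(c(r1$b, r1$d, r1$r), c(0.4, -0.3, 0.1), tolerance = 1e-3)
})

test_that("all taxa decline when mortality always exceeds reproduction", {
  comm <- simulateCommunity(60, seed = 8)
  comm$d_true <- -(comm$b_true + runif(60, 0.05, 0.3))
  comm$r_true <- comm$b_true + comm$d_true
  comm$true_eaf <- (1 - exp(-comm$b_true)) *
    (1 - qsipConstants()$natural_abundance_18O)
  qse <- adjustRecovery(simulateQsipExperiment(comm, fineDesign(),
                                               seed = 9, noise = FALSE))
  rates <- estimateRates(qse)
  expect_true(all(rates$r < 0))
})

test_that("community aggregation is an abundance-weighted mean", {
  single <- data.frame(b = 0.3, d = -0.4, r = -0.1)
  cr <- communityRates(single, weights = 1)
  expect_equal(unlist(cr), c(b_comm = 0.3, d_comm = -0.4, r_comm = -0.1,
                             mean_lifespan = 2.5))
  two <- data.frame(b = c(0.2, 0.4), d = c(-0.3, -0.3), r = c(-0.1, 0.1))
  expect_equal(communityRates(two, weights = c(1, 1))$b_comm, 0.3)
  expect_equal(communityRates(two, weights = c(3, 1))$b_comm, 0.25)
  cr2 <- communityRates(two, weights = c(1, 1))
  expect_equal(cr2$r_comm, cr2$b_comm + cr2$d_comm)
  expect_error(communityRates(data.frame(b = NA_real_, d = NA_real_,
                                         r = NA_real_), weights = 1),
               "no taxa")
  # mean life span is the inverse mortality magnitude
  expect_equal(meanLifespan(-0.27), 1 / 0.27)
  expect_equal(round(meanLifespan(0.27), 1), 3.7)
  expect_error(meanLifespan(0), "life span")
})
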