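test_that("rare-OTU filter applies the share threshold to the grand total", {
  # toy table: 6 OTUs split over two fractions; brute-force oracle below
  counts <- cbind(c(5000, 300, 10, 5, 4, 1), c(95000, 0, 0, 0, 0, 0))
  rownames(counts) <- paste0("OTU", 1:6)
  qse <- makeTinyQse(counts, densities = c(1.70, 1.71),
                     label_sets = data.frame(sample_id = "A_18O_r1",
                                             replicate = 1, treatment = "A",
                                             label = "18O"))
  grand <- sum(counts)              # 100320, computed before removal
  oracle <- rownames(counts)[rowSums(counts) / grand >= 5e-5]
  kept <- rownames(filterRareOtus(qse, 5e-5))
  expect_identical(kept, oracle)
  # threshold boundary: 5 reads of exactly 100,000 total is kept, 4 is not
  counts2 <- cbind(c(99991, 5, 4))
  rownames(counts2) <- c("big", "at", "below")
  qse2 <- makeTinyQse(counts2, densities = 1.70,
                      label_sets = data.frame(sample_id = "A_18O_r1",
                                              replicate = 1,
                                              treatment = "A",
                                              label = "18O"))
  expect_identical(rownames(filterRareOtus(qse2, 5e-5)), c("big", "at"))
  # idempotence
  once <- filterRareOtus(qse, 5e-5)
  expect_identical(rownames(filterRareOtus(once, 5e-5)), rownames(once))
})

test_that("prevalence filter requires presence in two of three replicates", {
  set.seed(42)
  n <- 20
  tubes <- expand.grid(replicate = 1:3, label = c("16O", "18O"),
                       stringsAsFactors = FALSE)
  tubes$treatment <- "A"
  tubes$sample_id <- with(tubes, paste("A", label, paste0("r", replicate),
                                       sep = "_"))
  counts <- matrix(rbinom(n * nrow(tubes), 1, 0.45) *
                     rpois(n * nrow(tubes), 40), n)
  rownames(counts) <- sprintf("OTU%02d", seq_len(n))
  qse <- makeTinyQse(counts, densities = 1.70, label_sets = tubes)
  kept <- rownames(filterPrevalence(qse, min_reps = 2))
  # independent tally oracle
  oracle <- vapply(seq_len(n), function(i) {
    any(vapply(c("16O", "18O"), function(lab) {
      pres <- vapply(1:3, function(r) {
        sum(counts[i, tubes$label == lab & tubes$replicate == r]) > 0
      }, logical(1))
      sum(pres) >= 2
    }, logical(1)))
  }, logical(1))
  expect_identical(kept, rownames(counts)[oracle])
  # row order within the table does not change the surviving set
  perm <- sample(n)
  qse_p <- makeTinyQse(counts[perm, ], densities = 1.70, label_sets = tubes)
  expect_setequal(rownames(filterPrevalence(qse_p, 2)), kept)
})

test_that("density window is a closed interval and errors on emptied tubes", {
  dens <- seq(1.65, 1.78, length.out = 20)
  counts <- matrix(10, 3, 20, dimnames = list(paste0("O", 1:3), NULL))
  qse <- makeTinyQse(counts, densities = dens,
                     label_sets = data.frame(sample_id = "A_18O_r1",
                                             replicate = 1, treatment = "A",
                                             label = "18O"))
  win <- selectDensityWindow(qse, 1.69, 1.74)
  expect_equal(ncol(win), sum(dens >= 1.69 & dens <= 1.74))  # interval oracle
  # boundary behavior
  qse2 <- makeTinyQse(matrix(1, 1, 2), densities = c(1.689, 1.70),
                      label_sets = data.frame(sample_id = "A_18O_r1",
                                              replicate = 1,
                                              treatment = "A",
                                              label = "18O"))
  expect_equal(fractionData(selectDensityWindow(qse2, 1.69, 1.74))$density,
               1.70)
  expect_error(selectDensityWindow(qse, 1.85, 1.86), "A_18O_r1")
})

test_that("recovery adjustment conserves the unfractionated total exactly", {
  # hand example: 100 and 300 copies/uL x 250 uL; unfractionated 200,000
  counts <- matrix(c(10, 30), 1, 2, dimnames = list("O1", NULL))
  fr <- data.frame(sample_id = "A_18O_r1", replicate = 1, treatment = "A",
                   label = "18O", fraction = 1:2, density = c(1.70, 1.72),
                   volume = 250, qpcr_copies_per_ul = c(100, 300))
  tot <- data.frame(sample_id = "A_18O_r1", replicate = 1, treatment = "A",
                    label = "18O", total_t0 = 2e5, total_tend = 2e5)
  qse <- adjustRecovery(QsipExperiment(counts, fr, totals = tot))
  expect_equal(fractionData(qse)$adjusted_copies, c(50000, 150000))
  # scale invariance: scaling raw copies leaves adjusted copies unchanged
  fr2 <- fr; fr2$qpcr_copies_per_ul <- fr$qpcr_copies_per_ul * 3
  qse2 <- suppressWarnings(
    adjustRecovery(QsipExperiment(counts, fr2, totals = tot)))
  expect_equal(fractionData(qse2)$adjusted_copies,
               fractionData(qse)$adjusted_copies)
  # identity when sums already match
  fr3 <- fr; fr3$qpcr_copies_per_ul <- c(400, 400)
  qse3 <- adjustRecovery(QsipExperiment(counts, fr3, totals = tot))
  expect_equal(fractionData(qse3)$adjusted_copies, c(1e5, 1e5))
  # recovery > 1 warns but keeps; <= 0 errors
  tot_small <- tot; tot_small$total_tend <- 5e4
  expect_warning(adjustRecovery(QsipExperiment(counts, fr,
                                               totals = tot_small)),
                 "> 1")
  tot_bad <- tot; tot_bad$total_tend <- 0
  expect_error(adjustRecovery(QsipExperiment(counts, fr,
                                             totals = tot_bad)),
               "must be > 0")
})

test_that("adjusted copies sum to the tube total on simulated data", {
  qse <- adjustRecovery(makeSimQse(25))
  cd <- fractionData(qse)
  tot <- qsipTotals(qse)
  sums <- tapply(cd$adjusted_copies, cd$sample_id, sum)
  expect_equal(as.numeric(sums[tot$sample_id]), tot$total_tend,
               tolerance = 1e-12)
})
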