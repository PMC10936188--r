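# Small in-code fixtures shared by the tests.

# a QsipExperiment built by hand: 2 tubes (one per label), k fractions
makeTinyQse <- function(counts, densities, label_sets = NULL,
                        totals_tend = NULL, totals_t0 = NULL,
                        volume = 250) {
  k <- length(densities)
  tubes <- if (is.null(label_sets))
    data.frame(sample_id = c("A_16O_r1", "A_18O_r1"),
               replicate = 1, treatment = "A", label = c("16O", "18O"))
  else label_sets
  fr <- do.call(rbind, lapply(seq_len(nrow(tubes)), function(i)
    data.frame(sample_id = tubes$sample_id[i],
               replicate = tubes$replicate[i],
               treatment = tubes$treatment[i], label = tubes$label[i],
               fraction = seq_len(k), density = densities, volume = volume,
               qpcr_copies_per_ul = 100)))
  if (is.null(totals_tend)) totals_tend <- rep(1e6, nrow(tubes))
  if (is.null(totals_t0)) totals_t0 <- rep(1e6, nrow(tubes))
  tot <- data.frame(sample_id = tubes$sample_id,
                    replicate = tubes$replicate,
                    treatment = tubes$treatment, label = tubes$label,
                    total_t0 = totals_t0, total_tend = totals_tend)
  QsipExperiment(counts, fr, totals = tot)
}

# default study-scale simulation used by several tests
makeSimQse <- function(n_taxa = 50, seed_comm = 1, seed_sim = 2,
                       noise = TRUE, design = gradientDesign()) {
  comm <- simulateCommunity(n_taxa, seed = seed_comm)
  simulateQsipExperiment(comm, design, seed = seed_sim, noise = noise)
}

# fine noise-free design for exact round trips
fineDesign <- function(n = 120)
  gradientDesign(n_fractions = n,
                 density_grid = seq(1.62, 1.82, length.out = n),
                 band_sd = 0.004, seq_depth = 1e6, qpcr_cv = 0)
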