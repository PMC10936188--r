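#' Simulate density-gradient fractionation of a labeled community
#'
#' Forward model of a heavy-water qSIP experiment for one treatment and one
#' isotope label, producing `n_replicates` tubes.  For each taxon the copies
#' at the end of the incubation, `n_t = n0 * exp((b + d) * t)`, are split
#' into an unlabeled pool (band centered at the GC-determined unlabeled
#' buoyant density) and a labeled pool whose band center is shifted through
#' the same density/molecular-weight mapping the estimator inverts, so that
#' the abundance-weighted band centroid corresponds exactly to the taxon's
#' `true_eaf`.  Bands are spread over the density grid with Gaussian kernels
#' of sd `band_sd` (mass integrated per fraction bin; mass falling beyond
#' the grid ends is truncated with a warning).  Per-fraction sequencing
#' counts are multinomial at `seq_depth` reads; per-fraction qPCR copies are
#' the taxon sums times a per-tube recovery loss and lognormal noise with
#' coefficient of variation `qpcr_cv`.
#'
#' With `label = "16O"` all effective enrichments are forced to zero, giving
#' the paired natural-abundance control tubes.
#'
#' @param community `data.frame` from [simulateCommunity()] (columns `gc`,
#'   `n0`, `b_true`, `d_true`, `true_eaf`).
#' @param design a [GradientDesign-class].
#' @param label `"18O"` (labeled water) or `"16O"` (control).
#' @param treatment treatment name recorded in the metadata.
#' @param seed integer seed.
#' @param noise `TRUE` for the full stochastic model; `FALSE` replaces every
#'   random draw by its expectation (counts become expected proportions at
#'   `seq_depth`, qPCR noise and recovery loss are switched off), which the
#'   estimator chain must invert exactly.
#' @param constants see [qsipConstants()].
#'
#' @return A [QsipExperiment-class] holding all tubes of this label, with
#'   `totals`, `t0_counts` and `ground_truth` metadata attached.
#'
#' @examples
#' comm <- simulateCommunity(5, seed = 1)
#' qse <- simulateGradient(comm, gradientDesign(), label = "18O", seed = 2)
#' qse
#'
#' @seealso [simulateQsipExperiment()] for paired 16O/18O designs.
#' @export
simulateGradient <- function(community, design = gradientDesign(),
                             label = c("18O", "16O"), treatment = "soil",
                             seed = NULL, noise = TRUE,
                             constants = qsipConstants()) {
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulateTubes(community, design, label, treatment, noise, constants)
  QsipExperiment(sim$counts, sim$fractions, totals = sim$totals,
                 t0_counts = sim$t0_counts, ground_truth = sim$ground_truth)
}

#' Simulate a complete paired 16O/18O qSIP experiment
#'
#' Convenience wrapper running [simulateGradient()] for both isotope labels
#' (and optionally several treatments) under one seed and binding the tubes
#' into a single [QsipExperiment-class].
#'
#' @inheritParams simulateGradient
#' @param treatments character vector of treatment names.
#' @param community a community `data.frame`, or a named list with one
#'   community per treatment.
#'
#' @return A [QsipExperiment-class] with `2 * n_replicates` tubes per
#'   treatment.
#' @examples
#' comm <- simulateCommunity(5, seed = 1)
#' qse <- simulateQsipExperiment(comm, gradientDesign(), seed = 2)
#' table(fractionData(qse)$label)
#' @export
simulateQsipExperiment <- function(community, design = gradientDesign(),
                                   treatments = "soil", seed = NULL,
                                   noise = TRUE,
                                   constants = qsipConstants()) {
  if (!is.null(seed)) set.seed(seed)
  parts <- list()
  for (tr in treatments) {
    comm <- if (is.data.frame(community)) community else community[[tr]]
    if (is.null(comm)) stop("no community supplied for treatment ", tr)
    for (lab in c("16O", "18O"))
      parts[[paste(tr, lab)]] <-
        .simulateTubes(comm, design, lab, tr, noise, constants)
  }
  counts <- do.call(base::cbind, lapply(parts, `[[`, "counts"))
  fractions <- do.call(rbind, c(lapply(parts, `[[`, "fractions"),
                                make.row.names = FALSE))
  totals <- do.call(rbind, c(lapply(parts, `[[`, "totals"),
                             make.row.names = FALSE))
  t0c <- do.call(base::cbind, lapply(parts, `[[`, "t0_counts"))
  gt <- unique(do.call(rbind, c(lapply(parts, `[[`, "ground_truth"),
                                make.row.names = FALSE)))
  QsipExperiment(counts, fractions, totals = totals, t0_counts = t0c,
                 ground_truth = gt)
}

# Gaussian band mass per fraction bin; bins are delimited by midpoints
# between grid densities, mass beyond the outer edges is dropped.
.bandMass <- function(center, sd, grid) {
  K <- length(grid)
  dg <- diff(grid)
  edges <- c(grid[1] - dg[1] / 2, grid[-K] + dg / 2, grid[K] + dg[K - 1] / 2)
  pnorm(edges[-1], center, sd) - pnorm(edges[-(K + 1)], center, sd)
}

# mean-one lognormal noise factors for a given coefficient of variation
.lnormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, -sdlog^2 / 2, sdlog)
}

.simulateTubes <- function(community, design, label, treatment, noise,
                           constants) {
  if (!is.data.frame(community) || nrow(community) == 0)
    stop("community is empty")
  need <- c("taxon_id", "gc", "n0", "b_true", "d_true", "true_eaf")
  if (!all(need %in% colnames(community)))
    stop("community lacks column(s): ",
         paste(setdiff(need, colnames(community)), collapse = ", "))
  n <- nrow(community)
  grid <- design@density_grid
  K <- design@n_fractions
  t_inc <- design@t_incubation
  a_max <- 1 - constants$natural_abundance_18O

  eaf <- if (label == "16O") rep(0, n) else community$true_eaf
  W_light <- densityFromGc(community$gc, constants)
  m_light <- mwFromGc(community$gc, constants)
  f_lab <- pmin(1, eaf / a_max)              # share of copies in heavy pool
  percopy <- ifelse(f_lab > 0, eaf / f_lab, 0)
  m_new <- m_light + (percopy / a_max) * constants$mw_gain_18O
  W_new <- W_light * m_new / m_light
  n_t <- community$n0 * exp((community$b_true + community$d_true) * t_inc)

  heavy <- f_lab > 0
  if (any(W_new[heavy] > max(grid)) || any(W_light < min(grid)) ||
      any(W_light > max(grid)))
    warning("band center outside the density grid; mass truncated at ",
            "grid ends")
  E <- matrix(0, n, K, dimnames = list(community$taxon_id, NULL))
  for (i in seq_len(n)) {
    m <- (1 - f_lab[i]) * .bandMass(W_light[i], design@band_sd, grid)
    if (f_lab[i] > 0)
      m <- m + f_lab[i] * .bandMass(W_new[i], design@band_sd, grid)
    E[i, ] <- n_t[i] * m
  }

  counts_l <- list(); fractions_l <- list(); totals_l <- list()
  t0c_l <- list()
  depth <- design@seq_depth
  p0 <- community$n0 / sum(community$n0)
  for (rep_i in seq_len(design@n_replicates)) {
    sample_id <- paste(treatment, label, paste0("r", rep_i), sep = "_")
    frac_tot <- colSums(E)                   # copies before recovery loss
    if (noise) {
      recovery <- runif(1, design@recovery_range[1], design@recovery_range[2])
      raw_abs <- frac_tot * recovery * .lnormNoise(K, design@qpcr_cv)
      cnt <- matrix(0, n, K)
      for (j in seq_len(K))
        if (frac_tot[j] > 0)
          cnt[, j] <- rmultinom(1, round(depth), E[, j] / frac_tot[j])
      total_t0 <- sum(community$n0) * .lnormNoise(1, design@qpcr_cv)
      total_tend <- sum(n_t) * .lnormNoise(1, design@qpcr_cv)
      t0_cnt <- rmultinom(1, round(depth), p0)[, 1]
    } else {
      raw_abs <- frac_tot
      cnt <- sweep(E, 2, ifelse(frac_tot > 0, frac_tot, 1), "/") * depth
      total_t0 <- sum(community$n0)
      total_tend <- sum(n_t)
      t0_cnt <- p0 * depth
    }
    rownames(cnt) <- community$taxon_id
    fr <- data.frame(
      sample_id = sample_id, replicate = rep_i, treatment = treatment,
      label = label, fraction = seq_len(K), density = grid,
      volume = design@volume, qpcr_copies_per_ul = raw_abs / design@volume,
      column_id = paste0(sample_id, ":f", sprintf("%02d", seq_len(K))),
      stringsAsFactors = FALSE
    )
    colnames(cnt) <- fr$column_id
    counts_l[[rep_i]] <- cnt
    fractions_l[[rep_i]] <- fr
    totals_l[[rep_i]] <- data.frame(
      sample_id = sample_id, replicate = rep_i, treatment = treatment,
      label = label, total_t0 = total_t0, total_tend = total_tend,
      stringsAsFactors = FALSE)
    t0c_l[[sample_id]] <- as.numeric(t0_cnt)
  }
  counts <- do.call(base::cbind, counts_l)
  fractions <- do.call(rbind, c(fractions_l, make.row.names = FALSE))
  totals <- do.call(rbind, c(totals_l, make.row.names = FALSE))
  t0c <- do.call(base::cbind, t0c_l)
  rownames(t0c) <- community$taxon_id
  gt <- community
  gt$treatment <- treatment
  list(counts = counts, fractions = fractions, totals = totals,
       t0_counts = t0c, ground_truth = gt)
}
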