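#' Simulate an 18O-water CUE microcosm with known ground truth
#'
#' Inverts the CUE chain: from a target `true_cue` and a respiration rate,
#' the implied biomass production is `c_growth = c_respiration * true_cue /
#' (1 - true_cue)`, the DNA produced over the incubation follows from the
#' sample-specific conversion factor, and the measured atom fraction 18O of
#' the labeled-soil DNA is the two-pool mixing value consistent with that
#' production.  With `noise = FALSE`, [cueFromSample()] recovers `true_cue`
#' exactly.
#'
#' @param true_cue target carbon use efficiency, in \[0, 1).
#' @param c_respiration respiration rate (ng C / g soil / h, default 650).
#' @param water_atom_fraction atom fraction 18O of the soil water (default
#'   [waterAtomFraction()]).
#' @param seed integer seed.
#' @param noise apply multiplicative lognormal measurement noise
#'   (`meas_cv`) to the respiration and DNA atom-fraction enrichment?
#' @param meas_cv coefficient of variation of the measurement noise
#'   (default 0.05).
#' @param dna_total total DNA after incubation (ng/g soil, default 10000).
#' @param conv_factor microbial biomass C per DNA (ng C / ng DNA, default
#'   30).
#' @param t_hours incubation time (default 24).
#' @param treatment,sample_id labels carried into the output.
#' @param constants see [qsipConstants()].
#'
#' @return one-row `data.frame` (a CUE sample) with the measured columns
#'   expected by [cueFromSample()] plus the generating `true_cue`.
#'
#' @examples
#' s <- simulateCueMicrocosm(0.5, seed = 1, noise = FALSE)
#' all.equal(cueFromSample(s)$cue, 0.5)
#'
#' @export
simulateCueMicrocosm <- function(true_cue, c_respiration = 650,
                                 water_atom_fraction = waterAtomFraction(),
                                 seed = NULL, noise = TRUE, meas_cv = 0.05,
                                 dna_total = 10000, conv_factor = 30,
                                 t_hours = 24, treatment = "soil",
                                 sample_id = "cue_1",
                                 constants = qsipConstants()) {
  if (true_cue < 0 || true_cue >= 1)
    stop("true_cue must lie in [0, 1); CUE = 1 implies zero respiration ",
         "share and an undefined microcosm")
  if (c_respiration <= 0) stop("c_respiration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  a_nat <- constants$natural_abundance_18O
  c_growth <- c_respiration * true_cue / (1 - true_cue)
  dna_produced <- c_growth * t_hours / conv_factor
  f_new <- dna_produced / dna_total
  if (f_new > 1)
    stop("implied DNA production exceeds the DNA pool; increase dna_total ",
         "or lower true_cue")
  a_lab <- a_nat + f_new * (water_atom_fraction - a_nat)
  if (noise) {
    c_respiration <- c_respiration * .lnormNoise(1, meas_cv)
    enrich <- (a_lab - a_nat) * .lnormNoise(1, meas_cv)
    a_lab <- a_nat + enrich
  }
  data.frame(sample_id = sample_id, treatment = treatment,
             c_respiration = c_respiration, dna_total = dna_total,
             a_dna_labeled = a_lab, a_dna_natural = a_nat,
             a_water = water_atom_fraction, conv_factor = conv_factor,
             t_hours = t_hours, true_cue = true_cue,
             stringsAsFactors = FALSE)
}
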