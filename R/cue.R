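#' Fraction of DNA newly synthesized during an 18O incubation
#'
#' Two-pool linear isotope mixing: DNA extracted after the incubation is a
#' blend of pre-existing DNA at the natural 18O abundance and new DNA whose
#' oxygen derives from the (labeled) soil water, so
#' `f_new = (a_dna_labeled - a_dna_natural) / (a_water - a_dna_natural)`.
#' Values outside \[0, 1\] by more than `tol` are clipped with a warning;
#' small excursions are clipped silently (measurement noise).
#'
#' @param a_dna_labeled atom fraction 18O of DNA from the labeled soil.
#' @param a_dna_natural atom fraction 18O of DNA from the parallel 16O
#'   soil (natural abundance).
#' @param a_water atom fraction 18O of the soil water during the
#'   incubation (see [waterAtomFraction()]).
#' @param water_o_fraction fraction of the oxygen in new DNA that derives
#'   from water (default 1; expose a smaller value to correct for oxygen
#'   incorporated from other sources).
#' @param tol tolerance before an out-of-range value triggers a warning.
#'
#' @return fraction of the DNA pool that is newly synthesized, in
#'   \[0, 1\].
#'
#' @examples
#' fractionNewDna(0.1, 0.002, 0.5)  # 0.098 / 0.498
#'
#' @export
fractionNewDna <- function(a_dna_labeled, a_dna_natural, a_water,
                           water_o_fraction = 1, tol = 1e-6) {
  if (any(a_water <= a_dna_natural))
    stop("a_water must exceed the natural DNA 18O abundance")
  f <- (a_dna_labeled - a_dna_natural) /
    ((a_water - a_dna_natural) * water_o_fraction)
  out <- f < -tol | f > 1 + tol
  if (any(out, na.rm = TRUE))
    warning(sum(out, na.rm = TRUE), " f_new value(s) outside [0, 1]; ",
            "clipped")
  pmin(pmax(f, 0), 1)
}

#' Microbial biomass carbon production rate from DNA production
#'
#' `dna_produced = f_new * dna_total`; a sample-specific conversion factor
#' (microbial biomass C per unit DNA) turns it into biomass C, divided by
#' the incubation time to give a rate.
#'
#' @param f_new fraction of DNA newly synthesized ([fractionNewDna()]).
#' @param dna_total total DNA measured after the incubation (ng/g soil).
#' @param conv_factor microbial biomass C per DNA (ng C per ng DNA).
#' @param t incubation time in hours (default 24).
#'
#' @return growth rate in ng C / g soil / h.
#' @examples
#' cGrowth(0.2, 10000, 30, 24)
#' @export
cGrowth <- function(f_new, dna_total, conv_factor, t = 24) {
  if (any(conv_factor <= 0)) stop("conv_factor must be > 0")
  if (any(t <= 0)) stop("t must be > 0")
  conv_factor * f_new * dna_total / t
}

#' Carbon use efficiency
#'
#' `CUE = C_growth / (C_growth + C_respiration)`: the share of the carbon
#' taken up (growth + respiration, under steady-state uptake) that is
#' allocated to biomass.  Lies in \[0, 1).
#'
#' @param c_growth biomass production rate (ng C / g soil / h).
#' @param c_respiration respiration rate (ng C / g soil / h).
#' @return carbon use efficiency (unitless).
#' @examples
#' cueRatio(350, 650)  # 0.35
#' @export
cueRatio <- function(c_growth, c_respiration) {
  if (any(c_growth < 0) || any(c_respiration < 0))
    stop("rates must be non-negative")
  if (any(c_growth + c_respiration == 0))
    stop("CUE undefined when growth and respiration are both zero")
  c_growth / (c_growth + c_respiration)
}

#' Atom fraction 18O of the soil water during incubation
#'
#' The label water added to pre-dried soil mixes with the residual soil
#' moisture; the resulting atom fraction is the volume-weighted mean of the
#' label and the natural-abundance residual water.
#'
#' @param label_volume_ul volume of labeled water added (uL, default 400).
#' @param label_atom_fraction atom fraction 18O of the label (default
#'   0.98).
#' @param soil_mass_g dry soil mass (g, default 2).
#' @param residual_moisture residual gravimetric water content of the
#'   air-dried soil (g water / g soil, default 0.02).
#' @param constants see [qsipConstants()] (for the natural abundance).
#'
#' @return atom fraction 18O of the soil water.
#' @examples
#' waterAtomFraction()
#' @export
waterAtomFraction <- function(label_volume_ul = 400,
                              label_atom_fraction = 0.98, soil_mass_g = 2,
                              residual_moisture = 0.02,
                              constants = qsipConstants()) {
  resid_ul <- soil_mass_g * residual_moisture * 1000
  (label_volume_ul * label_atom_fraction +
     resid_ul * constants$natural_abundance_18O) /
    (label_volume_ul + resid_ul)
}

#' Carbon use efficiency of CUE microcosm samples
#'
#' Applies the full CUE chain to a table of microcosm measurements:
#' [fractionNewDna()] from the three atom fractions, [cGrowth()] via the
#' sample-specific conversion factor, and [cueRatio()] against the
#' measured respiration.
#'
#' @param samples `data.frame` with columns `c_respiration` (ng C/g
#'   soil/h), `dna_total` (ng/g soil), `a_dna_labeled`, `a_dna_natural`,
#'   `a_water` (atom fractions 18O), `conv_factor` (ng C per ng DNA) and
#'   `t_hours`.
#' @param water_o_fraction see [fractionNewDna()].
#'
#' @return the input with `f_new`, `c_growth` and `cue` columns appended.
#'
#' @examples
#' s <- simulateCueMicrocosm(0.35, seed = 1, noise = FALSE)
#' cueFromSample(s)$cue
#'
#' @export
cueFromSample <- function(samples, water_o_fraction = 1) {
  need <- c("c_respiration", "dna_total", "a_dna_labeled", "a_dna_natural",
            "a_water", "conv_factor", "t_hours")
  miss <- setdiff(need, colnames(samples))
  if (length(miss)) stop("samples lack column(s): ",
                         paste(miss, collapse = ", "))
  samples$f_new <- fractionNewDna(samples$a_dna_labeled,
                                  samples$a_dna_natural, samples$a_water,
                                  water_o_fraction)
  samples$c_growth <- cGrowth(samples$f_new, samples$dna_total,
                              samples$conv_factor, samples$t_hours)
  samples$cue <- cueRatio(samples$c_growth, samples$c_respiration)
  samples
}
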