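#' GradientDesign: physical design of a simulated density gradient
#'
#' Bundles the tunable knobs of a simulated CsCl fractionation run.  The
#' defaults mirror a standard heavy-water qSIP experiment: a tube loaded at
#' an initial CsCl buoyant density of 1.718 g/mL, fractionated into 20 equal
#' ~250 uL fractions, three replicate tubes per label, and a 24-h (1 day)
#' incubation.
#'
#' @slot n_fractions number of fractions per tube.
#' @slot density_grid strictly increasing buoyant densities (g/mL) at which
#'   fractions are collected.
#' @slot band_sd within-gradient spread (sd, g/mL) of one taxon's DNA band.
#' @slot seq_depth sequencing reads per fraction library.
#' @slot qpcr_cv coefficient of variation of qPCR measurements.
#' @slot initial_density initial CsCl buoyant density (g/mL); recorded for
#'   provenance.
#' @slot n_replicates replicate tubes per treatment and label.
#' @slot t_incubation incubation time in days.
#' @slot volume fraction volume (uL).
#' @slot recovery_range range of the per-tube multiplicative DNA recovery
#'   loss applied to fraction-level qPCR copies.
#'
#' @seealso [gradientDesign()], [simulateGradient()]
#' @export
setClass("GradientDesign",
  representation(n_fractions = "integer", density_grid = "numeric",
                 band_sd = "numeric", seq_depth = "numeric",
                 qpcr_cv = "numeric", initial_density = "numeric",
                 n_replicates = "integer", t_incubation = "numeric",
                 volume = "numeric", recovery_range = "numeric"))

setValidity("GradientDesign", function(object) {
  msg <- NULL
  if (length(object@density_grid) != object@n_fractions)
    msg <- c(msg, "density_grid must have n_fractions entries")
  if (any(diff(object@density_grid) <= 0))
    msg <- c(msg, "density_grid must be strictly increasing")
  if (object@band_sd <= 0) msg <- c(msg, "band_sd must be > 0")
  if (object@seq_depth <= 0) msg <- c(msg, "seq_depth must be > 0")
  if (object@qpcr_cv < 0) msg <- c(msg, "qpcr_cv must be >= 0")
  if (object@n_replicates < 1) msg <- c(msg, "need >= 1 replicate")
  if (object@t_incubation <= 0) msg <- c(msg, "t_incubation must be > 0")
  if (object@volume <= 0) msg <- c(msg, "volume must be > 0")
  rr <- object@recovery_range
  if (length(rr) != 2 || any(rr <= 0) || any(rr > 1) || rr[1] > rr[2])
    msg <- c(msg, "recovery_range must be within (0, 1] and ordered")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GradientDesign
#'
#' @param n_fractions fractions per tube (default 20).
#' @param density_grid buoyant densities (g/mL) of the fractions; by default
#'   an even grid over 1.650-1.795 g/mL, wide enough to hold unlabeled bands
#'   of 30-70% GC DNA and their fully 18O-labeled counterparts.
#' @param band_sd Gaussian spread (g/mL) of a taxon's DNA band
#'   (default 0.006).
#' @param seq_depth reads per fraction library (default 5e4).
#' @param qpcr_cv coefficient of variation of qPCR noise (default 0.1).
#' @param initial_density initial CsCl density, g/mL (default 1.718).
#' @param n_replicates replicate tubes per label (default 3).
#' @param t_incubation incubation, days (default 1).
#' @param volume fraction volume, uL (default 250).
#' @param recovery_range per-tube DNA recovery efficiency is drawn uniformly
#'   from this interval (default c(0.4, 0.9)).
#'
#' @return A [GradientDesign-class] object.
#' @examples
#' gradientDesign()
#' gradientDesign(n_fractions = 40, band_sd = 0.004)
#' @export
gradientDesign <- function(n_fractions = 20L, density_grid = NULL,
                           band_sd = 0.006, seq_depth = 5e4, qpcr_cv = 0.1,
                           initial_density = 1.718, n_replicates = 3L,
                           t_incubation = 1.0, volume = 250,
                           recovery_range = c(0.4, 0.9)) {
  n_fractions <- as.integer(n_fractions)
  if (is.null(density_grid))
    density_grid <- seq(1.650, 1.795, length.out = n_fractions)
  new("GradientDesign", n_fractions = n_fractions,
      density_grid = as.numeric(density_grid), band_sd = band_sd,
      seq_depth = seq_depth, qpcr_cv = qpcr_cv,
      initial_density = initial_density,
      n_replicates = as.integer(n_replicates), t_incubation = t_incubation,
      volume = volume, recovery_range = recovery_range)
}

#' @describeIn gradientDesign compact display.
#' @param object a `GradientDesign`.
#' @export
setMethod("show", "GradientDesign", function(object) {
  cat("GradientDesign:", object@n_fractions, "fractions,",
      sprintf("%.3f-%.3f g/mL,", min(object@density_grid),
              max(object@density_grid)),
      object@n_replicates, "replicates/label\n")
  cat("  band_sd:", object@band_sd, "g/mL | seq_depth:", object@seq_depth,
      "| qpcr_cv:", object@qpcr_cv, "| t:", object@t_incubation, "d\n")
  invisible(NULL)
})
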