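#' Physical constants of the qSIP density/molecular-weight mapping
#'
#' The mapping between the buoyant density of DNA in a CsCl gradient, its GC
#' content, and its average molecular weight per nucleotide underpins every
#' excess-atom-fraction (EAF) calculation in this package.  The constants are
#' the published qSIP values:
#'
#' * buoyant density (g/mL) of unlabeled DNA is affine in GC content:
#'   `density = density_slope * GC + density_intercept`;
#' * average nucleotide molecular weight of unlabeled DNA is affine in GC:
#'   `mw = mw_slope * GC + mw_intercept`;
#' * complete replacement of oxygen by 18O adds `mw_gain_18O` mass units per
#'   average nucleotide;
#' * the natural abundance of 18O is `natural_abundance_18O`, so the maximum
#'   attainable excess atom fraction is `1 - natural_abundance_18O`.
#'
#' They are centralized here so an alternative calibration can be substituted
#' consistently in both the estimator and the simulator.
#'
#' @param ... named overrides for any of the constants listed above.
#'
#' @return A named list with elements `density_slope`, `density_intercept`,
#'   `mw_slope`, `mw_intercept`, `mw_gain_18O`, `natural_abundance_18O`.
#'
#' @examples
#' qsipConstants()
#' qsipConstants(mw_gain_18O = 12.08)
#'
#' @export
qsipConstants <- function(...) {
  const <- list(
    density_slope         = 0.083506,
    density_intercept     = 1.646057,
    mw_slope              = 0.496,
    mw_intercept          = 307.691,
    mw_gain_18O           = 12.07747,
    natural_abundance_18O = 0.002000429
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    const[names(dots)] <- dots
  }
  const
}

#' GC content from the buoyant density of unlabeled DNA
#'
#' Inverts the affine density/GC calibration.  Values of `W_light` that imply
#' a GC content outside \[0, 1\] are clamped with a warning when
#' `clamp = TRUE`.
#'
#' @param W_light buoyant density (g/mL) of the unlabeled DNA of a taxon.
#' @param constants constants registry, see [qsipConstants()].
#' @param clamp clamp out-of-range GC values into \[0, 1\]?
#'
#' @return Numeric vector of GC contents (fraction in \[0, 1\] when clamped);
#'   the attribute `"clamped"` marks which elements were out of range.
#'
#' @examples
#' gcFromDensity(1.729563)  # 1.0
#' gcFromDensity(1.646057)  # 0.0
#'
#' @seealso [mwFromGc()], [eaf18O()]
#' @export
gcFromDensity <- function(W_light, constants = qsipConstants(), clamp = TRUE) {
  gc <- (W_light - constants$density_intercept) / constants$density_slope
  out <- !is.na(gc) & (gc < 0 | gc > 1)
  if (any(out)) {
    if (clamp) {
      warning(sum(out), " GC value(s) outside [0, 1]; clamped")
      gc <- pmin(pmax(gc, 0), 1)
    }
  }
  attr(gc, "clamped") <- out
  gc
}

#' Unlabeled DNA density implied by a GC content
#'
#' Forward affine GC -> density map; inverse of [gcFromDensity()].
#'
#' @inheritParams gcFromDensity
#' @param gc GC content (fraction in \[0, 1\]).
#' @return buoyant density (g/mL) of unlabeled DNA.
#' @export
densityFromGc <- function(gc, constants = qsipConstants()) {
  constants$density_intercept + constants$density_slope * gc
}

#' Average nucleotide molecular weight of unlabeled DNA
#'
#' @inheritParams densityFromGc
#' @return molecular weight (g/mol per average nucleotide).
#' @examples
#' mwFromGc(1)  # 308.187
#' @export
mwFromGc <- function(gc, constants = qsipConstants()) {
  constants$mw_intercept + constants$mw_slope * gc
}
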