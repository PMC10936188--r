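#' OTU-table and fraction filters and the qPCR recovery adjustment
#'
#' Four standard preprocessing steps of a heavy-water qSIP analysis:
#'
#' * `filterRareOtus()` drops OTUs whose share of the grand total of reads
#'   (computed before any removal) is below `min_frac`
#'   (default 5e-5, i.e. 0.005%); OTUs exactly at the threshold are kept.
#' * `filterPrevalence()` drops OTUs not present (non-zero total counts) in
#'   at least `min_reps` distinct replicates of any treatment-by-label
#'   group.
#' * `selectDensityWindow()` keeps fractions whose buoyant density lies in
#'   the closed interval `[lo, hi]` (default 1.69-1.74 g/mL, the window that
#'   holds essentially all DNA in a typical soil gradient) and errors,
#'   naming the tube, if a tube loses all of its fractions.
#' * `adjustRecovery()` computes, per tube, the DNA recovery efficiency
#'   `sum(copies_per_uL * volume) / unfractionated_total` and fills the
#'   `adjusted_copies` column of [fractionData()] with the per-fraction
#'   absolute copies divided by it, so the adjusted copies of each tube sum
#'   exactly to its unfractionated t_end total.  Efficiencies above 1 are
#'   kept with a warning; non-positive efficiencies are an error.
#'
#' All four are idempotent.  `adjustRecovery()` should run before
#' `selectDensityWindow()` so the efficiency uses every collected fraction.
#'
#' @param x a [QsipExperiment-class].
#' @param min_frac minimum share of the grand read total (default 5e-5).
#' @param min_reps minimum number of distinct replicates with non-zero
#'   counts (default 2).
#' @param lo,hi closed density window bounds in g/mL.
#'
#' @return The filtered / annotated [QsipExperiment-class].
#'
#' @examples
#' qse <- simulateQsipExperiment(simulateCommunity(20, seed = 1), seed = 2)
#' qse <- adjustRecovery(qse)
#' qse <- selectDensityWindow(qse, 1.65, 1.80)
#' qse <- filterPrevalence(filterRareOtus(qse))
#'
#' @name qsip-filters
NULL

#' @rdname qsip-filters
#' @export
setGeneric("filterRareOtus",
           function(x, min_frac = 5e-5) standardGeneric("filterRareOtus"))

#' @rdname qsip-filters
#' @export
setMethod("filterRareOtus", "QsipExperiment", function(x, min_frac = 5e-5) {
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty OTU table")
  cnt <- assay(x, "counts")
  grand <- sum(cnt)
  if (grand <= 0) stop("OTU table has no reads")
  keep <- rowSums(cnt) / grand >= min_frac
  x[keep, ]
})

#' @rdname qsip-filters
#' @export
setGeneric("filterPrevalence",
           function(x, min_reps = 2) standardGeneric("filterPrevalence"))

#' @rdname qsip-filters
#' @export
setMethod("filterPrevalence", "QsipExperiment", function(x, min_reps = 2) {
  cd <- colData(x)
  if (any(is.na(cd$replicate))) stop("replicate metadata is missing")
  cnt <- assay(x, "counts")
  grp <- paste(cd$treatment, cd$label)
  keep <- rep(FALSE, nrow(x))
  for (g in unique(grp)) {
    sel <- grp == g
    reps <- cd$replicate[sel]
    # distinct replicates in which each taxon has non-zero counts
    n_pres <- rep(0L, nrow(x))
    for (r in unique(reps)) {
      sub <- cnt[, sel, drop = FALSE][, reps == r, drop = FALSE]
      n_pres <- n_pres + (rowSums(sub) > 0)
    }
    keep <- keep | n_pres >= min_reps
  }
  x[keep, ]
})

#' @rdname qsip-filters
#' @export
setGeneric("selectDensityWindow",
           function(x, lo = 1.69, hi = 1.74)
             standardGeneric("selectDensityWindow"))

#' @rdname qsip-filters
#' @export
setMethod("selectDensityWindow", "QsipExperiment",
          function(x, lo = 1.69, hi = 1.74) {
  cd <- colData(x)
  if (any(!is.finite(cd$density))) stop("non-finite densities")
  keep <- cd$density >= lo & cd$density <= hi
  lost <- setdiff(unique(cd$sample_id), unique(cd$sample_id[keep]))
  if (length(lost))
    stop("density window [", lo, ", ", hi, "] leaves no fractions for ",
         "sample(s): ", paste(lost, collapse = ", "))
  x[, keep]
})

#' @rdname qsip-filters
#' @export
setGeneric("adjustRecovery", function(x) standardGeneric("adjustRecovery"))

#' @rdname qsip-filters
#' @export
setMethod("adjustRecovery", "QsipExperiment", function(x) {
  tot <- qsipTotals(x)
  if (is.null(tot)) stop("totals table required for recovery adjustment")
  cd <- colData(x)
  adjusted <- rep(NA_real_, ncol(x))
  for (sid in unique(cd$sample_id)) {
    sel <- cd$sample_id == sid
    unfrac <- tot$total_tend[match(sid, tot$sample_id)]
    if (!is.finite(unfrac) || unfrac <= 0)
      stop("unfractionated total for ", sid, " must be > 0")
    raw_abs <- cd$qpcr_copies_per_ul[sel] * cd$volume[sel]
    recovery <- sum(raw_abs) / unfrac
    if (recovery <= 0) stop("non-positive recovery efficiency for ", sid)
    if (recovery > 1)
      warning("recovery efficiency ", sprintf("%.3f", recovery), " > 1 for ",
              sid, "; kept")
    adjusted[sel] <- raw_abs / recovery
  }
  colData(x)$adjusted_copies <- adjusted
  x
})
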