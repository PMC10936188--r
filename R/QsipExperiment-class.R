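#' @import methods
#' @import S4Vectors
#' @import SummarizedExperiment
#' @importFrom stats quantile rnorm runif rlnorm rbeta rmultinom pnorm setNames
#' @importFrom utils read.delim write.table
NULL

.FRACTION_COLS <- c("sample_id", "replicate", "treatment", "label",
                    "fraction", "density", "volume", "qpcr_copies_per_ul")

#' QsipExperiment: a fractionated qSIP experiment
#'
#' Container for one or more density-gradient fractionation experiments: a
#' taxa-by-fraction count matrix (assay `"counts"`), per-fraction metadata in
#' `colData` (tube identity, replicate, treatment, 16O/18O label, fraction
#' index, buoyant density in g/mL, fraction volume in uL, and qPCR 16S
#' copies/uL, plus recovery-adjusted absolute copies once
#' [adjustRecovery()] has been run), and in `metadata()`:
#'
#' * `totals` — per-tube unfractionated qPCR totals at t0 and t_end
#'   (`sample_id`, `replicate`, `treatment`, `label`, `total_t0`,
#'   `total_tend`);
#' * `t0_counts` — taxa-by-tube counts of the unfractionated day-0 samples;
#' * `ground_truth` — the generating per-taxon parameters when the object was
#'   simulated (absent for real data).
#'
#' @slot ... inherits all slots from
#'   [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [QsipExperiment()] the constructor, [simulateQsipExperiment()],
#'   [fractionData()], [adjustRecovery()], [estimateEaf()]
#' @export
setClass("QsipExperiment", contains = "SummarizedExperiment")

.validQsipExperiment <- function(object) {
  msg <- NULL
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  cd <- colData(object)
  missing_cols <- setdiff(.FRACTION_COLS, colnames(cd))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  else {
    if (!all(cd$label %in% c("16O", "18O")))
      msg <- c(msg, "label must be one of '16O', '18O'")
    dens_ok <- is.finite(cd$density) & cd$density > 1.5 & cd$density < 1.9
    if (!all(dens_ok))
      msg <- c(msg, "densities must lie in (1.5, 1.9) g/mL")
    if (any(!is.finite(cd$volume) | cd$volume <= 0))
      msg <- c(msg, "fraction volumes must be positive")
    if (any(cd$qpcr_copies_per_ul < 0, na.rm = TRUE))
      msg <- c(msg, "qPCR copies must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated taxon ids")
  tot <- metadata(object)$totals
  if (!is.null(tot)) {
    need <- c("sample_id", "total_t0", "total_tend")
    if (!all(need %in% colnames(tot)))
      msg <- c(msg, "totals table needs sample_id, total_t0, total_tend")
    else if (length(missing_cols) == 0 &&
             !all(unique(cd$sample_id) %in% tot$sample_id))
      msg <- c(msg, "every sample_id in colData needs a row in totals")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("QsipExperiment", .validQsipExperiment)

#' Construct a QsipExperiment
#'
#' @param counts taxa-by-fraction matrix of sequence counts; column names
#'   must match `fractions$column_id` when given, otherwise
#'   `sample_id:fraction` ids are built from `fractions` row order.
#' @param fractions `data.frame` of per-fraction metadata with columns
#'   `sample_id`, `replicate`, `treatment`, `label` (`"16O"`/`"18O"`),
#'   `fraction`, `density` (g/mL), `volume` (uL), `qpcr_copies_per_ul`.
#' @param totals optional per-tube totals table (`sample_id`, `replicate`,
#'   `treatment`, `label`, `total_t0`, `total_tend`).
#' @param t0_counts optional taxa-by-tube count matrix of unfractionated
#'   day-0 samples (columns named by `sample_id`).
#' @param ground_truth optional per-taxon simulation ground truth.
#'
#' @return A [QsipExperiment-class] object.
#' @export
QsipExperiment <- function(counts, fractions, totals = NULL,
                           t0_counts = NULL, ground_truth = NULL) {
  counts <- as.matrix(counts)
  fractions <- as.data.frame(fractions)
  if (nrow(fractions) != ncol(counts))
    stop("fractions must have one row per count column")
  if (is.null(fractions$column_id))
    fractions$column_id <- paste0(fractions$sample_id, ":f",
                                  sprintf("%02d", fractions$fraction))
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), fractions$column_id))
      stop("count column names do not match fraction metadata column_id")
    fractions <- fractions[match(colnames(counts), fractions$column_id), ,
                           drop = FALSE]
  } else colnames(counts) <- fractions$column_id
  if (is.null(fractions$adjusted_copies))
    fractions$adjusted_copies <- NA_real_
  cd <- DataFrame(fractions, row.names = fractions$column_id)
  md <- list()
  if (!is.null(totals)) md$totals <- as.data.frame(totals)
  if (!is.null(t0_counts)) md$t0_counts <- as.matrix(t0_counts)
  if (!is.null(ground_truth)) md$ground_truth <- as.data.frame(ground_truth)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = md)
  new("QsipExperiment", se)
}

#' @describeIn QsipExperiment compact display.
#' @param object a `QsipExperiment`.
#' @export
setMethod("show", "QsipExperiment", function(object) {
  cd <- colData(object)
  cat("QsipExperiment:", nrow(object), "taxa x", ncol(object), "fractions\n")
  cat("  tubes:", length(unique(cd$sample_id)),
      "| treatments:", paste(unique(cd$treatment), collapse = ", "),
      "| labels:", paste(unique(cd$label), collapse = ", "), "\n")
  cat("  density range:", sprintf("%.4f-%.4f g/mL", min(cd$density),
                                  max(cd$density)), "\n")
  cat("  recovery-adjusted:",
      if (all(is.na(cd$adjusted_copies))) "no" else "yes", "\n")
  if (!is.null(metadata(object)$ground_truth))
    cat("  simulated (ground truth attached)\n")
  invisible(NULL)
})

#' Accessors for QsipExperiment components
#'
#' `fractionData()` returns the per-fraction metadata, `qsipTotals()` the
#' per-tube unfractionated qPCR totals, `t0Counts()` the day-0 unfractionated
#' count matrix, and `groundTruth()` the simulation ground truth (or `NULL`
#' for real data).
#'
#' @param x a [QsipExperiment-class].
#' @return `fractionData`: a [S4Vectors::DataFrame-class]; `qsipTotals` and
#'   `groundTruth`: `data.frame`s; `t0Counts`: a matrix.
#' @name qsip-accessors
NULL

#' @rdname qsip-accessors
#' @export
fractionData <- function(x) colData(x)

#' @rdname qsip-accessors
#' @export
qsipTotals <- function(x) metadata(x)$totals

#' @rdname qsip-accessors
#' @export
t0Counts <- function(x) metadata(x)$t0_counts

#' @rdname qsip-accessors
#' @export
groundTruth <- function(x) metadata(x)$ground_truth
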