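#' Read and write qSIP tables
#'
#' Plain-TSV interchange for a [QsipExperiment-class]: UTF-8, `.` decimal,
#' `NA` markers explicit.  `writeQsipTables()` writes four files into `dir`
#' (`counts.tsv` taxa x fraction columns, `fractions.tsv` per-fraction
#' metadata, `totals.tsv` per-tube qPCR totals, `t0_counts.tsv` day-0
#' unfractionated counts, plus `ground_truth.tsv` when present);
#' `readQsipTables()` reads them back, validating counts (non-negative,
#' unique taxon ids), labels and metadata links, so the round trip is the
#' identity.
#'
#' @param x a [QsipExperiment-class].
#' @param dir directory for the TSV files (created if needed).
#'
#' @return `writeQsipTables()` the directory invisibly;
#'   `readQsipTables()` a [QsipExperiment-class].
#'
#' @examples
#' qse <- simulateQsipExperiment(simulateCommunity(5, seed = 1), seed = 2)
#' d <- file.path(tempdir(), "qsip_demo")
#' writeQsipTables(qse, d)
#' qse2 <- readQsipTables(d)
#'
#' @name qsip-io
NULL

#' @rdname qsip-io
#' @export
writeQsipTables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f, rn = FALSE)
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = rn, col.names = if (rn) NA else TRUE)
  wt(assay(x, "counts"), "counts.tsv", rn = TRUE)
  wt(as.data.frame(colData(x)), "fractions.tsv")
  if (!is.null(qsipTotals(x))) wt(qsipTotals(x), "totals.tsv")
  if (!is.null(t0Counts(x))) wt(t0Counts(x), "t0_counts.tsv", rn = TRUE)
  if (!is.null(groundTruth(x))) wt(groundTruth(x), "ground_truth.tsv")
  invisible(dir)
}

#' @rdname qsip-io
#' @export
readQsipTables <- function(dir) {
  rd <- function(f, rn = FALSE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    read.delim(p, check.names = FALSE, row.names = if (rn) 1 else NULL)
  }
  counts <- rd("counts.tsv", rn = TRUE)
  fractions <- rd("fractions.tsv")
  if (is.null(counts) || is.null(fractions))
    stop("counts.tsv and fractions.tsv are required in ", dir)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(fractions$adjusted_copies))
    fractions$adjusted_copies <- as.numeric(fractions$adjusted_copies)
  if (anyDuplicated(rownames(counts))) stop("duplicated taxon ids")
  if (any(counts < 0)) stop("negative counts in counts.tsv")
  if (!all(fractions$label %in% c("16O", "18O")))
    stop("unknown isotope label(s): ",
         paste(setdiff(fractions$label, c("16O", "18O")), collapse = ", "))
  t0c <- rd("t0_counts.tsv", rn = TRUE)
  if (!is.null(t0c)) {
    t0c <- as.matrix(t0c)
    storage.mode(t0c) <- "double"
  }
  QsipExperiment(counts, fractions, totals = rd("totals.tsv"),
                 t0_counts = t0c,
                 ground_truth = rd("ground_truth.tsv"))
}

#' Pipeline configuration
#'
#' Assembles (and validates) the thresholds and settings consumed by
#' [runQsipPipeline()]; `writeQsipConfig()` / `readQsipConfig()` round-trip
#' it through YAML unchanged.
#'
#' @param min_frac rare-OTU threshold (share of grand read total).
#' @param min_reps prevalence threshold (distinct replicates).
#' @param density_lo,density_hi closed density window (g/mL).
#' @param n_boot,alpha,boot_seed bootstrap settings, see
#'   [bootstrapConfig()].
#' @param t_incubation incubation time, days.
#' @param water_o_fraction see [fractionNewDna()].
#' @param config a config list as returned by `qsipConfig()`.
#' @param path YAML file path.
#'
#' @return `qsipConfig()` and `readQsipConfig()` a named list;
#'   `writeQsipConfig()` the path invisibly.
#' @examples
#' cfg <- qsipConfig(min_frac = 1e-4)
#' p <- tempfile(fileext = ".yaml")
#' writeQsipConfig(cfg, p)
#' identical(readQsipConfig(p), cfg)
#' @export
qsipConfig <- function(min_frac = 5e-5, min_reps = 2, density_lo = 1.69,
                       density_hi = 1.74, n_boot = 1000, alpha = 0.05,
                       boot_seed = 1, t_incubation = 1.0,
                       water_o_fraction = 1.0) {
  stopifnot(min_frac >= 0, min_frac < 1, min_reps >= 1,
            density_lo > 1.5, density_hi < 1.9, density_lo < density_hi,
            n_boot >= 100, alpha > 0, alpha < 1, t_incubation > 0,
            water_o_fraction > 0, water_o_fraction <= 1)
  list(min_frac = min_frac, min_reps = as.integer(min_reps),
       density_lo = density_lo, density_hi = density_hi,
       n_boot = as.integer(n_boot), alpha = alpha,
       boot_seed = as.integer(boot_seed), t_incubation = t_incubation,
       water_o_fraction = water_o_fraction)
}

#' @rdname qsipConfig
#' @export
writeQsipConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname qsipConfig
#' @export
readQsipConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(qsipConfig, cfg)
}
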