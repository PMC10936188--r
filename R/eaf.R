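#' Abundance-weighted mean buoyant density
#'
#' The buoyant density of a taxon in one tube is the mean of the fraction
#' densities weighted by the taxon's DNA mass in each fraction,
#' `W = sum(density * y) / sum(y)`, where `y` is the taxon's relative
#' abundance in a fraction times that fraction's (recovery-adjusted)
#' absolute 16S copies.
#'
#' @param weights per-fraction weights `y` (non-negative).
#' @param densities per-fraction buoyant densities (g/mL).
#'
#' @return The weighted density `W` (g/mL), or `NA` if all weights are zero
#'   (taxon absent from every fraction).
#'
#' @examples
#' weightedDensity(c(1, 3), c(1.70, 1.74))  # 1.73
#'
#' @export
weightedDensity <- function(weights, densities) {
  if (length(weights) != length(densities))
    stop("weights and densities differ in length")
  if (any(weights < 0, na.rm = TRUE)) stop("negative weights")
  s <- sum(weights, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  sum(weights * densities, na.rm = TRUE) / s
}

#' Per-taxon weighted densities and total abundances across tubes
#'
#' Computes, for every taxon in every tube, the abundance-weighted mean
#' buoyant density `W` and the total recovery-adjusted copies attributed to
#' the taxon over the retained fractions.
#'
#' @param x a [QsipExperiment-class]; run [adjustRecovery()] first (or use
#'   `weighting = "relative"` to weight by relative abundance alone, which
#'   gives identical `W` when all fraction totals are equal).
#' @param weighting `"copies"` (relative abundance times adjusted copies,
#'   the default) or `"relative"`.
#'
#' @return `data.frame` with one row per taxon and tube: `taxon_id`,
#'   `sample_id`, `replicate`, `treatment`, `label`, `W`, `total_abund`.
#'   `W` is `NA` where the taxon is absent from every fraction of a tube.
#'
#' @export
taxonDensity <- function(x, weighting = c("copies", "relative")) {
  weighting <- match.arg(weighting)
  cd <- colData(x)
  cnt <- assay(x, "counts")
  if (weighting == "copies" && all(is.na(cd$adjusted_copies)))
    stop("adjusted copies missing; run adjustRecovery() first")
  out <- NULL
  for (sid in unique(cd$sample_id)) {
    sel <- cd$sample_id == sid
    sub <- cnt[, sel, drop = FALSE]
    ftot <- colSums(sub)
    rel <- sweep(sub, 2, ifelse(ftot > 0, ftot, 1), "/")
    fw <- if (weighting == "copies") cd$adjusted_copies[sel] else rep(1, sum(sel))
    y <- sweep(rel, 2, fw, "*")
    tot <- rowSums(y)
    W <- ifelse(tot > 0, as.vector(y %*% cd$density[sel]) / tot, NA_real_)
    out <- rbind(out, data.frame(
      taxon_id = rownames(x), sample_id = sid,
      replicate = cd$replicate[sel][1], treatment = cd$treatment[sel][1],
      label = cd$label[sel][1], W = W, total_abund = tot,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Excess atom fraction 18O from paired buoyant densities
#'
#' Converts the weighted buoyant densities of a taxon in the labeled
#' (`W_lab`) and unlabeled (`W_light`) tubes into molecular weights and the
#' excess atom fraction 18O:
#'
#' * `gc = (W_light - 1.646057) / 0.083506` (GC from the unlabeled density),
#' * `m_light = 0.496 * gc + 307.691`,
#' * `m_lab = (W_lab / W_light) * m_light`,
#' * `m_heavy_max = m_light + 12.07747` (every oxygen atom 18O),
#' * `eaf = (m_lab - m_light) / (m_heavy_max - m_light) *
#'   (1 - 0.002000429)`,
#'
#' with the constants taken from `constants`.  Negative point estimates are
#' reported as-is; activity is decided only by the bootstrap CI rule (see
#' [callActive()]).
#'
#' @param W_lab weighted density (g/mL) in the 18O tubes.
#' @param W_light weighted density (g/mL) in the paired 16O tubes of the
#'   same treatment.
#' @param constants see [qsipConstants()].
#' @param clamp_gc clamp implied GC contents into \[0, 1\] (with warning)?
#'
#' @return `data.frame` with columns `gc`, `m_light`, `m_lab`,
#'   `m_heavy_max`, `eaf`.  Rows with missing `W_light` are `NA`
#'   throughout.
#'
#' @examples
#' eaf18O(1.7300, 1.7300)$eaf  # 0: no density shift
#'
#' @export
eaf18O <- function(W_lab, W_light, constants = qsipConstants(),
                   clamp_gc = TRUE) {
  n <- max(length(W_lab), length(W_light))
  W_lab <- rep_len(W_lab, n)
  W_light <- rep_len(W_light, n)
  gc <- as.numeric(gcFromDensity(W_light, constants, clamp = clamp_gc))
  m_light <- mwFromGc(gc, constants)
  m_lab <- (W_lab / W_light) * m_light
  m_heavy_max <- m_light + constants$mw_gain_18O
  eaf <- (m_lab - m_light) / (m_heavy_max - m_light) *
    (1 - constants$natural_abundance_18O)
  data.frame(gc = gc, m_light = m_light, m_lab = m_lab,
             m_heavy_max = m_heavy_max, eaf = eaf)
}

#' Per-taxon EAF point estimates for each treatment
#'
#' Averages each taxon's weighted density over the 16O replicates in which
#' it is present (`W_light`) and over the 18O replicates (`W_lab`) of the
#' same treatment, then applies [eaf18O()].  Taxa with no usable 16O
#' partner density are skipped with an attribute record.
#'
#' @inheritParams taxonDensity
#' @param densities optional precomputed output of [taxonDensity()].
#'
#' @return `data.frame` with one row per taxon and treatment: `taxon_id`,
#'   `treatment`, `W_light`, `W_lab`, `n_light_reps`, `n_lab_reps`, `gc`,
#'   `m_light`, `m_lab`, `m_heavy_max`, `eaf`.  The attribute `"skipped"`
#'   lists taxa without a 16O partner.
#'
#' @export
estimateEaf <- function(x, densities = NULL,
                        weighting = c("copies", "relative"),
                        constants = qsipConstants()) {
  weighting <- match.arg(weighting)
  if (is.null(densities)) densities <- taxonDensity(x, weighting)
  out <- NULL
  for (tr in unique(densities$treatment)) {
    d <- densities[densities$treatment == tr, ]
    light <- d[d$label == "16O", ]
    lab <- d[d$label == "18O", ]
    W_light <- tapply(light$W, light$taxon_id, mean, na.rm = TRUE)
    W_lab <- tapply(lab$W, lab$taxon_id, mean, na.rm = TRUE)
    taxa <- sort(union(names(W_light), names(W_lab)))
    Wl <- W_light[taxa]; Wh <- W_lab[taxa]
    res <- eaf18O(as.numeric(Wh), as.numeric(Wl), constants)
    out <- rbind(out, data.frame(
      taxon_id = taxa, treatment = tr,
      W_light = as.numeric(Wl), W_lab = as.numeric(Wh),
      n_light_reps = as.integer(tapply(!is.na(light$W), light$taxon_id,
                                       sum)[taxa]),
      n_lab_reps = as.integer(tapply(!is.na(lab$W), lab$taxon_id,
                                     sum)[taxa]),
      res, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  skipped <- out$taxon_id[!is.finite(out$W_light)]
  attr(out, "skipped") <- unique(skipped)
  out
}
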