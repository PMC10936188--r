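#' Unlabeled gene copies at the end of the incubation
#'
#' Under the labeling model, newly synthesized DNA carries the maximal 18O
#' load while pre-existing DNA keeps its light molecular weight, so the
#' unlabeled share of a taxon's copies follows from its measured labeled
#' molecular weight:
#' `n_light_t = n_t * (m_heavy_max - m_lab) / (m_heavy_max - m_light)`.
#'
#' @param n_t total copies at the end of the incubation.
#' @param m_lab,m_light,m_heavy_max molecular weights from [eaf18O()].
#' @param clamp clamp `m_lab` into `[m_light, m_heavy_max]` (noise can push
#'   it outside) so `0 <= n_light_t <= n_t`?
#'
#' @return unlabeled copies at t_end (vectorized).
#'
#' @examples
#' unlabeledCopies(100, 310, 308, 320)
#'
#' @export
unlabeledCopies <- function(n_t, m_lab, m_light, m_heavy_max, clamp = TRUE) {
  if (any(m_heavy_max == m_light, na.rm = TRUE))
    stop("degenerate molecular weights: m_heavy_max == m_light")
  if (clamp) m_lab <- pmin(pmax(m_lab, m_light), m_heavy_max)
  n_t * (m_heavy_max - m_lab) / (m_heavy_max - m_light)
}

#' Per-capita reproduction, mortality and net growth rates
#'
#' Exponential birth-death model: reproduction is read from the emergence
#' of labeled copies, mortality from the loss of unlabeled copies,
#'
#' * `b = log(n_t / n_light_t) / t`  (day^-1, >= 0),
#' * `d = log(n_light_t / n0) / t`   (day^-1, <= 0),
#' * `r = b + d = log(n_t / n0) / t`,
#'
#' the identity `r = b + d` holding exactly.  With `clamp = TRUE` (default)
#' `d` is truncated at 0 and `b` at 0 when sampling noise pushes them past
#' the boundary, with the `flag` column recording it.
#'
#' @param n0 copies at t0 (> 0).
#' @param n_t copies at t_end (> 0).
#' @param n_light_t unlabeled copies at t_end (0 < n_light_t <= n_t);
#'   `n_light_t = 0` leaves `b` undefined (`NA`, flagged).
#' @param t incubation time in days (> 0).
#' @param clamp enforce `b >= 0`, `d <= 0`?
#'
#' @return `data.frame` with columns `b`, `d`, `r`, `flag` (`""`, `"b=NA"`,
#'   `"b<0"`, `"d>0"`).
#'
#' @examples
#' perCapitaRates(100, 200, 50, 1)  # b = log(4), d = log(1/2), r = log(2)
#'
#' @export
perCapitaRates <- function(n0, n_t, n_light_t, t = 1, clamp = TRUE) {
  if (t <= 0) stop("t must be > 0")
  if (any(n0 <= 0, na.rm = TRUE) || any(n_t <= 0, na.rm = TRUE))
    stop("n0 and n_t must be > 0")
  if (any(n_light_t < 0, na.rm = TRUE)) stop("n_light_t must be >= 0")
  if (any(n_light_t > n_t, na.rm = TRUE) && !clamp)
    stop("n_light_t exceeds n_t")
  flag <- rep("", length(n_t))
  b <- log(n_t / n_light_t) / t
  b[n_light_t == 0] <- NA_real_
  flag[n_light_t == 0] <- "b=NA"
  d <- log(n_light_t / n0) / t
  d[n_light_t == 0] <- NA_real_
  if (clamp) {
    flag[!is.na(b) & b < 0] <- "b<0"
    flag[!is.na(d) & d > 0] <- "d>0"
    b <- pmax(b, 0)
    d <- pmin(d, 0)
  }
  data.frame(b = b, d = d, r = b + d, flag = flag,
             stringsAsFactors = FALSE)
}

#' Absolute taxon abundance from relative abundance and a qPCR total
#'
#' `n = rel_abund * total_copies`; used at t0 with the unfractionated day-0
#' totals and at t_end by summing a taxon's recovery-adjusted copies over
#' the retained fractions.
#'
#' @param rel_abund relative abundances (rows sum to 1 per sample).
#' @param total_copies unfractionated qPCR total of the sample.
#' @return absolute copies, same shape as `rel_abund`.
#' @examples
#' absoluteTaxonAbundance(0.01, 1e8)  # 1e6
#' @export
absoluteTaxonAbundance <- function(rel_abund, total_copies) {
  if (any(total_copies <= 0, na.rm = TRUE)) stop("totals must be > 0")
  rel_abund * total_copies
}

#' Per-taxon rate table for each treatment
#'
#' Combines the EAF molecular weights with abundance measurements: `n0` is
#' the taxon's day-0 relative abundance (counts pooled over tubes) times
#' the mean unfractionated t0 total, and `n_t` the per-tube sum of its
#' recovery-adjusted copies over retained fractions averaged across tubes.
#' By default both the 16O and 18O tubes contribute to the abundance
#' estimates — the day-0 state precedes labeling and the paired microcosms
#' run in parallel, so all six tubes measure the same quantities — while
#' the unlabeled pool is derived from the 18O molecular-weight shift via
#' [unlabeledCopies()] and the rates via [perCapitaRates()].  Taxa present
#' at t_end but absent at t0 get `n0` floored at one copy and are flagged
#' `"n0_floor"`.
#'
#' @param x a [QsipExperiment-class] (recovery-adjusted).
#' @param eaf output of [estimateEaf()] (computed if `NULL`).
#' @param t incubation time in days.
#' @param clamp see [perCapitaRates()].
#' @param abundance_labels tubes used for the abundance estimates:
#'   `"all"` (default) or `"18O"` only.
#' @param constants see [qsipConstants()].
#'
#' @return `data.frame` per taxon and treatment: `taxon_id`, `treatment`,
#'   `n0`, `n_t`, `n_light_t`, `b`, `d`, `r`, `flag`.
#'
#' @export
estimateRates <- function(x, eaf = NULL, t = 1, clamp = TRUE,
                          abundance_labels = c("all", "18O"),
                          constants = qsipConstants()) {
  abundance_labels <- match.arg(abundance_labels)
  if (is.null(eaf)) eaf <- estimateEaf(x, constants = constants)
  ab <- .taxonAbundances(x)
  tot <- qsipTotals(x)
  t0c <- t0Counts(x)
  out <- NULL
  for (tr in unique(eaf$treatment)) {
    e <- eaf[eaf$treatment == tr, ]
    keep_lab <- if (abundance_labels == "all") c("16O", "18O") else "18O"
    a <- ab[ab$treatment == tr & ab$label %in% keep_lab, ]
    tubes <- unique(a$sample_id)
    pooled <- rowSums(t0c[, tubes, drop = FALSE])
    p0 <- pooled / sum(pooled)
    tot_tr <- tot[tot$sample_id %in% tubes, ]
    n0 <- (p0 * mean(tot_tr$total_t0))[e$taxon_id]
    n_t <- tapply(a$n_t, a$taxon_id, mean)[e$taxon_id]
    flag0 <- rep("", nrow(e))
    floor_idx <- !is.na(n0) & n0 <= 0 & !is.na(n_t) & n_t > 0
    n0[floor_idx] <- 1
    flag0[floor_idx] <- "n0_floor"
    ok <- is.finite(n0) & is.finite(n_t) & n0 > 0 & n_t > 0 &
      is.finite(e$m_lab)
    n_light <- rep(NA_real_, nrow(e))
    n_light[ok] <- unlabeledCopies(n_t[ok], e$m_lab[ok], e$m_light[ok],
                                   e$m_heavy_max[ok], clamp = clamp)
    rt <- data.frame(b = NA_real_, d = NA_real_, r = NA_real_, flag = "",
                     stringsAsFactors = FALSE)[rep(1, nrow(e)), ]
    if (any(ok))
      rt[ok, ] <- perCapitaRates(n0[ok], n_t[ok], n_light[ok], t = t,
                                 clamp = clamp)
    rt$flag <- ifelse(flag0 != "", paste0(flag0, ";", rt$flag), rt$flag)
    out <- rbind(out, data.frame(
      taxon_id = e$taxon_id, treatment = tr, n0 = as.numeric(n0),
      n_t = as.numeric(n_t), n_light_t = n_light, rt,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# per-tube absolute taxon abundances at t0 (from unfractionated day-0
# counts x t0 total) and t_end (sum of adjusted copies over fractions)
.taxonAbundances <- function(x) {
  cd <- colData(x)
  tot <- qsipTotals(x)
  t0c <- t0Counts(x)
  if (is.null(tot) || is.null(t0c))
    stop("totals and t0 counts are required for abundance estimation")
  if (all(is.na(cd$adjusted_copies)))
    stop("adjusted copies missing; run adjustRecovery() first")
  cnt <- assay(x, "counts")
  out <- NULL
  for (sid in unique(cd$sample_id)) {
    sel <- cd$sample_id == sid
    sub <- cnt[, sel, drop = FALSE]
    ftot <- colSums(sub)
    rel <- sweep(sub, 2, ifelse(ftot > 0, ftot, 1), "/")
    y <- sweep(rel, 2, cd$adjusted_copies[sel], "*")
    n_t <- rowSums(y)
    rel0 <- t0c[, sid] / sum(t0c[, sid])
    n0 <- absoluteTaxonAbundance(rel0,
                                 tot$total_t0[match(sid, tot$sample_id)])
    out <- rbind(out, data.frame(
      taxon_id = rownames(x), sample_id = sid,
      replicate = cd$replicate[sel][1], treatment = cd$treatment[sel][1],
      label = cd$label[sel][1], n0 = as.numeric(n0[rownames(x)]),
      n_t = n_t, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Abundance-weighted community rates and mean life span
#'
#' Community-level reproduction, mortality and net growth are the
#' abundance-weighted means of the per-taxon rates (taxa with undefined
#' rates are dropped from numerator and denominator alike), and the mean
#' life span of an active cell is the multiplicative inverse of the
#' community mortality rate.
#'
#' @param rates per-taxon rate table ([estimateRates()] output, or any
#'   `data.frame` with `b`, `d`, `r`).
#' @param weights per-taxon weights; defaults to the t_end abundance column
#'   `n_t` (set `weight_time = "t0"` to weight by `n0`).
#' @param weight_time `"tend"` or `"t0"`; ignored when `weights` is given.
#' @param active_only restrict the average to taxa flagged active (requires
#'   an `active` column)?
#'
#' @return `data.frame` with `b_comm`, `d_comm`, `r_comm` (day^-1) and
#'   `mean_lifespan` (days).
#'
#' @examples
#' communityRates(data.frame(b = c(0.2, 0.4), d = c(-0.3, -0.3),
#'                           r = c(-0.1, 0.1)), weights = c(1, 1))
#'
#' @export
communityRates <- function(rates, weights = NULL,
                           weight_time = c("tend", "t0"),
                           active_only = FALSE) {
  weight_time <- match.arg(weight_time)
  if (is.null(weights)) {
    col <- if (weight_time == "tend") "n_t" else "n0"
    if (!col %in% colnames(rates))
      stop("no weights given and no '", col, "' column present")
    weights <- rates[[col]]
  }
  if (active_only) {
    if (!"active" %in% colnames(rates))
      stop("active_only = TRUE needs an 'active' column")
    keep <- rates$active %in% TRUE
    rates <- rates[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  wmean <- function(v) {
    ok <- is.finite(v) & is.finite(weights) & weights >= 0
    if (!any(ok)) stop("no taxa with defined rates")
    sum(weights[ok] * v[ok]) / sum(weights[ok])
  }
  b <- wmean(rates$b); d <- wmean(rates$d)
  data.frame(b_comm = b, d_comm = d, r_comm = b + d,
             mean_lifespan = meanLifespan(d))
}

#' Mean microbial life span from a mortality rate
#'
#' The multiplicative inverse of the magnitude of the per-capita mortality
#' rate: a community mortality of 0.27 day^-1 corresponds to a mean active
#' life span of 3.7 days.
#'
#' @param d per-capita mortality rate (day^-1, sign ignored).
#' @return mean life span in days.
#' @examples
#' meanLifespan(-0.27)
#' @export
meanLifespan <- function(d) {
  if (any(d == 0, na.rm = TRUE)) stop("mortality rate of 0 has no ",
                                      "finite life span")
  1 / abs(d)
}
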