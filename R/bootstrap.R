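#' Bootstrap configuration
#'
#' Settings for the replicate-resampling bootstrap used for EAF and rate
#' confidence intervals.  Replicates (tubes) are the resampling unit; with
#' three replicates per label the percentile interval is approximate, which
#' is why activity calls use the interval bound rather than its nominal
#' level.
#'
#' @param n_boot number of bootstrap resamples (>= 100, default 1000).
#' @param alpha two-sided miscoverage level (default 0.05 for 95% CIs).
#' @param seed integer seed making the resampling deterministic.
#' @param resample_unit only `"replicate"` is supported.
#'
#' @return A validated list of class `BootstrapConfig`.
#' @examples
#' bootstrapConfig(n_boot = 2000, seed = 7)
#' @export
bootstrapConfig <- function(n_boot = 1000, alpha = 0.05, seed = 1,
                            resample_unit = "replicate") {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!identical(resample_unit, "replicate"))
    stop("only replicate resampling is supported")
  structure(list(n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed), resample_unit = resample_unit),
            class = "BootstrapConfig")
}

#' Percentile bootstrap over replicates
#'
#' Draws `n_boot` resamples of replicate labels with replacement and
#' recomputes `statistic` on each, returning the point estimate (statistic
#' on the original replicates) and the percentile confidence interval at
#' level `1 - alpha`.  When `replicates2` is supplied (e.g. the 16O tubes
#' paired with resampled 18O tubes) both sides are resampled jointly and
#' `statistic(r1, r2)` is called with two lists.
#'
#' @param replicates list of per-replicate inputs (length >= 2).
#' @param statistic function of one (or two) lists of replicates returning
#'   a numeric scalar or vector.
#' @param cfg a [bootstrapConfig()].
#' @param replicates2 optional second list of replicates, resampled
#'   independently.
#'
#' @return list with `point`, `ci_low`, `ci_high` (each the shape of the
#'   statistic) and `prop_defined`, the share of resamples in which the
#'   statistic was finite; entries defined in fewer than half of the
#'   resamples get `NA` intervals.
#'
#' @examples
#' cfg <- bootstrapConfig(n_boot = 500, seed = 1)
#' bootstrapStatistic(as.list(c(0.1, 0.2, 0.3)),
#'                    function(r) mean(unlist(r)), cfg)
#'
#' @export
bootstrapStatistic <- function(replicates, statistic, cfg = bootstrapConfig(),
                               replicates2 = NULL) {
  if (length(replicates) < 2) stop("need >= 2 replicates")
  set.seed(cfg$seed)
  two <- !is.null(replicates2)
  point <- if (two) statistic(replicates, replicates2) else
    statistic(replicates)
  n1 <- length(replicates)
  res <- matrix(NA_real_, cfg$n_boot, length(point))
  for (b in seq_len(cfg$n_boot)) {
    r1 <- replicates[sample.int(n1, n1, replace = TRUE)]
    res[b, ] <- if (two) {
      n2 <- length(replicates2)
      statistic(r1, replicates2[sample.int(n2, n2, replace = TRUE)])
    } else statistic(r1)
  }
  pr <- colMeans(is.finite(res))
  qs <- apply(res, 2, quantile, probs = c(cfg$alpha / 2, 1 - cfg$alpha / 2),
              na.rm = TRUE, names = FALSE)
  ci_low <- qs[1, ]; ci_high <- qs[2, ]
  ci_low[pr < 0.5] <- NA_real_
  ci_high[pr < 0.5] <- NA_real_
  list(point = point, ci_low = ci_low, ci_high = ci_high,
       prop_defined = pr)
}

# rate chain shared by the point estimator and the bootstrap: floors n0,
# derives the unlabeled pool and the (b, d, r) rates, all NA-tolerant
.chainRates <- function(n0, n_t, m_lab, m_light, m_heavy_max, t, clamp) {
  n0 <- ifelse(!is.na(n0) & n0 <= 0 & !is.na(n_t) & n_t > 0, 1, n0)
  ok <- is.finite(n0) & is.finite(n_t) & n0 > 0 & n_t > 0 & is.finite(m_lab)
  n_light <- b <- d <- rep(NA_real_, length(n_t))
  if (any(ok)) {
    n_light[ok] <- unlabeledCopies(n_t[ok], m_lab[ok], m_light[ok],
                                   m_heavy_max[ok], clamp = clamp)
    rt <- perCapitaRates(n0[ok], n_t[ok], pmax(n_light[ok], 0), t = t,
                         clamp = clamp)
    b[ok] <- rt$b; d[ok] <- rt$d
  }
  list(n_light = n_light, b = b, d = d, r = b + d)
}

#' Bootstrap EAF and rate confidence intervals for a qSIP experiment
#'
#' Runs the full estimator chain (replicate-mean weighted densities,
#' molecular weights, EAF, unlabeled pool, per-capita rates) on `n_boot`
#' joint resamples of the 18O and 16O replicate tubes within each
#' treatment, and attaches percentile confidence intervals and active-taxon
#' calls to the point estimates.
#'
#' @param x a [QsipExperiment-class], recovery-adjusted and filtered.
#' @param cfg a [bootstrapConfig()].
#' @param t incubation time in days.
#' @param clamp see [perCapitaRates()].
#' @param joint resample the 16O side together with the 18O side (default),
#'   or keep the observed 16O replicates fixed (`FALSE`).
#' @param constants see [qsipConstants()].
#'
#' @return `data.frame` per taxon and treatment with the point estimates
#'   `eaf`, `b`, `d`, `r`, their `*_ci_low`/`*_ci_high` percentile bounds,
#'   the share of resamples in which the EAF was defined (`prop_defined`),
#'   and the `active` flag (`eaf_ci_low > 0`, strictly; taxa with missing
#'   CIs are inactive and flagged).
#'
#' @export
qsipBootstrap <- function(x, cfg = bootstrapConfig(), t = 1, clamp = TRUE,
                          joint = TRUE, constants = qsipConstants()) {
  set.seed(cfg$seed)
  dens <- taxonDensity(x)
  ab <- .taxonAbundances(x)
  eaf_pt <- estimateEaf(x, densities = dens, constants = constants)
  rates_pt <- estimateRates(x, eaf = eaf_pt, t = t, clamp = clamp,
                            constants = constants)
  out <- NULL
  for (tr in unique(eaf_pt$treatment)) {
    e <- eaf_pt[eaf_pt$treatment == tr, ]
    taxa <- e$taxon_id
    d_tr <- dens[dens$treatment == tr, ]
    a_lab <- ab[ab$treatment == tr & ab$label == "18O", ]
    a_light <- ab[ab$treatment == tr & ab$label == "16O", ]
    Wl <- .wideBy(d_tr[d_tr$label == "16O", ], "W", taxa)
    Wb <- .wideBy(d_tr[d_tr$label == "18O", ], "W", taxa)
    N0b <- .wideBy(a_lab, "n0", taxa); N0l <- .wideBy(a_light, "n0", taxa)
    Ntb <- .wideBy(a_lab, "n_t", taxa); Ntl <- .wideBy(a_light, "n_t", taxa)
    nL <- ncol(Wl); nB <- ncol(Wb)
    if (nL < 2 || nB < 2) stop("need >= 2 replicates per label in ", tr)
    B <- cfg$n_boot
    eafM <- bM <- dM <- rM <- matrix(NA_real_, B, length(taxa))
    for (bb in seq_len(B)) {
      iB <- sample.int(nB, nB, replace = TRUE)
      iL <- if (joint) sample.int(nL, nL, replace = TRUE) else seq_len(nL)
      W_light <- rowMeans(Wl[, iL, drop = FALSE], na.rm = TRUE)
      W_lab <- rowMeans(Wb[, iB, drop = FALSE], na.rm = TRUE)
      em <- eaf18O(W_lab, W_light, constants, clamp_gc = FALSE)
      n0m <- (rowMeans(N0b[, iB, drop = FALSE]) +
                rowMeans(N0l[, iL, drop = FALSE])) / 2
      ntm <- (rowMeans(Ntb[, iB, drop = FALSE]) +
                rowMeans(Ntl[, iL, drop = FALSE])) / 2
      ch <- .chainRates(n0m, ntm, em$m_lab, em$m_light, em$m_heavy_max,
                        t, clamp)
      eafM[bb, ] <- em$eaf
      bM[bb, ] <- ch$b; dM[bb, ] <- ch$d; rM[bb, ] <- ch$r
    }
    ci <- function(M) apply(M, 2, quantile,
                            probs = c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                            na.rm = TRUE, names = FALSE)
    suppressWarnings({
      qe <- ci(eafM); qb <- ci(bM); qd <- ci(dM); qr <- ci(rM)
    })
    pr <- colMeans(is.finite(eafM))
    bad <- pr < 0.5
    qe[, bad] <- NA_real_
    rr <- rates_pt[match(paste(taxa, tr), paste(rates_pt$taxon_id,
                                                rates_pt$treatment)), ]
    res <- data.frame(
      taxon_id = taxa, treatment = tr, eaf = e$eaf,
      eaf_ci_low = qe[1, ], eaf_ci_high = qe[2, ],
      b = rr$b, b_ci_low = qb[1, ], b_ci_high = qb[2, ],
      d = rr$d, d_ci_low = qd[1, ], d_ci_high = qd[2, ],
      r = rr$r, r_ci_low = qr[1, ], r_ci_high = qr[2, ],
      n_t = rr$n_t, n0 = rr$n0, prop_defined = pr,
      stringsAsFactors = FALSE)
    res$active <- callActive(res)
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}

# long -> wide matrix of one value column by taxon x replicate
.wideBy <- function(d, col, taxa) {
  reps <- sort(unique(d$sample_id))
  M <- matrix(NA_real_, length(taxa), length(reps),
              dimnames = list(taxa, reps))
  idx <- cbind(match(d$taxon_id, taxa), match(d$sample_id, reps))
  keep <- !is.na(idx[, 1])
  M[idx[keep, , drop = FALSE]] <- d[[col]][keep]
  M
}

#' Call taxa active from their EAF confidence intervals
#'
#' A taxon is active when the lower bound of its 95% bootstrap confidence
#' interval on the excess atom fraction 18O is strictly greater than zero.
#' Taxa with missing intervals are called inactive and recorded in the
#' `"missing_ci"` attribute.
#'
#' @param eaf_ci `data.frame` with an `eaf_ci_low` column (and optionally
#'   `taxon_id`).
#' @return logical vector of activity calls.
#' @examples
#' callActive(data.frame(eaf_ci_low = c(-0.01, 0, 0.01)))
#' @export
callActive <- function(eaf_ci) {
  if (!"eaf_ci_low" %in% colnames(eaf_ci)) stop("eaf_ci_low column required")
  lo <- eaf_ci$eaf_ci_low
  act <- !is.na(lo) & lo > 0
  attr(act, "missing_ci") <-
    if ("taxon_id" %in% colnames(eaf_ci)) eaf_ci$taxon_id[is.na(lo)] else
      which(is.na(lo))
  act
}

#' Summarize active-taxon counts
#'
#' @param active logical activity calls (one per taxon), or a
#'   `data.frame` with an `active` column.
#' @param exclude taxa (names or indices) excluded from the summary, e.g.
#'   OTUs unclassified at the phylum level.
#' @param taxon_id taxon names matching `active` (needed only with
#'   `exclude`).
#'
#' @return `data.frame` with `n_total`, `n_active`, `pct_active` (percent,
#'   rounded to the nearest integer).
#' @examples
#' summarizeActivity(rep(c(TRUE, FALSE), c(547, 596 - 547)))  # 92%
#' @export
summarizeActivity <- function(active, exclude = NULL, taxon_id = NULL) {
  if (is.data.frame(active)) {
    taxon_id <- active$taxon_id
    active <- active$active
  }
  if (!is.null(exclude)) {
    drop <- if (is.character(exclude)) taxon_id %in% exclude else
      seq_along(active) %in% exclude
    active <- active[!drop]
  }
  n_total <- length(active)
  n_active <- sum(active, na.rm = TRUE)
  data.frame(n_total = n_total, n_active = n_active,
             pct_active = round(100 * n_active / n_total))
}
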