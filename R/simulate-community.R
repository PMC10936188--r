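#' Simulate a soil community with known qSIP ground truth
#'
#' Draws a community of taxa with lognormal absolute abundances, uniform GC
#' contents, and per-capita reproduction (`b_true`, day^-1, >= 0) and
#' mortality (`d_true`, day^-1, <= 0) rates.  The taxon-level excess atom
#' fraction a heavy-water gradient experiment would measure is derived from
#' the reproduction rate under the labeling model's own assumptions (all
#' newly synthesized DNA is fully labeled, old DNA is lost at the same rate
#' regardless of label):
#'
#' `true_eaf = (1 - exp(-b_true * t)) * (1 - natural_abundance_18O)`
#'
#' so that a noise-free gradient simulation and the estimator chain agree on
#' both the EAF and the (b, d, r) rates.  `true_eaf` is an ordinary column:
#' overwrite it before calling [simulateGradient()] to probe the EAF
#' estimator at arbitrary enrichment levels (rate recovery is then
#' meaningless by construction).
#'
#' @param n_taxa number of taxa (>= 1).
#' @param seed integer seed; identical seeds give identical communities.
#' @param abundance_law distribution of absolute 16S copies per g soil at
#'   t0; a list such as `list(dist = "lognormal", meanlog = 10, sdlog = 2)`
#'   (the only distribution currently supported).
#' @param gc_range range of GC contents (default 0.3-0.7).
#' @param b_max upper bound of reproduction rates; `b_true` is drawn as
#'   `b_max * Beta(2, 6)` (day^-1, mostly < 0.5).
#' @param d_range range of mortality magnitudes; `-d_true` is drawn
#'   uniformly in it (default 0.15-0.7 day^-1, matching field-scale
#'   community mortality of a few tenths per day).
#' @param t_incubation incubation time (days) used to couple `true_eaf` to
#'   `b_true` (default 1).
#' @param constants see [qsipConstants()].
#'
#' @return `data.frame` with one row per taxon: `taxon_id`, `gc`, `n0`,
#'   `b_true`, `d_true`, `r_true`, `true_eaf`.
#'
#' @examples
#' comm <- simulateCommunity(10, seed = 1)
#' all(comm$r_true == comm$b_true + comm$d_true)
#'
#' @export
simulateCommunity <- function(n_taxa, seed,
                              abundance_law = list(dist = "lognormal",
                                                   meanlog = 10, sdlog = 2),
                              gc_range = c(0.3, 0.7), b_max = 1,
                              d_range = c(0.15, 0.7), t_incubation = 1,
                              constants = qsipConstants()) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (!is.list(abundance_law) || is.null(abundance_law$dist))
    stop("abundance_law must be a list with a 'dist' element")
  set.seed(seed)
  n0 <- switch(abundance_law$dist,
    lognormal = {
      if (is.null(abundance_law$meanlog) || is.null(abundance_law$sdlog))
        stop("lognormal abundance_law needs meanlog and sdlog")
      rlnorm(n_taxa, abundance_law$meanlog, abundance_law$sdlog)
    },
    stop("unsupported abundance distribution: ", abundance_law$dist)
  )
  gc <- runif(n_taxa, gc_range[1], gc_range[2])
  b <- b_max * rbeta(n_taxa, 2, 6)
  d <- -runif(n_taxa, d_range[1], d_range[2])
  stopifnot(all(abs(d) <= 1))
  eaf <- (1 - exp(-b * t_incubation)) * (1 - constants$natural_abundance_18O)
  data.frame(
    taxon_id = sprintf("OTU_%04d", seq_len(n_taxa)),
    gc = gc, n0 = n0, b_true = b, d_true = d, r_true = b + d,
    true_eaf = eaf, stringsAsFactors = FALSE
  )
}
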