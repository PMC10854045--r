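# Synthetic two-group expression with planted rank-reversal structure.
#
# The generator emulates the one mechanism the classifier exploits: in
# fusion-positive (TFP) samples the anchor gene's expression rises above a
# small set of partner genes that it sits just below in fusion-negative
# (TFN) samples. Everything is log-normal; only within-sample orderings
# matter downstream, so no attempt is made at a realistic microarray error
# model. Background genes come in three dispersion classes so that the
# stability screen has genuine stable and unstable strata to find; the
# anchor/partner block sits in the sparse upper tail of the baseline
# distribution so that the anchor's crossing window is essentially free of
# background genes and the planted partners are the only high-quality
# classifying pairs. Anchor noise is kept below partner noise so that the
# five pairs err on different samples and majority voting genuinely helps.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's standard validation conditions: 1000
#' genes, 100 TFN + 50 TFP samples, 5 planted partners, log2-scale noise
#' 0.5 and an anchor shift of 1.75 (3.5 noise SDs), giving per-pair
#' reversal probabilities of roughly 0.75-0.80 in TFP and around 0.01 in
#' TFN — deliberately imperfect single pairs that a majority vote over
#' several partners genuinely improves.
#'
#' @param n_genes total genes, including anchor and partners.
#' @param n_tfn,n_tfp samples per group.
#' @param n_planted_partners partner genes whose rank the anchor crosses.
#' @param erg_shift log2-scale rise of the anchor mean in TFP samples.
#' @param noise_sd log2-scale noise unit: background genes get
#'   `noise_sd/5` (stable class), `noise_sd` (normal) or `3*noise_sd`
#'   (unstable); partners get `noise_sd`, the anchor `noise_sd/2`.
#' @param frac_stable fraction of background genes in the stable (and,
#'   symmetrically, in the unstable) dispersion class.
#' @param monotone_distort apply a random strictly increasing per-sample
#'   transform to the finished matrix (see [distort_monotone()]).
#' @param seed integer seed; the generator is fully reproducible.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000L, n_tfn = 100L, n_tfp = 50L,
                       n_planted_partners = 5L, erg_shift = 1.75,
                       noise_sd = 0.5, frac_stable = 0.2,
                       monotone_distort = FALSE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfn = as.integer(n_tfn),
              n_tfp = as.integer(n_tfp),
              n_planted_partners = as.integer(n_planted_partners),
              erg_shift = erg_shift, noise_sd = noise_sd,
              frac_stable = frac_stable,
              monotone_distort = isTRUE(monotone_distort),
              seed = as.integer(seed))
  if (cfg$n_genes <= cfg$n_planted_partners + 1L)
    stop("n_genes must exceed n_planted_partners + 1")
  if (cfg$n_tfn < 1L || cfg$n_tfp < 1L)
    stop("need at least one sample per group")
  if (cfg$n_planted_partners < 1L) stop("need at least one planted partner")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$erg_shift < 0) stop("erg_shift must be nonnegative")
  if (cfg$frac_stable < 0 || cfg$frac_stable > 0.5)
    stop("frac_stable must be in [0, 0.5]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-group expression matrix with planted reversals
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expression` (genes x samples matrix),
#'   `labels` (named TFP/TFN vector), `planted_partners` (gene ids),
#'   `background_class` (named vector: stable / normal / unstable),
#'   and `config`.
#' @export
simulate_expression <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  n_bg <- cfg$n_genes - cfg$n_planted_partners - 1L
  anchor <- "ERG"
  partners <- sprintf("PTN%02d", seq_len(cfg$n_planted_partners))
  bg <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(anchor, partners, bg)
  samples <- c(sprintf("N%03d", seq_len(cfg$n_tfn)),
               sprintf("P%03d", seq_len(cfg$n_tfp)))
  labels <- stats::setNames(rep(c("TFN", "TFP"), c(cfg$n_tfn, cfg$n_tfp)),
                            samples)

  # background dispersion classes
  n_stable <- floor(cfg$frac_stable * n_bg)
  bg_class <- rep("normal", n_bg)
  if (n_stable > 0L) {
    bg_class[sample.int(n_bg, 2L * n_stable)] <-
      rep(c("stable", "unstable"), each = n_stable)
  }
  bg_sd <- c(stable = cfg$noise_sd / 5, normal = cfg$noise_sd,
             unstable = 3 * cfg$noise_sd)[bg_class]

  # baselines: background log2-means from N(5, 1); the anchor/partner
  # block sits at 9.5, deep in the upper tail, so the anchor's crossing
  # window holds (almost) no background genes
  mu_bg <- stats::rnorm(n_bg, mean = 5, sd = 1)
  mu_sig <- 9.5
  mu_partner <- mu_sig + stats::runif(cfg$n_planted_partners, 0, 0.1)
  mu_anchor <- min(mu_partner) - 2.6 * cfg$noise_sd

  mu <- c(mu_anchor, mu_partner, mu_bg)
  sdv <- c(cfg$noise_sd / 2, rep(cfg$noise_sd, cfg$n_planted_partners),
           bg_sd)
  n_s <- length(samples)
  logx <- matrix(mu, nrow = cfg$n_genes, ncol = n_s) +
    matrix(stats::rnorm(cfg$n_genes * n_s), cfg$n_genes, n_s) * sdv
  logx[1L, labels == "TFP"] <- logx[1L, labels == "TFP"] + cfg$erg_shift
  x <- 2^logx
  dimnames(x) <- list(genes, samples)
  if (cfg$monotone_distort)
    x <- distort_monotone(x, seed = cfg$seed + 1L)
  list(expression = x, labels = labels, planted_partners = partners,
       background_class = stats::setNames(bg_class, bg), config = cfg)
}

#' Apply a random strictly increasing transform to each sample
#'
#' Emulates platform or normalization differences: each column is passed
#' through an independent random piecewise-linear strictly increasing map,
#' which changes every value but preserves all within-sample orderings
#' (and hence every downstream classification) exactly.
#'
#' @param x numeric matrix, genes x samples.
#' @param seed integer seed; the same seed reproduces the same transforms.
#' @param knots number of interior knots of each piecewise-linear map.
#' @return matrix of the same shape and dimnames.
#' @export
distort_monotone <- function(x, seed = 1L, knots = 5L) {
  check_expression(x)
  set.seed(as.integer(seed))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    lo <- min(col); hi <- max(col)
    if (hi <= lo) { # constant column: any increasing affine map works
      out[, j] <- col * stats::runif(1L, 0.5, 2) + stats::runif(1L, 0, 1)
      next
    }
    xin <- c(lo, sort(stats::runif(knots, lo, hi)), hi)
    yout <- cumsum(stats::rexp(knots + 2L))
    out[, j] <- stats::approx(xin, yout, xout = col, ties = "ordered")$y
  }
  out
}
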