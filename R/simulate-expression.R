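#' Specification for a simulated diel expression time course
#'
#' Describes a gene-by-time-point Poisson count matrix emulating an RNA-seq
#' diel sampling design: time points every \code{interval_h} hours over two
#' days (12 samples of 4 h by default, starting at ZT1). A fraction of genes
#' is planted as rhythmic: their expected expression is cosine-modulated on a
#' log2 scale around a gene-specific mean, with peak phases recycled over
#' \code{phases_zt} so phase groups are balanced. Counts are drawn as
#' \deqn{x_{gs} \sim Poisson(c_s\, \mu_g\, m_g(t_s)),\qquad
#'       m_g(t) = 2^{(A/2)\cos(2\pi (t-\phi_g)/24)}}
#' where \eqn{c_s} are per-library size factors and \eqn{A} is the
#' peak-to-trough log2 fold change for rhythmic genes (\eqn{m_g \equiv 1}
#' otherwise).
#'
#' @param n_genes number of genes.
#' @param n_timepoints number of samples (default 12).
#' @param interval_h sampling interval in hours (default 4).
#' @param start_zt ZT of the first sample (default 1: sampling begins one
#'   hour after lights-on).
#' @param frac_rhythmic fraction of genes planted rhythmic, in [0, 1].
#' @param amplitude_logfc peak-to-trough log2 fold change of rhythmic genes
#'   (> 0; default 2, i.e. four-fold).
#' @param phases_zt peak phases (ZT hours) assigned to rhythmic genes by
#'   recycling (default the six sampled ZTs 1, 5, ..., 21).
#' @param mean_log_expr named numeric \code{c(meanlog=, sdlog=)}: log-normal
#'   parameters of the per-gene mean count \eqn{\mu_g} (natural-log scale).
#'   Default meanlog = log(100), sdlog = 1.
#' @param size_factors per-sample positive scalars \eqn{c_s}; length must be
#'   \code{n_timepoints}. Default all 1.
#' @param seed integer seed.
#' @return An object of class \code{expression_sim_spec}.
#' @export
expression_sim_spec <- function(n_genes,
                                n_timepoints = 12,
                                interval_h = 4,
                                start_zt = 1,
                                frac_rhythmic = 0.1,
                                amplitude_logfc = 2,
                                phases_zt = c(1, 5, 9, 13, 17, 21),
                                mean_log_expr = c(meanlog = log(100), sdlog = 1),
                                size_factors = NULL,
                                seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stop("invalid spec: n_genes must be a positive count")
  }
  if (frac_rhythmic < 0 || frac_rhythmic > 1) {
    stop("invalid spec: frac_rhythmic must lie in [0, 1]")
  }
  stopifnot(n_timepoints >= 4, interval_h > 0, amplitude_logfc > 0,
            all(c("meanlog", "sdlog") %in% names(mean_log_expr)))
  if (is.null(size_factors)) size_factors <- rep(1, n_timepoints)
  if (length(size_factors) != n_timepoints) {
    stop("invalid spec: size_factors length must equal n_timepoints")
  }
  if (any(size_factors <= 0)) stop("invalid spec: size_factors must be > 0")
  structure(
    list(n_genes = as.integer(n_genes), n_timepoints = as.integer(n_timepoints),
         interval_h = interval_h, start_zt = start_zt,
         frac_rhythmic = frac_rhythmic, amplitude_logfc = amplitude_logfc,
         phases_zt = phases_zt, mean_log_expr = mean_log_expr,
         size_factors = size_factors, seed = as.integer(seed)),
    class = "expression_sim_spec"
  )
}

# sample labels "ZT<h>_day<d>" for a diel sampling design
sample_labels <- function(n_timepoints, interval_h, start_zt) {
  t_abs <- start_zt + interval_h * (seq_len(n_timepoints) - 1L)
  sprintf("ZT%g_day%d", t_abs %% 24, 1L + t_abs %/% 24)
}

#' Simulate a diel Poisson count matrix with known ground truth
#'
#' @param spec an [expression_sim_spec()].
#' @return A list with \code{counts} (integer matrix, genes x samples;
#'   columns labelled \code{ZT<h>_day<d>}) and \code{truth} (per-gene
#'   \code{rhythmic_flag}, \code{true_phase_zt} (NA for arrhythmic genes),
#'   per-gene mean \code{mu}, and \code{true_size_factors}).
#' @export
simulate_expression_timecourse <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  S <- spec$n_timepoints
  zt_abs <- spec$start_zt + spec$interval_h * (seq_len(S) - 1L)
  mu <- stats::rlnorm(G, spec$mean_log_expr[["meanlog"]],
                      spec$mean_log_expr[["sdlog"]])
  n_rhy <- round(spec$frac_rhythmic * G)
  rhythmic <- rep(FALSE, G)
  if (n_rhy > 0) rhythmic[sample.int(G, n_rhy)] <- TRUE
  phase <- rep(NA_real_, G)
  if (n_rhy > 0) {
    phase[rhythmic] <- rep_len(spec$phases_zt, n_rhy)
  }
  lambda <- matrix(mu, G, S)
  if (n_rhy > 0) {
    mod <- 2^((spec$amplitude_logfc / 2) *
                cos(2 * pi * outer(phase[rhythmic], zt_abs, function(p, t)
                  (t - p)) / 24))
    lambda[rhythmic, ] <- lambda[rhythmic, , drop = FALSE] * mod
  }
  lambda <- sweep(lambda, 2, spec$size_factors, `*`)
  counts <- matrix(stats::rpois(G * S, lambda), G, S)
  rownames(counts) <- sprintf("gene_%05d", seq_len(G))
  colnames(counts) <- sample_labels(S, spec$interval_h, spec$start_zt)
  list(counts = counts,
       truth = list(rhythmic_flag = stats::setNames(rhythmic, rownames(counts)),
                    true_phase_zt = stats::setNames(phase, rownames(counts)),
                    mu = stats::setNames(mu, rownames(counts)),
                    true_size_factors = stats::setNames(spec$size_factors,
                                                        colnames(counts))))
}

#' Simulate a pair of replicate sequencing libraries
#'
#' Two independent Poisson libraries sharing per-gene expected counts but
#' scaled by library-specific factors, as when two libraries are built from
#' different animals collected at the same time point.
#'
#' @param means per-gene expected counts (>= 0).
#' @param factors two positive library scale factors.
#' @param seed integer seed.
#' @return A list with integer vectors \code{lib1} and \code{lib2}.
#' @export
simulate_replicate_pair <- function(means, factors = c(1, 1), seed = 1L) {
  if (any(means < 0)) stop("means must be non-negative")
  stopifnot(length(factors) == 2L, all(factors > 0))
  set.seed(as.integer(seed))
  list(lib1 = stats::rpois(length(means), factors[1] * means),
       lib2 = stats::rpois(length(means), factors[2] * means))
}
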