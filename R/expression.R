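#' Filter aligned-read records and remove start-position duplicates
#'
#' Keeps only uniquely aligned records with at most two mismatches, then
#' removes duplicate reads sharing a (gene, strand, start) triple — likely
#' PCR artifacts — keeping the first occurrence. Idempotent.
#'
#' @param records data frame with columns \code{gene_id}, \code{start}
#'   (0-based), \code{strand} (\code{"+"}/\code{"-"}), \code{mismatches},
#'   \code{uniquely_aligned} (logical).
#' @param max_mismatches mismatch ceiling (default 2).
#' @return The surviving records, original order preserved.
#' @export
filter_and_dedup <- function(records, max_mismatches = 2) {
  stopifnot(all(c("gene_id", "start", "strand", "mismatches",
                  "uniquely_aligned") %in% names(records)))
  keep <- records$uniquely_aligned & records$mismatches <= max_mismatches
  out <- records[keep, , drop = FALSE]
  dup <- duplicated(paste(out$gene_id, out$strand, out$start, sep = "\r"))
  out[!dup, , drop = FALSE]
}

#' Tally filtered records into a count-matrix column
#'
#' @param records filtered/de-duplicated read records (see
#'   [filter_and_dedup()]).
#' @param gene_ids the genes of the count matrix, in order.
#' @param sample_label label attached to the column.
#' @return Named integer vector of per-gene counts. Records for genes not in
#'   \code{gene_ids} are skipped with a warning.
#' @export
tally_counts <- function(records, gene_ids, sample_label = NULL) {
  unknown <- setdiff(unique(records$gene_id), gene_ids)
  if (length(unknown)) {
    warning("skipping records for ", length(unknown),
            " unknown gene id(s): ", paste(utils::head(unknown, 5),
                                           collapse = ", "))
    records <- records[records$gene_id %in% gene_ids, , drop = FALSE]
  }
  counts <- table(factor(records$gene_id, levels = gene_ids))
  out <- stats::setNames(as.integer(counts), gene_ids)
  if (!is.null(sample_label)) attr(out, "sample_label") <- sample_label
  out
}

#' Poisson-weighted trimmed-mean-of-M-values normalization
#'
#' Scales libraries so that the trimmed, weighted mean of per-gene log-fold
#' changes against a pseudo-reference vanishes. The pseudo-reference is the
#' per-gene geometric mean across samples over genes positive everywhere
#' (no single time point is privileged). For each sample the M-values
#' \eqn{M_g = \log_2(x_{gs}/ref_g)} are trimmed to the interquartile half
#' (values below the 25th or above the 75th percentile dropped) and the
#' survivors averaged with weights \eqn{w_g = 1/sd_g}, where
#' \eqn{sd_g = \sqrt{1/x_{gs} + 1/ref_g}} is the delta-method SD of an
#' M-value under Poisson counting noise. Then
#' \eqn{\log_2 c_s = \sum w_g M_g / \sum w_g} and the normalized matrix is
#' \eqn{\log_2 x_{gs} - \log_2 c_s}.
#'
#' Genes with a zero count in any sample are excluded from factor
#' estimation (their log-fold is undefined); they stay in the normalized
#' matrix with a 0.5 pseudocount and are flagged.
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @return A list of class \code{poisson_tmm}: \code{size_factors}
#'   (\eqn{c_s > 0}), \code{log2_size_factors}, \code{normalized} (log2
#'   matrix), \code{zero_flagged} (gene ids given the pseudocount), and
#'   \code{detail} — one data frame per sample with gene, \code{M},
#'   \code{weight}, \code{trimmed}.
#' @export
poisson_tmm_normalize <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) < 8) {
    stop(structure(class = c("normalization_failed", "error", "condition"),
                   list(message = paste0("normalization failed: only ",
                                         sum(pos), " genes positive in all ",
                                         "samples (need >= 8)"),
                        call = sys.call(-1))))
  }
  xp <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(xp)))           # geometric mean pseudo-reference
  log2c <- numeric(ncol(counts))
  detail <- vector("list", ncol(counts))
  names(detail) <- colnames(counts)
  for (s in seq_len(ncol(counts))) {
    x <- xp[, s]
    M <- log2(x / ref)
    w <- 1 / sqrt(1 / x + 1 / ref)
    q <- stats::quantile(M, c(0.25, 0.75), names = FALSE)
    keep <- M >= q[1] & M <= q[2]
    log2c[s] <- sum(w[keep] * M[keep]) / sum(w[keep])
    detail[[s]] <- data.frame(gene_id = rownames(xp), M = M, weight = w,
                              trimmed = !keep, row.names = NULL)
  }
  normalized <- sweep(log2(counts + 0.5 * (counts == 0)), 2, log2c)
  structure(list(size_factors = stats::setNames(2^log2c, colnames(counts)),
                 log2_size_factors = stats::setNames(log2c, colnames(counts)),
                 normalized = normalized,
                 zero_flagged = rownames(counts)[!pos],
                 detail = detail),
            class = "poisson_tmm")
}

#' Replicate concordance against the 99% Poisson region
#'
#' Given two replicate libraries, a gene is concordant when its count in
#' library 1 lies within the central (equal-tail, 0.5% per side) 99% region
#' of Binomial(x1 + x2, N1/(N1+N2)) — the conditional distribution of x1
#' given the gene total under independent Poisson sampling with library
#' totals N1, N2. Genes with zero total in both libraries are ignored.
#'
#' @param lib1,lib2 equal-length count vectors with positive totals.
#' @return Fraction of informative genes that are concordant, in [0, 1].
#' @export
replicate_concordance <- function(lib1, lib2) {
  stopifnot(length(lib1) == length(lib2))
  n1 <- sum(lib1); n2 <- sum(lib2)
  if (n1 + n2 == 0) stop("both libraries are all-zero; concordance undefined")
  tot <- lib1 + lib2
  use <- tot > 0
  p <- n1 / (n1 + n2)
  lo <- stats::qbinom(0.005, tot[use], p)
  hi <- stats::qbinom(0.995, tot[use], p)
  mean(lib1[use] >= lo & lib1[use] <= hi)
}

# positive-frequency FFT powers of a mean-centered series plus the index of
# the target-period bin (must fall on the natural grid)
fft_powers <- function(series, interval_h, target_period_h) {
  n <- length(series)
  k0 <- n * interval_h / target_period_h
  if (abs(k0 - round(k0)) > 1e-9 || round(k0) < 1 || round(k0) > n %/% 2) {
    stop("target period ", target_period_h,
         " h is not on the natural FFT grid of this series")
  }
  x <- series - mean(series)
  P <- Mod(stats::fft(x))^2
  list(power = P[1 + seq_len(n %/% 2)], k0 = as.integer(round(k0)))
}

#' Spectral g-factor: fraction of power at the 24-h frequency
#'
#' The g-factor of a time course is the ratio of the periodogram power at
#' the frequency corresponding to the target (24-h) period to the summed
#' power over all positive frequencies up to Nyquist, after mean-centering
#' (so the DC term, which reflects expression level rather than
#' rhythmicity, is excluded). Values near 1 indicate a nearly pure 24-h
#' rhythm. The harmonics variant adds the powers of on-grid higher
#' harmonics (12 h, 8 h, ...) to the numerator, which credits non-sinusoidal
#' 24-h waveforms.
#'
#' @param series per-time-point values (length >= 4; typically 12 samples
#'   every 4 h).
#' @param interval_h sampling interval in hours (default 4).
#' @param target_period_h rhythm period (default 24; must be representable
#'   on the natural FFT grid of the series).
#' @param include_harmonics include on-grid harmonics of the target
#'   frequency in the numerator (default FALSE).
#' @return g in [0, 1]; a constant series returns 0 with attribute
#'   \code{degenerate = TRUE}.
#' @export
g_factor <- function(series, interval_h = 4, target_period_h = 24,
                     include_harmonics = FALSE) {
  series <- as.numeric(series)
  stopifnot(length(series) >= 4)
  if (isTRUE(all.equal(stats::sd(series), 0))) {
    return(structure(0, degenerate = TRUE))
  }
  fp <- fft_powers(series, interval_h, target_period_h)
  num_bins <- if (include_harmonics) {
    seq(fp$k0, length(fp$power), by = fp$k0)
  } else fp$k0
  unname(sum(fp$power[num_bins]) / sum(fp$power))
}

#' g-factor table for a normalized expression matrix
#'
#' @param mat numeric matrix, genes x time points (normalized log2
#'   expression by default; raw counts are also accepted).
#' @param interval_h,target_period_h see [g_factor()].
#' @return Data frame with \code{gene_id}, \code{g}, \code{g_harmonic}.
#' @export
g_factor_table <- function(mat, interval_h = 4, target_period_h = 24) {
  stopifnot(is.matrix(mat))
  data.frame(
    gene_id = rownames(mat),
    g = apply(mat, 1, g_factor, interval_h = interval_h,
              target_period_h = target_period_h),
    g_harmonic = apply(mat, 1, g_factor, interval_h = interval_h,
                       target_period_h = target_period_h,
                       include_harmonics = TRUE),
    row.names = NULL)
}

#' Select diel cycle genes by g-factor cutoff
#'
#' @param g_table data frame from [g_factor_table()] (columns
#'   \code{gene_id}, \code{g}).
#' @param cutoff strict lower bound on g (default 0.5): a gene is selected
#'   iff g > cutoff.
#' @return Character vector of selected gene ids, with the cutoff attached
#'   as attribute \code{cutoff}.
#' @export
select_dcgs <- function(g_table, cutoff = 0.5) {
  stopifnot(all(c("gene_id", "g") %in% names(g_table)),
            all(g_table$g >= 0 & g_table$g <= 1))
  structure(g_table$gene_id[g_table$g > cutoff], cutoff = cutoff)
}

# circular mean of hour values on a 24-h clock, in [0, 24)
circular_mean_zt <- function(zt) {
  zt <- zt[!is.na(zt)]
  if (!length(zt)) return(NA_real_)
  ang <- 2 * pi * zt / 24
  (atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)) %% 24
}

#' K-means clustering of diel genes into phase groups
#'
#' Profiles are z-scored per gene (so clustering groups temporal shapes,
#' not expression levels) and partitioned by Euclidean K-means, keeping the
#' best of \code{restarts} seeded random initializations by total
#' within-cluster sum of squares. Clusters are relabelled 1..K by ascending
#' circular-mean peak ZT of their member genes, giving a reproducible,
#' phase-ordered labelling.
#'
#' @param profiles numeric matrix, genes x time points, with row names.
#' @param K number of clusters (default 5).
#' @param seed integer seed for the initializations.
#' @param restarts number of random starts (default 50).
#' @param interval_h,start_zt sampling design, for peak-ZT estimation.
#' @return A list of class \code{phase_clusters}: \code{assignment} (named
#'   integer in 1..K), \code{K}, \code{centers} (reordered), \code{peak_zt}
#'   (per gene), \code{cluster_peak_zt}, \code{empty} (logical per cluster;
#'   clusters left empty when there are fewer distinct profiles than K),
#'   \code{seed}, \code{restarts}, \code{tot_withinss}.
#' @export
kmeans_phase_clusters <- function(profiles, K = 5, seed = 1L, restarts = 50,
                                  interval_h = 4, start_zt = 1) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= K)
  Z <- t(apply(profiles, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  peaks <- vapply(rownames(profiles), function(g) {
    pp <- estimate_peak_zt(profiles[g, ], interval_h = interval_h,
                           start_zt = start_zt)
    pp$peak_zt
  }, numeric(1))
  n_distinct <- nrow(unique(Z))
  if (n_distinct < K) {
    # degenerate: fewer distinct temporal shapes than clusters
    grp <- match(apply(Z, 1, paste, collapse = "\r"),
                 unique(apply(Z, 1, paste, collapse = "\r")))
    assignment <- stats::setNames(grp, rownames(profiles))
    centers <- unique(Z)
    empty <- c(rep(FALSE, n_distinct), rep(TRUE, K - n_distinct))
  } else {
    set.seed(as.integer(seed))
    km <- stats::kmeans(Z, centers = K, nstart = restarts, iter.max = 100)
    cl_peak <- vapply(seq_len(K), function(k)
      circular_mean_zt(peaks[km$cluster == k]), numeric(1))
    ord <- order(cl_peak, na.last = TRUE)
    relabel <- match(seq_len(K), ord)
    assignment <- stats::setNames(relabel[km$cluster], rownames(profiles))
    centers <- km$centers[ord, , drop = FALSE]
    rownames(centers) <- seq_len(K)
    empty <- rep(FALSE, K)
  }
  cluster_peak <- vapply(seq_len(K), function(k) {
    if (any(assignment == k)) circular_mean_zt(peaks[assignment == k])
    else NA_real_
  }, numeric(1))
  structure(list(assignment = assignment, K = K, centers = centers,
                 peak_zt = peaks, cluster_peak_zt = cluster_peak,
                 empty = empty, seed = seed, restarts = restarts,
                 tot_withinss = if (exists("km", inherits = FALSE))
                   km$tot.withinss else 0),
            class = "phase_clusters")
}

#' Peak Zeitgeber time of a diel expression profile
#'
#' The phase of the 24-h discrete-Fourier component, converted to the clock
#' time of maximal expression: a pure cosine peaking at ZT p returns p.
#'
#' @param profile per-time-point values.
#' @param interval_h sampling interval (default 4 h).
#' @param start_zt ZT of the first sample (default 1).
#' @param target_period_h rhythm period (default 24 h; must lie on the
#'   natural FFT grid).
#' @return A list of class \code{peak_phase}: \code{peak_zt} in [0, 24)
#'   (\code{NA} with \code{degenerate = TRUE} when the 24-h power is zero)
#'   and \code{amplitude} (modulus of the 24-h component, 2|X_k|/n).
#' @export
estimate_peak_zt <- function(profile, interval_h = 4, start_zt = 1,
                             target_period_h = 24) {
  profile <- as.numeric(profile)
  stopifnot(length(profile) >= 4)
  n <- length(profile)
  k0 <- n * interval_h / target_period_h
  if (abs(k0 - round(k0)) > 1e-9) {
    stop("target period not on the natural FFT grid")
  }
  k0 <- as.integer(round(k0))
  x <- profile - mean(profile)
  X <- stats::fft(x)[k0 + 1L]
  amp <- 2 * Mod(X) / n
  if (Mod(X) < 1e-12 * max(1, sum(abs(x)))) {
    return(structure(list(peak_zt = NA_real_, amplitude = 0,
                          degenerate = TRUE), class = "peak_phase"))
  }
  theta <- Arg(X)
  # x_t ~ cos(2*pi*(zt_t - p)/T) with zt_t = start_zt + interval*t gives
  # theta = 2*pi*(start_zt - p)/T  =>  p = start_zt - T*theta/(2*pi)
  peak <- (start_zt - target_period_h * theta / (2 * pi)) %% 24
  structure(list(peak_zt = peak, amplitude = amp, degenerate = FALSE),
            class = "peak_phase")
}

#' Average replicate columns of a (normalized) matrix
#'
#' Columns sharing a sample label (e.g. the duplicated time-point library)
#' are averaged after normalization, before rhythm scoring.
#'
#' @param mat numeric matrix with column names; replicate columns share a
#'   name.
#' @return Matrix with one column per distinct label, in first-appearance
#'   order.
#' @export
collapse_replicates <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  labs <- unique(colnames(mat))
  out <- vapply(labs, function(l)
    rowMeans(mat[, colnames(mat) == l, drop = FALSE]), numeric(nrow(mat)))
  colnames(out) <- labs
  out
}
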