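#' Assemble a pipeline run configuration
#'
#' Bundles the parameters of the full simulate - behavior - expression -
#' compare pipeline. Every numeric parameter is range-checked here so a
#' malformed configuration fails before any computation.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @param n_animals,duration_h,condition activity-cohort design (defaults:
#'   35 animals, 72 h, LD).
#' @param n_genes,frac_rhythmic expression design (defaults 2000, 0.09).
#' @param period_min,period_max,period_step periodogram grid (16-32 h,
#'   0.01-h step).
#' @param n_permutations,alpha rhythm-test settings (1000, 0.05).
#' @param g_cutoff g-factor cutoff for DCG selection (0.5).
#' @param K phase clusters (5).
#' @param fold_threshold day/night fold-change threshold (3).
#' @param homolog_table path to a homolog day/night count TSV; defaults to
#'   the packaged larval table.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed,
                       n_animals = 35, duration_h = 72, condition = "LD",
                       n_genes = 2000, frac_rhythmic = 0.09,
                       period_min = 16, period_max = 32, period_step = 0.01,
                       n_permutations = 1000, alpha = 0.05,
                       g_cutoff = 0.5, K = 5, fold_threshold = 3,
                       homolog_table = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("configuration error: seed is mandatory")
  }
  stopifnot(period_min > 0, period_max > period_min, period_step > 0,
            n_permutations >= 100, alpha > 0, alpha < 1,
            g_cutoff >= 0, g_cutoff <= 1, K >= 2, fold_threshold > 0,
            n_animals >= 1, duration_h >= 24, n_genes >= 10,
            frac_rhythmic >= 0, frac_rhythmic <= 1)
  if (is.null(homolog_table)) {
    homolog_table <- system.file("extdata", "table3_larval_counts.tsv",
                                 package = "dielrhythm")
  }
  if (!file.exists(homolog_table)) {
    stop("configuration error: homolog table '", homolog_table,
         "' not found")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full diel-rhythm pipeline
#'
#' Executes the stages in order — simulate (activity cohort + expression
#' matrix), behavior (normalize, average, periodogram, permutation rhythm
#' test, day/night summary, daily peaks), expression (Poisson-weighted TMM
#' normalization, g-factor screen, DCG selection, K-means phase clusters,
#' peak ZT), compare (day/night fold-change filter and DCG/homolog
#' overlap) — writing each stage's tables under \code{config$out_dir} and
#' finishing with a JSON manifest recording the parameters, seed and an MD5
#' hash of every output file. Reruns with the same configuration reproduce
#' identical outputs and manifests. On failure, files written by the
#' partial run are removed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(...) if (!quiet) message(...)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  grid <- seq(config$period_min, config$period_max, by = config$period_step)
  out <- function(f) file.path(config$out_dir, f)

  tryCatch({
    ## stage 1: simulate ---------------------------------------------------
    note("[simulate] cohort: ", config$n_animals, " animals, ",
         config$duration_h, " h, ", config$condition,
         "; expression: ", config$n_genes, " genes, frac_rhythmic = ",
         config$frac_rhythmic, "; seed = ", config$seed)
    aspec <- activity_sim_spec(n_animals = config$n_animals,
                               duration_h = config$duration_h,
                               condition = config$condition,
                               seed = config$seed)
    cohort <- simulate_activity_cohort(aspec)
    espec <- expression_sim_spec(n_genes = config$n_genes,
                                 frac_rhythmic = config$frac_rhythmic,
                                 seed = config$seed + 1L)
    expr <- simulate_expression_timecourse(espec)
    write_activity_csv(cohort$traces, emit(out("activity.csv")))
    write_light_schedule(aspec$schedule, emit(out("schedule.yaml")))
    write_counts_tsv(expr$counts, emit(out("counts.tsv")))
    utils::write.table(
      data.frame(gene_id = names(expr$truth$rhythmic_flag),
                 rhythmic = expr$truth$rhythmic_flag,
                 true_phase_zt = expr$truth$true_phase_zt),
      emit(out("expression_truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

    ## stage 2: behavior ---------------------------------------------------
    note("[behavior] periodogram grid ", config$period_min, "-",
         config$period_max, " h step ", config$period_step, "; ",
         config$n_permutations, " permutations, alpha = ", config$alpha)
    traces <- read_activity_csv(out("activity.csv"))
    schedule <- read_light_schedule(out("schedule.yaml"))
    norm <- lapply(traces, normalize_to_max)
    coh <- aggregate_cohort(norm)
    pg <- dft_periodogram(coh$mean_pct, grid)
    rt <- test_rhythmicity(coh$mean_pct, grid,
                           n_permutations = config$n_permutations,
                           alpha = config$alpha, seed = config$seed + 2L)
    dns <- day_night_summary(traces, schedule)
    peaks <- daily_peaks(coh, schedule)
    write_cohort_profile_tsv(coh, schedule, emit(out("cohort_profile.tsv")))
    write_periodogram_tsv(pg, emit(out("periodogram.tsv")))
    write_rhythm_test_json(rt, emit(out("rhythm_test.json")))
    utils::write.table(
      data.frame(day = seq_along(peaks), peak_zt = peaks),
      emit(out("daily_peaks.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    note("[behavior] dominant period ", round(pg$dominant_period_h, 2),
         " h, p = ", signif(rt$p_value, 3),
         "; dark/light totals ", round(dns$mean_dark_total_cm, 1), "/",
         round(dns$mean_light_total_cm, 1), " cm")

    ## stage 3: expression -------------------------------------------------
    note("[expression] TMM normalization + g-factor screen (cutoff ",
         config$g_cutoff, "), K = ", config$K)
    counts <- read_counts_tsv(out("counts.tsv"))
    nm <- poisson_tmm_normalize(counts)
    scored <- collapse_replicates(nm$normalized)
    gtab <- g_factor_table(scored, interval_h = espec$interval_h)
    dcgs <- select_dcgs(gtab, cutoff = config$g_cutoff)
    utils::write.table(
      data.frame(sample = names(nm$size_factors),
                 size_factor = nm$size_factors),
      emit(out("size_factors.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    gtab$selected <- gtab$gene_id %in% dcgs
    utils::write.table(gtab, emit(out("g_factors.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(nm$normalized),
                 round(nm$normalized, 6), check.names = FALSE),
      emit(out("normalized_log2.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (length(dcgs) >= config$K) {
      cl <- kmeans_phase_clusters(scored[dcgs, , drop = FALSE],
                                  K = config$K, seed = config$seed + 3L,
                                  interval_h = espec$interval_h,
                                  start_zt = espec$start_zt)
      utils::write.table(
        data.frame(gene_id = names(cl$assignment),
                   cluster = cl$assignment,
                   peak_zt = round(cl$peak_zt, 3)),
        emit(out("clusters.tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      note("[expression] ", length(dcgs), " DCGs in ", config$K,
           " phase clusters")
    } else {
      note("[expression] only ", length(dcgs),
           " DCGs selected; clustering skipped")
    }

    ## stage 4: compare ----------------------------------------------------
    note("[compare] fold threshold ", config$fold_threshold, " on ",
         config$homolog_table)
    homologs <- read_homolog_table(config$homolog_table)
    fc <- fold_change_filter(homologs, threshold = config$fold_threshold)
    utils::write.table(fc$table, emit(out("fold_change.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ov <- overlap_dcgs(dcgs, homologs)
    utils::write.table(
      data.frame(n_dcgs = length(dcgs), n_mapped = ov$n_mapped,
                 n_unmapped = ov$n_unmapped,
                 n_day_up = length(fc$day_up),
                 n_night_up = length(fc$night_up)),
      emit(out("compare_summary.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)

    ## manifest ------------------------------------------------------------
    params <- config
    params$out_dir <- NULL
    class(params) <- NULL
    manifest <- list(
      parameters = params,
      seed = config$seed,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(written)), basename(written))))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    note("[done] manifest with ", length(written), " outputs at ",
         out("manifest.json"))
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
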