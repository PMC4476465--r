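#' Write an activity cohort to CSV
#'
#' Long format: one row per animal-hour with columns \code{animal_id},
#' \code{hour_index}, \code{distance_cm}, \code{condition}.
#'
#' @param traces list of \code{activity_trace} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_activity_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    hourly <- bin_hourly(tr)
    data.frame(animal_id = tr$animal_id,
               hour_index = seq_along(hourly) - 1L,
               distance_cm = hourly,
               condition = tr$condition)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an activity cohort from CSV
#'
#' Accepts either hourly records (\code{animal_id}, \code{hour_index},
#' \code{distance_cm}) or raw event records (\code{animal_id},
#' \code{time_s}, \code{distance_cm}); raw events are binned on demand by
#' [bin_hourly()].
#'
#' @param path CSV path.
#' @return List of \code{activity_trace} objects, one per animal.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(df) || !"distance_cm" %in% names(df)) {
    stop("activity file '", path,
         "': need columns animal_id and distance_cm")
  }
  if (!any(c("hour_index", "time_s") %in% names(df))) {
    stop("activity file '", path,
         "': need an hour_index or time_s column")
  }
  bad <- which(!is.finite(df$distance_cm) | df$distance_cm < 0)
  if (length(bad)) {
    stop("activity file '", path, "': invalid distance_cm at row ", bad[1])
  }
  lapply(split(df, df$animal_id), function(a) {
    cond <- if ("condition" %in% names(a)) a$condition[1] else NA_character_
    if ("hour_index" %in% names(a)) {
      a <- a[order(a$hour_index), , drop = FALSE]
      structure(list(animal_id = a$animal_id[1], hourly_cm = a$distance_cm,
                     duration_h = nrow(a), condition = cond),
                class = "activity_trace")
    } else {
      activity_trace_events(a$animal_id[1],
                            data.frame(time_s = a$time_s,
                                       displacement_cm = a$distance_cm),
                            duration_h = ceiling(max(a$time_s) / 3600),
                            condition = cond)
    }
  })
}

#' Write a count matrix to TSV
#'
#' First column \code{gene_id}, then one column per sample labelled
#' \code{ZT<h>_day<d>}.
#'
#' @param counts matrix with row and column names.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a count matrix from TSV
#'
#' Every count cell must hold a non-negative integer; violations raise an
#' error naming the offending row and column.
#'
#' @param path TSV path (first column \code{gene_id}).
#' @return Integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "gene_id") {
    stop("counts file '", path, "': first column must be gene_id")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts file '", path, "': non-integer count at row ", bad[1, 1],
         ", column '", colnames(vals)[bad[1, 2]], "'")
  }
  mat <- matrix(as.integer(num), nrow(num), ncol(num),
                dimnames = list(df$gene_id, colnames(vals)))
  mat
}

#' Write a cohort activity profile to TSV
#'
#' Columns \code{hour}, \code{zt}, \code{mean_pct}, \code{se_pct}.
#'
#' @param cohort a \code{cohort_activity}.
#' @param schedule a \code{light_schedule} (for the ZT column).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_profile_tsv <- function(cohort, schedule, path) {
  h <- seq_along(cohort$mean_pct) - 1L
  utils::write.table(
    data.frame(hour = h, zt = zt_of_hour(schedule, h),
               mean_pct = cohort$mean_pct, se_pct = cohort$se_pct),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a periodogram to TSV
#'
#' @param pg a \code{periodogram}.
#' @param path output TSV path (columns \code{period_h}, \code{power}).
#' @return \code{path}, invisibly.
#' @export
write_periodogram_tsv <- function(pg, path) {
  utils::write.table(
    data.frame(period_h = pg$period_grid_h, power = pg$power),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a rhythm-test summary to JSON
#'
#' @param rt a \code{rhythm_test}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_rhythm_test_json <- function(rt, path) {
  jsonlite::write_json(
    list(observed_max_power = rt$observed_max_power,
         dominant_period_h = rt$dominant_period_h,
         p_value = rt$p_value, n_permutations = rt$n_permutations,
         alpha = rt$alpha, significant = rt$significant),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
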