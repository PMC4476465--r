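#' Read a homolog day/night table
#'
#' Tab-separated table of cross-species homolog pairs with larval day and
#' night read counts. Two transcribed tables ship with the package (see
#' \code{system.file("extdata", ...)}: \code{table2_homolog_overlap.tsv},
#' adult microarray homolog pairs with peak times, and
#' \code{table3_larval_counts.tsv}, larval day/night count pairs).
#'
#' @param path TSV path with at least \code{nv_gene_id}; count tables also
#'   carry \code{day_count} and \code{night_count}.
#' @return Data frame; \code{nv_gene_id} is read as character.
#' @export
read_homolog_table <- function(path) {
  if (!file.exists(path)) stop("homolog table '", path, "' not found")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(nv_gene_id = "character"))
  if (!"nv_gene_id" %in% names(df)) {
    stop("homolog table '", path, "' lacks an nv_gene_id column")
  }
  df
}

#' Day/night fold-change filter on homolog count pairs
#'
#' Classifies each homolog pair by the ratio of day to night read counts: a
#' pair is day-upregulated iff \code{day_count >= threshold * night_count}
#' with \code{day_count > 0} (a positive count against a zero opposite
#' count passes — the fold is treated as infinite); night-upregulated
#' symmetrically. The threshold is inclusive. Pairs meeting neither rule —
#' or, degenerately, both (equal counts at threshold 1), or with both
#' counts zero — get direction \code{"none"}; the both-zero case is
#' additionally flagged.
#'
#' @param pairs data frame with \code{nv_gene_id}, \code{day_count},
#'   \code{night_count} (non-negative integers).
#' @param threshold fold-change threshold (default 3).
#' @return A list of class \code{fold_change_result}: \code{day_up} and
#'   \code{night_up} (character id vectors), \code{table} (input with a
#'   \code{direction} column), \code{flagged_zero} (ids with both counts
#'   zero), \code{threshold}.
#' @export
fold_change_filter <- function(pairs, threshold = 3.0) {
  stopifnot(all(c("nv_gene_id", "day_count", "night_count") %in% names(pairs)),
            all(pairs$day_count >= 0), all(pairs$night_count >= 0),
            threshold > 0)
  d <- pairs$day_count
  n <- pairs$night_count
  day_up <- d > 0 & d >= threshold * n
  night_up <- n > 0 & n >= threshold * d
  both <- day_up & night_up
  day_up[both] <- FALSE
  night_up[both] <- FALSE
  direction <- ifelse(day_up, "day", ifelse(night_up, "night", "none"))
  out <- pairs
  out$direction <- direction
  structure(list(day_up = pairs$nv_gene_id[day_up],
                 night_up = pairs$nv_gene_id[night_up],
                 table = out,
                 flagged_zero = pairs$nv_gene_id[d == 0 & n == 0],
                 threshold = threshold),
            class = "fold_change_result")
}

#' Join diel cycle genes against a homolog map
#'
#' Inner join of a DCG set with a cross-species homolog table keyed by
#' \code{nv_gene_id}; DCGs without a homolog are counted and reported.
#'
#' @param dcgs character vector of DCG gene ids (e.g. from
#'   [select_dcgs()]).
#' @param homolog_map data frame keyed by \code{nv_gene_id}.
#' @return A list of class \code{overlap_table}: \code{table} (joined
#'   rows, one per mapped DCG), \code{n_mapped}, \code{n_unmapped},
#'   \code{unmapped} (ids).
#' @export
overlap_dcgs <- function(dcgs, homolog_map) {
  stopifnot("nv_gene_id" %in% names(homolog_map))
  dcgs <- as.character(dcgs)
  tab <- homolog_map[homolog_map$nv_gene_id %in% dcgs, , drop = FALSE]
  rownames(tab) <- NULL
  unmapped <- setdiff(dcgs, homolog_map$nv_gene_id)
  structure(list(table = tab, n_mapped = nrow(tab),
                 n_unmapped = length(unmapped), unmapped = unmapped),
            class = "overlap_table")
}
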