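#' Bookkeeping identities for detection-set summaries
#'
#' Small audited arithmetic used by the run summary: the inclusion-exclusion
#' union of two detected-protein sets, the count of proteins detected under
#' both conditions given the exclusive-detection counts, and differential
#' totals.
#'
#' @param n_a,n_b sizes of the two detected sets.
#' @param n_ab size of their intersection.
#' @return \code{venn_union}: |A u B| = |A| + |B| - |A n B|.
#' @export
venn_union <- function(n_a, n_b, n_ab) {
  if (n_ab > min(n_a, n_b)) abort("intersection larger than a set")
  n_a + n_b - n_ab
}

#' @rdname venn_union
#' @param n_total proteins detected under a stressor.
#' @param n_stress_only,n_control_only exclusive-detection counts.
#' @export
both_condition_count <- function(n_total, n_stress_only, n_control_only) {
  out <- n_total - n_stress_only - n_control_only
  if (out < 0) abort("exclusive counts exceed the total")
  out
}

#' @rdname venn_union
#' @param n_up,n_down up/down differential counts.
#' @export
de_total <- function(n_up, n_down) n_up + n_down

#' Differential-expression summary table
#'
#' Table-style bookkeeping of per-level classification records: proteins used
#' for DE (detected under both conditions), up/down counts at FDR alone and
#' at FDR plus the fold threshold, exclusive-detection counts per level and
#' their any-level unions.
#'
#' @param records long data.frame of classification records with columns
#'   \code{protein_id, level, category, fold_change, fdr_pass} (one row per
#'   protein per stress level), as produced by [classify_proteins()] runs.
#' @param fold_thresh fold threshold used for the fold-filtered rows.
#' @return list with \code{per_level} (data.frame, one row per level) and
#'   \code{aggregate} (any-level union counts).
#' @export
summarize_de <- function(records, fold_thresh = 2) {
  stopifnot(all(c("protein_id", "level", "category") %in% names(records)))
  lv <- unique(records$level)
  empty <- data.frame(level = character(), n_used = integer(),
                      de_fdr_up = integer(), de_fdr_down = integer(),
                      de_fold_up = integer(), de_fold_down = integer(),
                      de_fold_total = integer(), stress_only = integer(),
                      control_only = integer(), stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(lv, function(l) {
    r <- records[records$level == l, ]
    both <- r$category %in% c("up", "down", "nonsig")
    fdr_up <- both & isTRUE_vec(r$fdr_pass) & !is.na(r$fold_change) &
      r$fold_change > 1
    fdr_down <- both & isTRUE_vec(r$fdr_pass) & !is.na(r$fold_change) &
      r$fold_change < 1
    data.frame(level = l,
               n_used = sum(both),
               de_fdr_up = sum(fdr_up),
               de_fdr_down = sum(fdr_down),
               de_fold_up = sum(r$category == "up"),
               de_fold_down = sum(r$category == "down"),
               de_fold_total = de_total(sum(r$category == "up"),
                                        sum(r$category == "down")),
               stress_only = sum(r$category == "stress_only"),
               control_only = sum(r$category == "control_only"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) per <- empty
  rownames(per) <- NULL
  agg <- list(
    stress_only_any = length(unique(
      records$protein_id[records$category == "stress_only"])),
    control_only_any = length(unique(
      records$protein_id[records$category == "control_only"])),
    detected_any = length(unique(records$protein_id)))
  list(per_level = per, aggregate = agg)
}

isTRUE_vec <- function(x) !is.na(x) & x
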