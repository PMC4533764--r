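#' Median-of-ratios size factors
#'
#' DESeq-style normalisation stand-in: for each sample, the size factor is
#' the median over all-nonzero genes of the ratio of that gene's count to its
#' across-sample geometric mean.
#'
#' @param counts integer count matrix (genes x samples).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  nz <- rowSums(counts == 0) == 0
  if (!any(nz))
    abort(paste("no gene has nonzero counts in every sample;",
                "add a pseudocount upstream or filter samples"))
  lg <- log(counts[nz, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - gm)))
  if (any(sf <= 0)) abort("non-positive size factor")
  sf
}

#' Normalise counts by size factors
#' @param counts count matrix.
#' @param sf size factors from [size_factors()] (computed if missing).
#' @return matrix of normalised abundances.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Per-gene log2 fold change between sample groups
#'
#' \code{log2((mean_stress + c) / (mean_control + c))} on normalised
#' abundances; the pseudocount keeps censored/zero genes finite.
#'
#' @param normalized normalised abundance matrix.
#' @param stress_cols,control_cols column names/indices of the two groups.
#' @param pseudocount c, in normalised units (default 1).
#' @return named numeric vector of log2 fold changes.
#' @export
log2fc <- function(normalized, stress_cols, control_cols, pseudocount = 1) {
  ms <- rowMeans(normalized[, stress_cols, drop = FALSE])
  mc <- rowMeans(normalized[, control_cols, drop = FALSE])
  log2((ms + pseudocount) / (mc + pseudocount))
}

#' Percentile abundance ranks (blue-plot ranking)
#'
#' Ranks features within each sample and rescales average ranks to
#' [0, 100]: the least abundant feature maps to 0, the most abundant to 100,
#' ties share their averaged rank. With several columns the default is to
#' rank per column first and then average the percentile ranks across
#' columns (e.g. a condition's time points).
#'
#' @param abundances numeric matrix (features x samples) or vector.
#' @param average if TRUE (default) return the across-column mean percentile
#'   rank per feature; otherwise the per-column matrix.
#' @return numeric vector (or matrix) of ranks in [0, 100].
#' @export
percentile_rank <- function(abundances, average = TRUE) {
  m <- as.matrix(abundances)
  n <- nrow(m)
  if (n < 2) abort("percentile ranking needs >= 2 features")
  pr <- apply(m, 2, function(col) 100 * (rank(col) - 1) / (n - 1))
  if (average) rowMeans(pr) else pr
}

#' Permutation differential-expression call for transcript data
#'
#' A deliberately simple stand-in for a count-model DE test, so externally
#' computed DE tables can replace it: the statistic is the mean log2
#' difference of \code{log2(x + pseudocount)} between groups (or the mean
#' log2 ratio itself in one-sample mode for microarray data, where the null
#' is generated by sign flips). Two-sided permutation p-values are
#' Benjamini-Hochberg adjusted; categories require fold >= \code{fold_thresh}
#' and adjusted p <= \code{fdr}.
#'
#' @param x normalised abundance matrix, or a log2-ratio matrix in
#'   one-sample mode.
#' @param stress_cols stress-group columns.
#' @param control_cols control columns, or NULL for one-sample (sign-flip)
#'   mode on a log-ratio matrix.
#' @param n_perm maximum permutations (exhaustive when fewer exist).
#' @param fdr BH-adjusted significance threshold.
#' @param fold_thresh linear fold-change threshold.
#' @param pseudocount added before log2 in two-group mode.
#' @param seed permutation seed.
#' @return data.frame \code{gene_id, log2fc, p, q, category} with category in
#'   \code{up/down/nonsig}.
#' @export
de_call_mrna <- function(x, stress_cols, control_cols = NULL, n_perm = 1000,
                         fdr = 0.05, fold_thresh = 2, pseudocount = 1,
                         seed = 1) {
  local_seed(seed)
  if (is.null(control_cols)) {
    lr <- x[, stress_cols, drop = FALSE]
    obs <- rowMeans(lr)
    k <- ncol(lr)
    n_all <- 2^k
    flips <- if (n_all <= n_perm) {
      lapply(seq_len(n_all) - 1L, function(b) 2 * (bitwAnd(b, 2^(0:(k - 1))) > 0) - 1)
    } else {
      replicate(n_perm, sample(c(-1, 1), k, replace = TRUE), simplify = FALSE)
    }
    perm <- vapply(flips, function(sg) rowMeans(sweep(lr, 2, sg, "*")),
                   numeric(nrow(lr)))
    p <- (rowSums(abs(perm) >= abs(obs) - 1e-12)) / length(flips)
    lfc <- obs
  } else {
    lx <- log2(x[, c(stress_cols, control_cols), drop = FALSE] + pseudocount)
    g1 <- length(stress_cols); nc <- g1 + length(control_cols)
    stat <- function(ix) rowMeans(lx[, ix, drop = FALSE]) -
      rowMeans(lx[, -ix, drop = FALSE])
    obs <- stat(seq_len(g1))
    combos <- if (choose(nc, g1) <= n_perm) {
      utils::combn(nc, g1, simplify = FALSE)
    } else {
      c(list(seq_len(g1)),
        replicate(n_perm - 1, sort(sample.int(nc, g1)), simplify = FALSE))
    }
    perm <- vapply(combos, stat, numeric(nrow(lx)))
    p <- rowSums(abs(perm) >= abs(obs) - 1e-12) / length(combos)
    lfc <- obs
  }
  q <- p.adjust(p, "BH")
  category <- rep("nonsig", length(obs))
  category[q <= fdr & lfc >= log2(fold_thresh)] <- "up"
  category[q <= fdr & lfc <= -log2(fold_thresh)] <- "down"
  data.frame(gene_id = rownames(x) %||% as.character(seq_along(obs)),
             log2fc = unname(lfc), p = unname(p), q = unname(q),
             category = category, stringsAsFactors = FALSE)
}
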