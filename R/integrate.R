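#' Join protein and mRNA layers into integration records
#'
#' Builds one record per protein-detected gene per stress level, merging the
#' five-way protein classification with microarray and RNAseq differential
#' calls, percentile abundance ranks (stress and control), 5'UTR lengths and
#' RBS scores. Missing layers stay NA and are never imputed.
#'
#' @param protein_records long data.frame from per-level [classify_proteins()]
#'   runs, with columns \code{protein_id, level, category, fold_change,
#'   display_value, fdr_pass}.
#' @param mrna_de named list with elements \code{microarray} and
#'   \code{rnaseq}, each a long data.frame \code{gene_id, level, log2fc,
#'   category}.
#' @param ranks named list with \code{protein} and \code{mrna}: matrices of
#'   percentile ranks, genes x conditions, with a \code{"ctrl"} column plus
#'   one column per stress level.
#' @param tss optional TSS records ([call_tss()] output across conditions).
#' @param rbs optional RBS table ([score_rbs_all()] output).
#' @return long integration data.frame, one row per (gene, level).
#' @export
join_omics <- function(protein_records, mrna_de = list(), ranks = list(),
                       tss = NULL, rbs = NULL) {
  pr <- protein_records
  if (anyDuplicated(pr[c("protein_id", "level")]))
    abort("duplicate gene id '%s' among protein records",
          pr$protein_id[duplicated(pr[c("protein_id", "level")])][1])
  out <- data.frame(gene_id = pr$protein_id, level = pr$level,
                    protein_category = pr$category,
                    fold_change = pr$fold_change,
                    display_value = pr$display_value,
                    fdr_pass = pr$fdr_pass, stringsAsFactors = FALSE)
  pull_de <- function(tab, prefix) {
    if (is.null(tab)) {
      out[[paste0(prefix, "_log2fc")]] <<- rep(NA_real_, nrow(out))
      out[[paste0(prefix, "_category")]] <<- rep(NA_character_, nrow(out))
      return(invisible())
    }
    key_a <- paste(out$gene_id, out$level)
    key_b <- paste(tab$gene_id, tab$level)
    k <- match(key_a, key_b)
    unmatched <- sum(is.na(k))
    if (unmatched > 0)
      message(unmatched, " records with no ", prefix, " entry")
    out[[paste0(prefix, "_log2fc")]] <<- tab$log2fc[k]
    out[[paste0(prefix, "_category")]] <<- tab$category[k]
  }
  pull_de(mrna_de$microarray, "ma")
  pull_de(mrna_de$rnaseq, "rs")

  pull_rank <- function(m, prefix) {
    if (is.null(m)) {
      out[[paste0(prefix, "_rank")]] <<- rep(NA_real_, nrow(out))
      out[[paste0(prefix, "_rank_ctrl")]] <<- rep(NA_real_, nrow(out))
      return(invisible())
    }
    k <- match(out$gene_id, rownames(m))
    out[[paste0(prefix, "_rank")]] <<-
      m[cbind(k, match(out$level, colnames(m)))]
    out[[paste0(prefix, "_rank_ctrl")]] <<- m[k, "ctrl"]
  }
  pull_rank(ranks$protein, "protein")
  pull_rank(ranks$mrna, "mrna")

  if (!is.null(tss)) {
    stress_tss <- tss[tss$condition != "control", ]
    ctl_tss <- tss[tss$condition == "control", ]
    out$utr_len <- stress_tss$utr_len[match(out$gene_id, stress_tss$gene_id)]
    out$utr_len_ctrl <- ctl_tss$utr_len[match(out$gene_id, ctl_tss$gene_id)]
  } else {
    out$utr_len <- rep(NA_real_, nrow(out))
    out$utr_len_ctrl <- rep(NA_real_, nrow(out))
  }
  out$rbs_score <- if (!is.null(rbs)) rbs$score[match(out$gene_id, rbs$gene_id)]
                   else rep(NA_real_, nrow(out))
  out
}

#' Call proteome-transcriptome discordance
#'
#' A record is discordant when protein and mRNA move in clearly opposite
#' directions - protein up or stress-only while the reference mRNA is called
#' down, or protein down or control-only while the mRNA is up - or when a
#' protein is exclusively detected under one condition although its mRNA is
#' unchanged and well expressed (percentile rank at least
#' \code{good_mrna_rank}), the "despite good mRNA levels" pattern. The
#' subtype records which clause fired.
#'
#' @param records integration records ([join_omics()] output).
#' @param fold_thresh fold threshold (already baked into categories; kept as
#'   an explicit, documented knob).
#' @param good_mrna_rank minimum mRNA percentile rank for the
#'   exclusive-detection clause.
#' @param reference which transcript dataset provides the mRNA DE call.
#' @return records with added \code{discordant} flag and
#'   \code{discordance_subtype} (\code{opposite_de},
#'   \code{exclusive_good_mrna} or NA).
#' @export
call_discordance <- function(records, fold_thresh = 2, good_mrna_rank = 50,
                             reference = c("microarray", "rnaseq")) {
  reference <- match.arg(reference)
  mcat <- records[[if (reference == "microarray") "ma_category" else "rs_category"]]
  pcat <- records$protein_category
  opp <- (pcat %in% c("up", "stress_only") & !is.na(mcat) & mcat == "down") |
         (pcat %in% c("down", "control_only") & !is.na(mcat) & mcat == "up")
  excl <- pcat %in% c("stress_only", "control_only") &
    !is.na(mcat) & mcat == "nonsig" &
    !is.na(records$mrna_rank) & records$mrna_rank >= good_mrna_rank
  records$discordant <- opp | excl
  records$discordance_subtype <- ifelse(opp, "opposite_de",
                                        ifelse(excl, "exclusive_good_mrna",
                                               NA_character_))
  records
}

#' Screen post-transcriptional regulation hypotheses
#'
#' Three per-gene mechanisms, evaluated on the long integration table:
#' \itemize{
#' \item H1 - constitutively inefficient translation: mRNA percentile rank at
#'   least \code{rank_hi} and protein rank at most \code{rank_lo} in every
#'   condition, control included.
#' \item H2 - stress-blocked translation: at both medium and high stress the
#'   reference mRNA is up (fold > threshold) while the protein is down or not
#'   detected under stress.
#' \item H3 - translational up-regulation: protein called up (FDR and fold)
#'   while the mRNA is non-significant in both transcript datasets. H3 genes
#'   are annotated with \code{long_utr} (5'UTR above the median) and
#'   \code{strong_rbs} (score above the mean), the features expected if long
#'   5'UTR regulatory elements and strong RBSs drive their translation.
#' }
#'
#' @param records integration records.
#' @param rank_hi,rank_lo H1 thresholds (defaults 80 / 20).
#' @param levels_h2 stress levels that must agree for H2.
#' @param reference mRNA DE dataset for H2.
#' @return per-gene data.frame \code{gene_id, H1, H2, H3, long_utr,
#'   strong_rbs}.
#' @export
screen_hypotheses <- function(records, rank_hi = 80, rank_lo = 20,
                              levels_h2 = c("med", "high"),
                              reference = c("microarray", "rnaseq")) {
  reference <- match.arg(reference)
  mcat_col <- if (reference == "microarray") "ma_category" else "rs_category"
  med_utr <- median(records$utr_len, na.rm = TRUE)
  mean_rbs <- mean(records$rbs_score, na.rm = TRUE)
  genes <- unique(records$gene_id)
  res <- lapply(genes, function(g) {
    r <- records[records$gene_id == g, ]
    h1 <- all(!is.na(r$mrna_rank)) && all(!is.na(r$protein_rank)) &&
      all(r$mrna_rank >= rank_hi) && all(r$mrna_rank_ctrl >= rank_hi) &&
      all(r$protein_rank <= rank_lo) && all(r$protein_rank_ctrl <= rank_lo)
    rh2 <- r[r$level %in% levels_h2, ]
    h2 <- nrow(rh2) == length(levels_h2) &&
      all(!is.na(rh2[[mcat_col]]) & rh2[[mcat_col]] == "up" &
            rh2$protein_category %in% c("down", "control_only"))
    h3_row <- r$protein_category == "up" &
      !is.na(r$ma_category) & r$ma_category == "nonsig" &
      !is.na(r$rs_category) & r$rs_category == "nonsig"
    h3 <- any(h3_row)
    data.frame(gene_id = g, H1 = h1, H2 = h2, H3 = h3,
               long_utr = h3 && !is.na(r$utr_len[1]) && r$utr_len[1] > med_utr,
               strong_rbs = h3 && !is.na(r$rbs_score[1]) &&
                 r$rbs_score[1] > mean_rbs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Revised abundance-percentile screens
#'
#' Compares actual abundances instead of differential calls:
#' \code{rev_lowM_highP} flags proteins expressed from scarce transcripts
#' (mRNA rank strictly below \code{mrna_rank_lt}) yet highly abundant
#' (protein rank strictly above \code{protein_rank_gt}) and up or
#' stress-only; \code{rev_highM_lowP} is the mirrored screen (mRNA rank >
#' \code{protein_rank_gt}, protein rank < \code{mrna_rank_lt}) restricted to
#' down or control-only proteins.
#'
#' @param records integration records.
#' @param mrna_rank_lt,protein_rank_gt the two percentile thresholds
#'   (defaults 60 and 80).
#' @return records with logical columns \code{rev_lowM_highP} and
#'   \code{rev_highM_lowP} added.
#' @export
screen_revised <- function(records, mrna_rank_lt = 60, protein_rank_gt = 80) {
  mr <- records$mrna_rank; pr <- records$protein_rank
  records$rev_lowM_highP <- !is.na(mr) & !is.na(pr) &
    mr < mrna_rank_lt & pr > protein_rank_gt &
    records$protein_category %in% c("up", "stress_only")
  records$rev_highM_lowP <- !is.na(mr) & !is.na(pr) &
    mr > protein_rank_gt & pr < mrna_rank_lt &
    records$protein_category %in% c("down", "control_only")
  records
}

#' Pearson correlation of fold changes by protein category
#'
#' Sample Pearson r between two layers' fold changes within each protein
#' category. Exclusive-detection categories are excluded: with a constant
#' sentinel value they have no standard deviation and the coefficient is
#' undefined. Pairs with fewer than \code{min_n} complete observations are
#' reported NA.
#'
#' @param records integration records for one stress level.
#' @param pairs list of layer pairs among \code{"protein"},
#'   \code{"microarray"}, \code{"rnaseq"}.
#' @param min_n minimum complete pairs (default 3).
#' @return data.frame \code{category, pair, n, r}.
#' @export
pearson_by_category <- function(records,
                                pairs = list(c("protein", "microarray"),
                                             c("protein", "rnaseq"),
                                             c("microarray", "rnaseq")),
                                min_n = 3) {
  layer_val <- function(layer) {
    switch(layer,
           protein = log2(records$fold_change),
           microarray = records$ma_log2fc,
           rnaseq = records$rs_log2fc,
           abort("unknown layer '%s'", layer))
  }
  cats <- c("up", "down", "nonsig")
  out <- list()
  for (cat in cats) {
    in_cat <- records$protein_category == cat
    for (pp in pairs) {
      a <- layer_val(pp[1])[in_cat]; b <- layer_val(pp[2])[in_cat]
      ok <- is.finite(a) & is.finite(b)
      r <- if (sum(ok) >= min_n) cor(a[ok], b[ok]) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        category = cat, pair = paste(pp, collapse = "_vs_"),
        n = sum(ok), r = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' COG category enrichment of differential calls
#'
#' One-sided Fisher exact tests for over-representation of up-regulated (and
#' separately down-regulated) proteins in each COG functional category
#' against the rest of the classified proteome, Benjamini-Hochberg adjusted
#' across letters x directions. Labels: \code{up-enriched},
#' \code{down-enriched}, \code{both} (both directions significant) or
#' \code{none}.
#'
#' @param records integration records for one stress level (categories
#'   \code{up}/\code{stress_only} count as up-regulated,
#'   \code{down}/\code{control_only} as down-regulated).
#' @param cog named character vector gene_id -> COG letter.
#' @param alpha BH significance threshold (default 0.05).
#' @return data.frame \code{cog_letter, n_up, n_down, n_total, odds_up,
#'   p_up, q_up, odds_down, p_down, q_down, label}.
#' @export
cog_enrichment <- function(records, cog, alpha = 0.05) {
  g <- unique(records$gene_id)
  cat_of <- records$protein_category[match(g, records$gene_id)]
  letter <- unname(cog[g])
  keep <- !is.na(letter)
  if (!any(keep)) abort("no categorized protein has a COG assignment")
  g <- g[keep]; cat_of <- cat_of[keep]; letter <- letter[keep]
  is_up <- cat_of %in% c("up", "stress_only")
  is_down <- cat_of %in% c("down", "control_only")
  letters_u <- sort(unique(letter))
  rows <- lapply(letters_u, function(ltr) {
    in_cog <- letter == ltr
    f <- function(flag) {
      tab <- matrix(c(sum(flag & in_cog), sum(!flag & in_cog),
                      sum(flag & !in_cog), sum(!flag & !in_cog)), 2)
      ft <- fisher.test(tab, alternative = "greater")
      c(or = unname(ft$estimate), p = ft$p.value)
    }
    up <- f(is_up); down <- f(is_down)
    data.frame(cog_letter = ltr, n_up = sum(is_up & in_cog),
               n_down = sum(is_down & in_cog), n_total = sum(in_cog),
               odds_up = up["or"], p_up = up["p"],
               odds_down = down["or"], p_down = down["p"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  q <- p.adjust(c(out$p_up, out$p_down), "BH")
  out$q_up <- q[seq_len(nrow(out))]
  out$q_down <- q[nrow(out) + seq_len(nrow(out))]
  out$label <- ifelse(out$q_up <= alpha & out$q_down <= alpha, "both",
                      ifelse(out$q_up <= alpha, "up-enriched",
                             ifelse(out$q_down <= alpha, "down-enriched",
                                    "none")))
  rownames(out) <- NULL
  out
}
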