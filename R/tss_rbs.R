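#' 5'UTR length from a TSS call
#'
#' Strand-aware distance from the TSS to the first base of the start codon
#' (1-based closed coordinates): plus strand \code{cds_start - tss_pos},
#' minus strand \code{tss_pos - cds_end}. A TSS at the translational start
#' gives length 0, the leaderless geometry in which transcription and
#' translation start at the same base.
#'
#' @param tss_pos TSS contig coordinate (1-based).
#' @param cds_start,cds_end CDS bounds (1-based closed).
#' @param strand \code{"+"} or \code{"-"}.
#' @param inside_tol nt the TSS may sit inside the CDS before it is an error
#'   (clamped to 0 within the tolerance).
#' @return UTR length in nt (>= 0).
#' @export
utr_length <- function(tss_pos, cds_start, cds_end, strand, inside_tol = 0) {
  L <- if (strand == "+") cds_start - tss_pos else tss_pos - cds_end
  if (L < -inside_tol)
    abort("TSS at %d lies %d nt inside the CDS [%d, %d] (%s)",
          tss_pos, -L, cds_start, cds_end, strand)
  max(L, 0L)
}

#' Call transcription start sites from TEX-enriched coverage
#'
#' For every operon-leading (or monocistronic) gene, scans the window
#' \code{window_up} nt upstream of the start codon on the gene's strand for
#' positions with depth >= \code{min_depth} and a sharp coverage step
#' \code{(cov[p]+1)/(cov[upstream of p]+1) >= min_step} in the TEX+ track;
#' when a TEX- track is supplied the TEX+/TEX- ratio at the candidate must
#' also reach \code{min_tex} (primary 5' ends survive the exonuclease,
#' processed ends do not). The winner is the candidate with the largest step
#' ratio, ties broken towards the start codon (the shorter UTR, conservative
#' for leaderless calling). The window is capped at the adjacent upstream
#' gene to avoid run-through signal. Genes without any candidate get no
#' record.
#'
#' @param tracks_tex named list of TEX+ [coverage_track()]s by strand
#'   (\code{"+"}, \code{"-"}).
#' @param tracks_notex optional matching list of TEX- tracks (or NULL).
#' @param annotation annotation index (see [read_gff3()]).
#' @param window_up search window upstream of the start codon, nt.
#' @param min_depth minimum TEX+ depth at a candidate TSS.
#' @param min_step minimum step ratio.
#' @param min_tex minimum TEX+/TEX- ratio (ignored when tracks_notex NULL).
#' @param leaderless_tol UTRs at or below this length are flagged leaderless.
#' @param condition label stored in the records.
#' @return data.frame of TSS records: \code{gene_id, condition, tss_pos,
#'   utr_len, leaderless, step_score, tex_enrichment_obs}.
#' @export
call_tss <- function(tracks_tex, tracks_notex = NULL, annotation,
                     window_up = 300, min_depth = 10, min_step = 3,
                     min_tex = 2, leaderless_tol = 5, condition = "control") {
  for (s in c("+", "-")) {
    tr <- tracks_tex[[s]]
    if (is.null(tr)) abort("missing TEX+ track for strand %s", s)
    if (!tr$contig %in% annotation$contig)
      abort("track contig '%s' not present in the annotation", tr$contig)
  }
  lead <- annotation[annotation$first_in_operon, , drop = FALSE]
  recs <- vector("list", nrow(lead))
  n_missed <- 0L
  for (i in seq_len(nrow(lead))) {
    g <- lead[i, ]
    cov <- tracks_tex[[g$strand]]$values
    notex <- if (!is.null(tracks_notex)) tracks_notex[[g$strand]]$values
    L <- length(cov)
    same_contig <- annotation$contig == g$contig
    if (g$strand == "+") {
      prev_end <- suppressWarnings(
        max(annotation$cds_end[same_contig & annotation$cds_end < g$cds_start]))
      lo <- max(1, g$cds_start - window_up, prev_end + 1)
      win <- lo:g$cds_start
      up1 <- pmax(win - 1L, 1L)
    } else {
      nxt_start <- suppressWarnings(
        min(annotation$cds_start[same_contig & annotation$cds_start > g$cds_end]))
      hi <- min(L, g$cds_end + window_up, nxt_start - 1)
      win <- g$cds_end:hi
      up1 <- pmin(win + 1L, L)
    }
    step <- (cov[win] + 1) / (cov[up1] + 1)
    ok <- cov[win] >= min_depth & step >= min_step
    tex_obs <- rep(NA_real_, length(win))
    if (!is.null(notex)) {
      tex_obs <- (cov[win] + 1) / (notex[win] + 1)
      ok <- ok & tex_obs >= min_tex
    }
    if (!any(ok)) { n_missed <- n_missed + 1L; next }
    cand <- which(ok)
    best <- cand[order(-step[cand],
                       if (g$strand == "+") -win[cand] else win[cand])][1]
    tss <- win[best]
    ul <- utr_length(tss, g$cds_start, g$cds_end, g$strand)
    recs[[i]] <- data.frame(
      gene_id = g$gene_id, condition = condition, tss_pos = tss,
      utr_len = ul, leaderless = ul <= leaderless_tol,
      step_score = step[best], tex_enrichment_obs = tex_obs[best],
      stringsAsFactors = FALSE)
  }
  if (n_missed > 0)
    message(n_missed, " operon-leading genes without a TSS candidate (no record)")
  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), condition = character(),
                      tss_pos = integer(), utr_len = integer(),
                      leaderless = logical(), step_score = numeric(),
                      tex_enrichment_obs = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect condition-dependent leaderless switches
#'
#' Compares the leaderless status (UTR length <= \code{leaderless_tol}) of
#' each gene between the control condition and every stress condition it was
#' observed in, and records the direction of any switch: a transcript with a
#' 5'UTR under control that becomes leaderless under stress
#' (\code{leadered_to_leaderless}, the mRNA-trimming signature), or the
#' reverse (\code{leaderless_to_leadered}).
#'
#' @param records TSS record data.frame ([call_tss()] output, possibly
#'   concatenated across conditions).
#' @param control name of the reference condition.
#' @param leaderless_tol leaderless tolerance in nt.
#' @return data.frame \code{gene_id, condition, direction, utr_control,
#'   utr_stress}.
#' @export
detect_tss_shift <- function(records, control = "control", leaderless_tol = 5) {
  ctl <- records[records$condition == control, ]
  out <- list()
  for (cond in setdiff(unique(records$condition), control)) {
    st <- records[records$condition == cond, ]
    common <- intersect(ctl$gene_id, st$gene_id)
    if (!length(common)) next
    uc <- ctl$utr_len[match(common, ctl$gene_id)]
    us <- st$utr_len[match(common, st$gene_id)]
    ll_c <- uc <= leaderless_tol
    ll_s <- us <= leaderless_tol
    sw <- ll_c != ll_s
    if (!any(sw)) next
    out[[cond]] <- data.frame(
      gene_id = common[sw], condition = cond,
      direction = ifelse(ll_s[sw], "leadered_to_leaderless",
                         "leaderless_to_leadered"),
      utr_control = uc[sw], utr_stress = us[sw], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), condition = character(),
                      direction = character(), utr_control = integer(),
                      utr_stress = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

## Fixed Shine-Dalgarno score table: motif class x spacer bin. Calibrated so
## a perfect AGGAGG at the optimal 5-10 nt spacer scores 12.87 and a window
## with no SD-like word scores the floor -18.92 (the printed score range);
## intermediate bins are populated with the printed intermediate values.
RBS_SCORE_FLOOR <- -18.92
RBS_SCORE_CEILING <- 12.87

rbs_score_table <- function() {
  tab <- rbind(
    exact6 = c(12.38, 12.87, 12.09),
    exact5 = c(11.11, 12.38, 9.25),
    mm6    = c(9.25, 11.11, 7.68),
    exact4 = c(6.23, 7.68, 4.45),
    mm5    = c(3.47, 4.45, 2.21),
    exact3 = c(1.18, 2.21, 0.33))
  colnames(tab) <- c("s3_4", "s5_10", "s11_15")
  tab
}

spacer_bin <- function(s) {
  if (s <= 4) "s3_4" else if (s <= 10) "s5_10" else "s11_15"
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Shine-Dalgarno RBS strength score
#'
#' Exhaustively searches the 21 nt upstream of the start codon for the
#' best-scoring (motif, spacer) pair: AGGAGG and its subwords down to 3 nt
#' (with single-mismatch 5/6-mers in lower score bins) crossed with spacer
#' bins 3-4, 5-10 and 11-15 nt, scored from a fixed calibrated table
#' (ceiling 12.87 for AGGAGG at spacer 5-10, floor -18.92 when no motif is
#' found). The score is a pure function of the 21-nt upstream window.
#'
#' @param genome \code{DNAStringSet} (first sequence used) or a single
#'   character sequence.
#' @param cds_start,cds_end CDS bounds, 1-based closed.
#' @param strand \code{"+"} or \code{"-"}.
#' @param spacer_range allowed motif-to-start-codon spacer range, nt.
#' @return one-row data.frame \code{motif, spacer, score}; \code{motif} is
#'   \code{NA} at the floor score.
#' @export
score_rbs <- function(genome, cds_start, cds_end, strand,
                      spacer_range = c(3, 15)) {
  seqchr <- if (inherits(genome, "DNAStringSet")) as.character(genome[[1]])
            else as.character(genome)
  glen <- nchar(seqchr)
  need <- spacer_range[2] + 6L
  if (strand == "+") {
    from <- cds_start - need; to <- cds_start - 1L
    if (from < 1) {
      warn("gene at %d: insufficient upstream sequence; no-RBS floor score",
           cds_start)
      return(data.frame(motif = NA_character_, spacer = NA_integer_,
                        score = RBS_SCORE_FLOOR, stringsAsFactors = FALSE))
    }
    win <- substr(seqchr, from, to)
  } else {
    from <- cds_end + 1L; to <- cds_end + need
    if (to > glen) {
      warn("gene at %d: insufficient upstream sequence; no-RBS floor score",
           cds_end)
      return(data.frame(motif = NA_character_, spacer = NA_integer_,
                        score = RBS_SCORE_FLOOR, stringsAsFactors = FALSE))
    }
    win <- revcomp(substr(seqchr, from, to))
  }
  ## `win` now reads 5'->3' and ends immediately before the start codon
  tab <- rbs_score_table()
  wlen <- nchar(win)
  best <- list(score = RBS_SCORE_FLOOR, motif = NA_character_,
               spacer = NA_integer_)
  exact <- list(exact6 = "AGGAGG", exact5 = c("GGAGG", "AGGAG"),
                exact4 = c("AGGA", "GGAG", "GAGG"),
                exact3 = c("AGG", "GGA", "GAG"))
  for (s in spacer_range[1]:spacer_range[2]) {
    bin <- spacer_bin(s)
    for (k in c(6L, 5L, 4L, 3L)) {
      to_i <- wlen - s
      from_i <- to_i - k + 1L
      if (from_i < 1) next
      sub <- substr(win, from_i, to_i)
      cls <- NULL
      key <- paste0("exact", k)
      if (sub %in% exact[[key]]) cls <- key
      else if (k == 6L && hamming(sub, "AGGAGG") == 1L) cls <- "mm6"
      else if (k == 5L && min(vapply(exact$exact5, hamming, 0L, a = sub)) == 1L)
        cls <- "mm5"
      if (is.null(cls)) next
      sc <- tab[cls, bin]
      if (sc > best$score) best <- list(score = sc, motif = sub, spacer = s)
    }
  }
  data.frame(motif = best$motif, spacer = best$spacer, score = best$score,
             stringsAsFactors = FALSE)
}

#' Score the RBS of every gene in an annotation
#'
#' @param genome genome sequence (see [score_rbs()]).
#' @param annotation annotation index.
#' @param ... passed to [score_rbs()].
#' @return data.frame \code{gene_id, motif, spacer, score}.
#' @export
score_rbs_all <- function(genome, annotation, ...) {
  recs <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    cbind(gene_id = g$gene_id,
          score_rbs(genome, g$cds_start, g$cds_end, g$strand, ...))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Median 5'UTR length over operon-leading genes
#'
#' @param utr_len numeric vector of UTR lengths (an even count averages the
#'   central pair, the usual sample-median rule).
#' @return median UTR length.
#' @export
median_utr <- function(utr_len) {
  if (!length(utr_len)) abort("no UTR records")
  median(utr_len)
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}
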