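#' Generate strand-specific TEX+/TEX- coverage with planted TSS signals
#'
#' Emulates a differential RNA-seq (dRNA-seq) experiment: per condition and
#' strand, transcript coverage starts sharply at each operon's planted TSS and
#' extends through the operon; the TEX-treated library has the first 5 nt
#' downstream of each TSS amplified by \code{tex_enrichment}, mimicking the
#' 5'-monophosphate-dependent exonuclease enrichment of primary 5' ends.
#' Background is Poisson everywhere.
#'
#' @param annotation annotation index from [generate_genome()] (must carry the
#'   \code{contig_lengths} attribute).
#' @param truth planted-truth table from [generate_genome()].
#' @param depth mean transcript read depth per nt (> 0).
#' @param tex_enrichment multiplicative TEX+ enrichment at the TSS (>= 1).
#' @param conditions condition labels; UTRs come from the truth columns
#'   \code{utr_control} / \code{utr_stress} (any non-control label uses the
#'   stress column).
#' @param background mean Poisson background depth per nt.
#' @param seed integer seed; fixed seed gives identical tracks.
#' @return nested list \code{tracks[[condition]][[strand]][[library]]}, each a
#'   \code{coverage_track} (see [coverage_track()]); strands are \code{"+"} and
#'   \code{"-"}, libraries \code{"TEX+"} and \code{"TEX-"}.
#' @export
generate_coverage <- function(annotation, truth, depth = 50,
                              tex_enrichment = 5,
                              conditions = c("control", "stress"),
                              background = 0.3, seed = 1) {
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0)
    abort("depth must be a single positive number")
  if (tex_enrichment < 1) abort("tex_enrichment must be >= 1")
  clen <- attr(annotation, "contig_lengths")
  if (is.null(clen)) abort("annotation lacks a contig_lengths attribute")
  contig <- names(clen)[1]
  L <- unname(clen[1])
  local_seed(seed)

  operons <- split(seq_len(nrow(annotation)), annotation$operon_id)
  out <- list()
  for (cond in conditions) {
    utr <- if (cond == "control") truth$utr_control else truth$utr_stress
    vals <- list(`+` = rpois(L, background), `-` = rpois(L, background))
    tex_pos <- list(`+` = integer(0), `-` = integer(0))
    for (ix in operons) {
      strand <- annotation$strand[ix[1]]
      lead <- ix[which(truth$first_in_operon[ix])]
      u <- utr[lead]
      if (strand == "+") {
        tss <- annotation$cds_start[lead] - u
        span <- tss:max(annotation$cds_end[ix])
      } else {
        tss <- annotation$cds_end[lead] + u
        span <- min(annotation$cds_start[ix]):tss
      }
      d <- depth * rlnorm(1, 0, 0.4)
      vals[[strand]][span] <- vals[[strand]][span] + rpois(length(span), d)
      tex_pos[[strand]] <- c(tex_pos[[strand]], tss)
    }
    cond_tracks <- list()
    for (s in c("+", "-")) {
      texp <- vals[[s]]
      for (tss in tex_pos[[s]]) {
        dn <- if (s == "+") tss:(tss + 4L) else tss:(tss - 4L)
        dn <- dn[dn >= 1 & dn <= L]
        texp[dn] <- round(texp[dn] * tex_enrichment)
      }
      cond_tracks[[s]] <- list(
        `TEX+` = coverage_track(contig, s, texp, "TEX+", cond),
        `TEX-` = coverage_track(contig, s, vals[[s]], "TEX-", cond))
    }
    out[[cond]] <- cond_tracks
  }
  out
}
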