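#' Generate a miniature annotated genome with planted ground truth
#'
#' Lays out operons of geometric size along a single contig, draws per-gene
#' CDS coordinates, plants a transcription start site upstream of every
#' operon-leading gene at its true 5'UTR distance (0 for leaderless genes),
#' writes a Shine-Dalgarno motif (AGGAGG) at the configured spacer for genes
#' with a planted RBS, and assigns every gene a ground-truth expression class.
#'
#' Coordinates are 1-based closed (GFF3 convention). For minus-strand operons
#' the operon-leading gene is the rightmost one and its TSS lies downstream
#' (in contig coordinates) of its CDS end.
#'
#' @param config a [generator_config()].
#' @return a list with elements \code{genome} (a named
#'   \code{Biostrings::DNAStringSet} of one contig), \code{annotation} (an
#'   annotation index data.frame, see [read_gff3()]), and \code{truth}
#'   (a data.frame of planted ground truth, one row per gene).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(child_seed(config$seed, "genome"))
  n <- config$n_genes

  ## operon sizes: shifted geometric with mean operon_mean_size
  p_geom <- 1 / config$operon_mean_size
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, rgeom(n, p_geom) + 1L)
  cum <- cumsum(sizes)
  k <- which(cum >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)
  sizes <- sizes[sizes > 0]
  n_op <- length(sizes)

  operon_id <- rep(sprintf("op%04d", seq_len(n_op)), sizes)
  op_strand <- rep(sample(c("+", "-"), n_op, replace = TRUE), sizes)
  gene_id <- sprintf("SYN%04d", seq_len(n))

  ## position within operon, in transcription order
  pos_in_op <- sequence(sizes)
  ## For '-' operons genes are laid left-to-right in reverse transcription
  ## order, so the operon-leading gene is the rightmost.
  first_in_operon <- ifelse(op_strand == "+", pos_in_op == 1L,
                            pos_in_op == ave(pos_in_op, operon_id, FUN = max))

  cds_len <- 3L * sample(100:200, n, replace = TRUE)

  ## ground-truth UTRs for operon-leading genes; clamped to [6, 250] so a
  ## planted leadered UTR is never confusable with leaderless at tolerance 5
  draw_utr <- function(m) {
    u <- round(rlnorm(m, meanlog = log(config$utr_median),
                      sdlog = config$utr_sigma))
    pmin(pmax(u, 6L), 250L)
  }
  utr_control <- rep(NA_integer_, n)
  lead <- which(first_in_operon)
  is_ll <- rbinom(length(lead), 1, config$leaderless_fraction) == 1
  utr_control[lead] <- ifelse(is_ll, 0L, draw_utr(length(lead)))

  ## condition-dependent TSS switches
  utr_stress <- utr_control
  n_shift <- round(config$tss_shift_fraction * length(lead))
  if (n_shift > 0) {
    shift <- sample(lead, n_shift)
    for (g in shift) {
      utr_stress[g] <- if (utr_control[g] == 0L) draw_utr(1L) else 0L
    }
  }

  ## layout: generous inter-operon gap leaves room for UTR + TSS search window
  intra_gap <- 20L
  op_gap <- 400L
  cds_start <- integer(n); cds_end <- integer(n)
  cursor <- 500L
  idx <- 1L
  for (o in seq_len(n_op)) {
    cursor <- cursor + op_gap
    for (j in seq_len(sizes[o])) {
      cds_start[idx] <- cursor
      cds_end[idx] <- cursor + cds_len[idx] - 1L
      cursor <- cds_end[idx] + intra_gap
      idx <- idx + 1L
    }
  }
  genome_len <- cursor + 500L

  ## planted TSS coordinates per condition (NA for internal operon genes)
  tss_at <- function(utr) {
    ifelse(is.na(utr), NA_integer_,
           ifelse(op_strand == "+", cds_start - utr, cds_end + utr))
  }
  tss_control <- tss_at(utr_control)
  tss_stress <- tss_at(utr_stress)

  ## sequence with start/stop codons and planted SD motifs
  seq_chr <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  sd_motif <- rep("", n)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  place <- function(at, nt, strand) {
    ## write `nt` occupying positions at..at+len-1 on the given strand
    ## (for '-' the motif is reverse-complemented into contig space)
    v <- strsplit(nt, "")[[1]]
    if (strand == "-") v <- rev(unname(comp[v]))
    seq_chr[at:(at + length(v) - 1L)] <<- v
  }
  spacer <- config$sd_spacer
  for (i in seq_len(n)) {
    s <- op_strand[i]
    if (s == "+") {
      place(cds_start[i], "ATG", "+")
      place(cds_end[i] - 2L, "TAA", "+")
    } else {
      place(cds_end[i] - 2L, "ATG", "-")
      place(cds_start[i], "TAA", "-")
    }
    ## plant an SD motif unless the gene is (planted) leaderless in control,
    ## or its UTR is too short to host motif + spacer
    leaderless_here <- first_in_operon[i] && !is.na(utr_control[i]) &&
      utr_control[i] == 0L
    room <- !first_in_operon[i] || is.na(utr_control[i]) ||
      utr_control[i] >= spacer + 6L
    if (!leaderless_here && room) {
      if (s == "+") {
        place(cds_start[i] - spacer - 6L, "AGGAGG", "+")
      } else {
        place(cds_end[i] + spacer + 1L, "AGGAGG", "-")
      }
      sd_motif[i] <- "AGGAGG"
    }
  }

  genome <- Biostrings::DNAStringSet(paste(seq_chr, collapse = ""))
  names(genome) <- "synctg1"

  ## ground-truth expression classes and per-gene generative parameters
  cls_tab <- class_param_table()
  classes <- sample(cls_tab$class, n, replace = TRUE,
                    prob = config$class_fractions[cls_tab$class])
  row <- match(classes, cls_tab$class)
  u_m <- runif(n, cls_tab$u_m_lo[row], cls_tab$u_m_hi[row])
  ## protein baseline percentile tracks the mRNA one unless the class pins it
  z <- 0.85 * qnorm(u_m) + sqrt(1 - 0.85^2) * rnorm(n)
  u_p <- pnorm(z)
  pin <- !is.na(cls_tab$u_p_lo[row])
  u_p[pin] <- runif(sum(pin), cls_tab$u_p_lo[row[pin]], cls_tab$u_p_hi[row[pin]])
  baseline_mrna <- qlnorm(u_m, config$baseline_meanlog, config$baseline_sdlog)
  baseline_protein <- qlnorm(u_p, config$baseline_meanlog, config$baseline_sdlog)

  cogs <- sample(strsplit("CDEFGHIJKLMNOPQRSTUV", "")[[1]], n, replace = TRUE)

  annotation <- data.frame(
    gene_id = gene_id, contig = "synctg1", strand = op_strand,
    cds_start = cds_start, cds_end = cds_end,
    operon_id = operon_id, first_in_operon = first_in_operon,
    cog = cogs, stringsAsFactors = FALSE)
  attr(annotation, "contig_lengths") <- c(synctg1 = genome_len)

  truth <- data.frame(
    gene_id = gene_id, strand = op_strand, operon_id = operon_id,
    first_in_operon = first_in_operon,
    utr_control = utr_control, utr_stress = utr_stress,
    tss_control = tss_control, tss_stress = tss_stress,
    true_class = classes,
    mrna_log2fc_high = cls_tab$m_high[row],
    protein_log2fc_high = cls_tab$p_high[row],
    true_translation_boost = 2^(cls_tab$p_high[row] - cls_tab$m_high[row]),
    baseline_mrna = baseline_mrna,
    baseline_protein = baseline_protein,
    sd_motif_planted = sd_motif,
    cog = cogs, stringsAsFactors = FALSE)

  list(genome = genome, annotation = annotation, truth = truth)
}

#' Write / read the planted-truth table
#'
#' Lossless TSV round-trip of the ground-truth table emitted by
#' [generate_genome()].
#' @param truth truth data.frame.
#' @param path file path.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- read_tsv(path)
  tr$first_in_operon <- as.logical(tr$first_in_operon)
  tr$sd_motif_planted[is.na(tr$sd_motif_planted)] <- ""
  tr
}
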