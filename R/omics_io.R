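#' Per-nucleotide strand-specific coverage track
#'
#' A dense, per-nt non-negative depth vector over one contig, tagged with
#' strand, library (TEX-treated or not) and condition.
#'
#' @param contig contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param values numeric vector of per-nt depth, length = contig length.
#' @param library \code{"TEX+"} or \code{"TEX-"}.
#' @param condition condition label.
#' @export
coverage_track <- function(contig, strand, values, library = "TEX-",
                           condition = "control") {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (!library %in% c("TEX+", "TEX-")) abort("library must be 'TEX+' or 'TEX-'")
  if (any(values < 0)) abort("coverage values must be >= 0")
  structure(list(contig = contig, strand = strand,
                 values = as.numeric(values),
                 library = library, condition = condition),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s) %s/%s: %d nt, mean depth %.2f\n",
              x$contig, x$strand, x$condition, x$library,
              length(x$values), mean(x$values)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## FASTA

#' Read / write a genome FASTA
#' @param path file path.
#' @param genome a \code{Biostrings::DNAStringSet}.
#' @return \code{read_fasta}: a \code{DNAStringSet}.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GFF3 annotation

#' Read a GFF3 gene annotation into an annotation index
#'
#' Parses CDS/gene features (via \pkg{rtracklayer}) into a validated
#' data.frame with one row per gene: \code{gene_id, contig, strand,
#' cds_start, cds_end} (1-based closed), \code{operon_id, first_in_operon,
#' cog}. Records are ordered deterministically by (contig, cds_start).
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named vector of contig lengths, attached as
#'   an attribute (needed downstream by the TSS caller).
#' @return annotation index data.frame.
#' @export
read_gff3 <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("CDS", "gene")]
  if (length(gr) == 0) abort("no CDS/gene features in %s", path)
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  if (anyNA(ids) || any(ids == ""))
    abort("GFF3 features must carry an ID attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    bad <- ids[strand == "*"][1]
    abort("missing strand for feature '%s'", bad)
  }
  if (anyDuplicated(ids)) {
    abort("duplicate gene id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  fio <- md$first_in_operon
  ann <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    cds_start = BiocGenerics::start(gr),
    cds_end = BiocGenerics::end(gr),
    operon_id = if (!is.null(md$operon)) as.character(md$operon) else ids,
    first_in_operon = if (!is.null(fio)) fio %in% c("1", "true", "TRUE") else TRUE,
    cog = if (!is.null(md$cog)) as.character(md$cog) else NA_character_,
    stringsAsFactors = FALSE)
  ann$cog[!is.na(ann$cog) & ann$cog == ""] <- NA_character_
  if (any(ann$cds_start > ann$cds_end))
    abort("gene '%s' has end < start", ann$gene_id[ann$cds_start > ann$cds_end][1])
  ann <- ann[order(ann$contig, ann$cds_start), , drop = FALSE]
  rownames(ann) <- NULL
  for (op in unique(ann$operon_id[ann$first_in_operon])) {
    if (!op %in% ann$operon_id) abort("operon '%s' referenced but absent", op)
  }
  if (!is.null(contig_lengths)) attr(ann, "contig_lengths") <- contig_lengths
  ann
}

#' @rdname read_gff3
#' @param annotation annotation index data.frame.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(annotation$cds_start, annotation$cds_end),
    strand = annotation$strand)
  gr$type <- "CDS"
  gr$ID <- annotation$gene_id
  gr$operon <- annotation$operon_id
  gr$first_in_operon <- ifelse(annotation$first_in_operon, "1", "0")
  cg <- annotation$cog
  cg[is.na(cg)] <- "NA"
  gr$cog <- cg
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

## ---------------------------------------------------------------------------
## bedGraph coverage

#' Read / write a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open on disk and are expanded to a
#' dense 1-based per-nt vector in memory. Positions not covered by any
#' interval are 0. Overlapping intervals follow a last-interval-wins dialect
#' and raise a warning. Negative values, malformed lines and out-of-bounds
#' intervals fail with the offending line number.
#'
#' @param path bedGraph file (4 columns: contig, start, end, value).
#' @param contig_lengths named vector with the length of the track's contig.
#' @param strand,library,condition metadata attached to the returned track.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, contig_lengths, strand = "+",
                          library = "TEX-", condition = "control") {
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  contig <- names(contig_lengths)[1]
  L <- unname(contig_lengths[1])
  values <- numeric(L)
  covered <- logical(L)
  overlap_warned <- FALSE
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      abort("%s line %d: expected 4 tab-separated fields", path, i)
    s0 <- suppressWarnings(as.numeric(f[2]))
    e0 <- suppressWarnings(as.numeric(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (anyNA(c(s0, e0, v)))
      abort("%s line %d: non-numeric coordinates or value", path, i)
    if (f[1] != contig)
      abort("%s line %d: unknown contig '%s'", path, i, f[1])
    if (v < 0) abort("%s line %d: negative coverage value", path, i)
    if (s0 < 0 || e0 > L || s0 >= e0)
      abort("%s line %d: interval [%g, %g) out of bounds for contig of length %d",
            path, i, s0, e0, L)
    span <- (s0 + 1L):e0                     # to 1-based closed
    if (!overlap_warned && any(covered[span])) {
      warn("%s line %d: overlapping intervals; last interval wins", path, i)
      overlap_warned <- TRUE
    }
    values[span] <- v
    covered[span] <- TRUE
  }
  coverage_track(contig, strand, values, library, condition)
}

#' @rdname read_bedgraph
#' @param track a [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths              # 0-based starts
  keep <- r$values != 0
  df <- data.frame(track$contig, starts0[keep], ends[keep], r$values[keep])
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Expression matrices

#' Parse `<stressor>_<level>_<time>_<rep>` sample names
#'
#' @param x character vector of sample names, e.g. \code{"BuOH_high_75_2"}.
#' @return data.frame with columns sample, stressor, level, time, rep.
#' @export
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)_(ctrl|low|med|high)_([0-9]+)_([0-9]+)$", x))
  bad <- which(vapply(m, length, 1L) != 5L)
  if (length(bad))
    abort("malformed sample name '%s' (want <stressor>_<level>_<time>_<rep>)",
          x[bad[1]])
  data.frame(sample = x,
             stressor = vapply(m, `[`, "", 2L),
             level = vapply(m, `[`, "", 3L),
             time = as.integer(vapply(m, `[`, "", 4L)),
             rep = as.integer(vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Read / write an expression matrix TSV
#'
#' First column \code{gene_id} (or \code{protein_id}), remaining columns
#' samples named \code{<stressor>_<level>_<time>_<rep>}. \code{kind} controls
#' validation: \code{counts} must be non-negative integers with no missing
#' cells; \code{log_ratio} must be complete numerics; \code{protein_ratio}
#' and \code{abundance} allow empty cells (= not detected) but present values
#' must be positive.
#'
#' @param path TSV file.
#' @param kind one of \code{"counts"}, \code{"log_ratio"},
#'   \code{"protein_ratio"}, \code{"abundance"}.
#' @return numeric matrix (genes x samples) with a \code{samples} attribute
#'   holding the parsed sample metadata.
#' @export
read_matrix <- function(path, kind = c("counts", "log_ratio",
                                       "protein_ratio", "abundance")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  if (ncol(df) < 2) abort("%s: need a gene_id column plus >= 1 sample", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) abort("%s: duplicate feature id '%s'",
                                path, ids[duplicated(ids)][1])
  meta <- parse_sample_names(colnames(df)[-1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    abort("%s: non-numeric values in sample column '%s'",
          path, colnames(df)[-1][bad])
  }
  rownames(m) <- ids
  if (kind == "counts") {
    if (anyNA(m)) abort("%s: missing values not allowed in a count matrix", path)
    if (any(m < 0) || any(m != floor(m)))
      abort("%s: counts must be non-negative integers (first bad feature '%s')",
            path, ids[which(rowSums(m < 0 | m != floor(m)) > 0)[1]])
    storage.mode(m) <- "integer"
  } else if (kind == "log_ratio") {
    if (anyNA(m)) abort("%s: missing values not allowed in a log-ratio matrix",
                        path)
  } else {
    if (any(m[!is.na(m)] <= 0))
      abort("%s: %s values must be positive where present", path, kind)
  }
  attr(m, "samples") <- meta
  m
}

#' @rdname read_matrix
#' @param m matrix with feature rownames; NA cells are written empty.
#' @param id_col name for the feature-id column.
#' @export
write_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv(df, path)
}
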