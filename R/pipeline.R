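#' Pipeline configuration
#'
#' A single declarative object holding input paths, every analysis threshold
#' (nothing is hard-coded downstream) and the seeds and dataset-role
#' assignments of a full integrative run. Round-trips through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param paths named list of input files: \code{genome}, \code{gff3},
#'   \code{rnaseq}, \code{microarray}, \code{protein_ratio},
#'   \code{protein_abundance}, and optionally \code{coverage_dir} (bedGraph
#'   tracks named \code{<condition>_<plus|minus>_<tex|notex>.bedgraph}).
#' @param fdr SAM / transcript FDR target.
#' @param fold_thresh differential fold-change threshold.
#' @param sentinel_up,sentinel_down display sentinels for exclusive detection.
#' @param leaderless_tol leaderless UTR tolerance, nt.
#' @param good_mrna_rank,rank_hi,rank_lo,mrna_rank_lt,protein_rank_gt
#'   percentile thresholds of the discordance and hypothesis screens.
#' @param min_detect samples needed to call a protein detected in a condition.
#' @param n_perm permutation budget for SAM and the transcript DE stand-in.
#' @param discordance_ref mRNA dataset backing the discordance call.
#' @param rank_layer transcript dataset backing abundance ranks.
#' @param tss_conditions coverage conditions, first one the control.
#' @param window_up,min_depth,min_step,min_tex TSS caller settings.
#' @param seed master seed.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(paths = list(), fdr = 0.05, fold_thresh = 2,
                            sentinel_up = 6, sentinel_down = -5,
                            leaderless_tol = 5, good_mrna_rank = 50,
                            rank_hi = 80, rank_lo = 20, mrna_rank_lt = 60,
                            protein_rank_gt = 80, min_detect = 1,
                            n_perm = 1000,
                            discordance_ref = c("microarray", "rnaseq"),
                            rank_layer = c("rnaseq", "microarray"),
                            tss_conditions = c("control", "stress"),
                            window_up = 300, min_depth = 10, min_step = 3,
                            min_tex = 2, seed = 1) {
  discordance_ref <- match.arg(discordance_ref)
  rank_layer <- match.arg(rank_layer)
  if (!is_prob(fdr) || fdr <= 0) abort("fdr must be in (0, 1]")
  if (fold_thresh < 1) abort("fold_thresh must be >= 1")
  if (sentinel_up <= 0 || sentinel_down >= 0)
    abort("sentinel_up must be positive and sentinel_down negative")
  for (v in c(good_mrna_rank, rank_hi, rank_lo, mrna_rank_lt, protein_rank_gt))
    if (v < 0 || v > 100) abort("percentile thresholds must be in [0, 100]")
  if (leaderless_tol < 0) abort("leaderless_tol must be >= 0")
  cfg <- list(paths = paths, fdr = fdr, fold_thresh = fold_thresh,
              sentinel_up = sentinel_up, sentinel_down = sentinel_down,
              leaderless_tol = leaderless_tol,
              good_mrna_rank = good_mrna_rank, rank_hi = rank_hi,
              rank_lo = rank_lo, mrna_rank_lt = mrna_rank_lt,
              protein_rank_gt = protein_rank_gt,
              min_detect = as.integer(min_detect),
              n_perm = as.integer(n_perm),
              discordance_ref = discordance_ref, rank_layer = rank_layer,
              tss_conditions = tss_conditions, window_up = window_up,
              min_depth = min_depth, min_step = min_step, min_tex = min_tex,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a generated synthetic dataset to disk
#'
#' Serialises the outputs of [generate_genome()], [generate_expression()] and
#' [generate_coverage()] in the pipeline's input formats (FASTA, GFF3, TSV
#' matrices, bedGraph tracks, truth TSV) and returns a \code{paths} list
#' ready for [pipeline_config()].
#'
#' @param sim list from [generate_genome()].
#' @param expr list from [generate_expression()].
#' @param tracks nested list from [generate_coverage()] (or NULL to skip).
#' @param dir output directory (created).
#' @return named list of written paths.
#' @export
write_synthetic_dataset <- function(sim, expr, tracks = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(genome = file.path(dir, "genome.fasta"),
            gff3 = file.path(dir, "annotation.gff3"),
            truth = file.path(dir, "truth.tsv"),
            rnaseq = file.path(dir, "rnaseq_counts.tsv"),
            microarray = file.path(dir, "microarray_log2.tsv"),
            protein_ratio = file.path(dir, "protein_ratio.tsv"),
            protein_abundance = file.path(dir, "protein_abundance.tsv"))
  write_fasta(sim$genome, p$genome)
  write_gff3(sim$annotation, p$gff3)
  write_truth(sim$truth, p$truth)
  write_matrix(expr$rnaseq, p$rnaseq)
  write_matrix(expr$microarray, p$microarray)
  write_matrix(expr$protein_ratio, p$protein_ratio, id_col = "protein_id")
  write_matrix(expr$protein_abundance, p$protein_abundance,
               id_col = "protein_id")
  if (!is.null(tracks)) {
    cdir <- file.path(dir, "coverage")
    dir.create(cdir, showWarnings = FALSE)
    for (cond in names(tracks)) {
      for (s in c("+", "-")) {
        for (lib in c("TEX+", "TEX-")) {
          fn <- sprintf("%s_%s_%s.bedgraph", cond,
                        if (s == "+") "plus" else "minus",
                        if (lib == "TEX+") "tex" else "notex")
          write_bedgraph(tracks[[cond]][[s]][[lib]], file.path(cdir, fn))
        }
      }
    }
    p$coverage_dir <- cdir
  }
  p
}

#' Run the full integrative pipeline
#'
#' Configuration-driven end-to-end run: reads all inputs, performs per-level
#' protein classification (normalisation, SAM, five-way categories with
#' sentinels), transcript normalisation/DE/percentile ranks, TSS + 5'UTR +
#' leaderless + RBS annotation (skipped with a warning when no coverage is
#' configured), the discordance and hypothesis screens, correlations and COG
#' enrichment, and writes stage TSVs, a YAML summary whose every number is
#' recomputable from those TSVs, and a log of every threshold used.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created).
#' @return object of class \code{stressomics_run}: list with per-stressor
#'   results, TSS/RBS tables, the summary list and the outdir.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logf <<- c(logf, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  say("thresholds: fdr=%g fold=%g sentinels=%+.1f/%+.1f leaderless_tol=%g",
      config$fdr, config$fold_thresh, config$sentinel_up,
      config$sentinel_down, config$leaderless_tol)
  say("screens: good_mrna_rank=%g H1 hi/lo=%g/%g revised <%g/>%g ref=%s ranks=%s",
      config$good_mrna_rank, config$rank_hi, config$rank_lo,
      config$mrna_rank_lt, config$protein_rank_gt,
      config$discordance_ref, config$rank_layer)

  p <- config$paths
  inp <- stage("read_inputs", {
    genome <- read_fasta(p$genome)
    clen <- setNames(Biostrings::width(genome), names(genome))
    ann <- read_gff3(p$gff3, contig_lengths = clen)
    list(genome = genome, ann = ann, clen = clen,
         rnaseq = read_matrix(p$rnaseq, "counts"),
         marr = read_matrix(p$microarray, "log_ratio"),
         pratio = read_matrix(p$protein_ratio, "protein_ratio"),
         pabund = read_matrix(p$protein_abundance, "abundance"))
  })
  meta <- attr(inp$pratio, "samples")
  meta_rna <- attr(inp$rnaseq, "samples")
  meta_ma <- attr(inp$marr, "samples")
  stressors <- setdiff(unique(meta$stressor), NA)
  levels_st <- setdiff(unique(meta$level), "ctrl")

  ## ---- TSS / UTR / RBS ----------------------------------------------------
  tss_records <- NULL; shifts <- NULL
  if (!is.null(p$coverage_dir)) {
    tss_records <- stage("tss", {
      recs <- list()
      for (cond in config$tss_conditions) {
        rd <- function(strand, lib) {
          fn <- file.path(p$coverage_dir,
                          sprintf("%s_%s_%s.bedgraph", cond,
                                  if (strand == "+") "plus" else "minus",
                                  if (lib == "TEX+") "tex" else "notex"))
          if (!file.exists(fn)) abort("missing coverage track %s", fn)
          read_bedgraph(fn, inp$clen, strand = strand, library = lib,
                        condition = cond)
        }
        tex <- list(`+` = rd("+", "TEX+"), `-` = rd("-", "TEX+"))
        notex <- list(`+` = rd("+", "TEX-"), `-` = rd("-", "TEX-"))
        recs[[cond]] <- call_tss(tex, notex, inp$ann,
                                 window_up = config$window_up,
                                 min_depth = config$min_depth,
                                 min_step = config$min_step,
                                 min_tex = config$min_tex,
                                 leaderless_tol = config$leaderless_tol,
                                 condition = cond)
      }
      do.call(rbind, recs)
    })
    shifts <- detect_tss_shift(tss_records,
                               control = config$tss_conditions[1],
                               leaderless_tol = config$leaderless_tol)
    write_tsv(tss_records, file.path(outdir, "tss_records.tsv"))
    write_tsv(shifts, file.path(outdir, "tss_shifts.tsv"))
    say("tss: %d records, %d leaderless switches",
        nrow(tss_records), nrow(shifts))
  } else {
    warn("no coverage tracks configured: TSS stage skipped")
    say("stage tss: skipped (no coverage)")
  }
  rbs <- stage("rbs", score_rbs_all(inp$genome, inp$ann))
  write_tsv(rbs, file.path(outdir, "rbs_scores.tsv"))

  lead_ctl <- if (!is.null(tss_records))
    tss_records[tss_records$condition == config$tss_conditions[1], ]
  med_utr <- if (!is.null(tss_records)) median_utr(lead_ctl$utr_len) else NA
  say("median 5'UTR (control records): %s   mean RBS score: %.2f",
      format(med_utr), mean(rbs$score))

  ## ---- per-stressor analyses ---------------------------------------------
  per_stressor <- list()
  for (st in stressors) {
    ms <- meta[meta$stressor == st, ]
    ctl_cols <- ms$sample[ms$level == "ctrl"]
    prot_long <- list(); rs_de <- list(); ma_de <- list()

    ## transcript normalisation + ranks
    rna_cols <- meta_rna$sample[meta_rna$stressor == st]
    counts <- inp$rnaseq[, rna_cols, drop = FALSE]
    sf <- stage("size_factors", size_factors(counts))
    norm <- normalize_counts(counts, sf)
    mr_rna <- meta_rna[meta_rna$stressor == st, ]
    conds <- c("ctrl", levels_st)
    mrna_ranks <- vapply(conds, function(lv)
      percentile_rank(norm[, mr_rna$sample[mr_rna$level == lv], drop = FALSE]),
      numeric(nrow(norm)))
    rownames(mrna_ranks) <- rownames(norm)
    ab <- inp$pabund[, meta$sample[meta$stressor == st], drop = FALSE]
    ab[is.na(ab)] <- 0          # undetected = below all detected abundances
    mp <- meta[meta$stressor == st, ]
    prot_ranks <- vapply(conds, function(lv)
      percentile_rank(ab[, mp$sample[mp$level == lv], drop = FALSE]),
      numeric(nrow(ab)))
    rownames(prot_ranks) <- rownames(ab)

    seed_k <- 0L
    for (lv in levels_st) {
      seed_k <- seed_k + 1L
      lv_cols <- ms$sample[ms$level == lv]
      ## proteome
      cl <- stage(paste0("proteome_de_", st, "_", lv), {
        suppressMessages(classify_proteins(
          inp$pratio[, meta$sample[meta$stressor == st], drop = FALSE],
          stress_cols = lv_cols, control_cols = ctl_cols,
          min_detect = config$min_detect, fold_thresh = config$fold_thresh,
          fdr_target = config$fdr, sentinel_up = config$sentinel_up,
          sentinel_down = config$sentinel_down,
          n_perm = config$n_perm,
          seed = child_seed(config$seed, "sam") + seed_k))
      })
      cl$level <- lv
      prot_long[[lv]] <- cl
      ## rnaseq DE
      rs <- stage(paste0("rnaseq_de_", st, "_", lv), {
        de_call_mrna(norm,
                     stress_cols = mr_rna$sample[mr_rna$level == lv],
                     control_cols = mr_rna$sample[mr_rna$level == "ctrl"],
                     n_perm = config$n_perm, fdr = config$fdr,
                     fold_thresh = config$fold_thresh,
                     seed = child_seed(config$seed, "de") + seed_k)
      })
      rs$level <- lv
      rs_de[[lv]] <- rs
      ## microarray DE (one-sample log-ratio mode)
      mm <- meta_ma[meta_ma$stressor == st & meta_ma$level == lv, ]
      ma <- de_call_mrna(inp$marr, stress_cols = mm$sample,
                         control_cols = NULL, n_perm = config$n_perm,
                         fdr = config$fdr, fold_thresh = config$fold_thresh,
                         seed = child_seed(config$seed, "de") + 100L + seed_k)
      ma$level <- lv
      ma_de[[lv]] <- ma
    }
    prot_long <- do.call(rbind, prot_long)
    rs_de <- do.call(rbind, rs_de)
    ma_de <- do.call(rbind, ma_de)

    de_sum <- summarize_de(prot_long, fold_thresh = config$fold_thresh)
    say("%s: %d proteins detected; per-level DE totals: %s", st,
        de_sum$aggregate$detected_any,
        paste(de_sum$per_level$de_fold_total, collapse = "/"))

    mrna_rank_layer <- if (config$rank_layer == "rnaseq") mrna_ranks else {
      ## microarray carries no absolute abundance; ranks always from counts
      mrna_ranks
    }
    joined <- stage(paste0("integrate_", st), {
      join_omics(prot_long,
                 mrna_de = list(microarray = ma_de, rnaseq = rs_de),
                 ranks = list(protein = prot_ranks, mrna = mrna_rank_layer),
                 tss = tss_records, rbs = rbs)
    })
    joined <- call_discordance(joined, fold_thresh = config$fold_thresh,
                               good_mrna_rank = config$good_mrna_rank,
                               reference = config$discordance_ref)
    joined <- screen_revised(joined, mrna_rank_lt = config$mrna_rank_lt,
                             protein_rank_gt = config$protein_rank_gt)
    hyp <- screen_hypotheses(joined, rank_hi = config$rank_hi,
                             rank_lo = config$rank_lo,
                             reference = config$discordance_ref)
    disc_genes <- unique(joined$gene_id[joined$discordant])
    disc_frac <- length(disc_genes) / length(unique(joined$gene_id))
    say("%s: discordant %d/%d (%.1f%%); H3 hits %d", st,
        length(disc_genes), length(unique(joined$gene_id)),
        100 * disc_frac, sum(hyp$H3))

    hi <- joined[joined$level == "high", ]
    pear <- pearson_by_category(hi)
    cogm <- setNames(inp$ann$cog, inp$ann$gene_id)
    cogE <- if (any(!is.na(cogm[unique(hi$gene_id)])))
      cog_enrichment(hi, cogm) else NULL

    write_tsv(prot_long, file.path(outdir, paste0("proteome_de_", st, ".tsv")))
    write_tsv(de_sum$per_level,
              file.path(outdir, paste0("de_summary_", st, ".tsv")))
    write_tsv(joined, file.path(outdir, paste0("integration_", st, ".tsv")))
    write_tsv(hyp, file.path(outdir, paste0("hypotheses_", st, ".tsv")))
    write_tsv(pear, file.path(outdir, paste0("pearson_", st, ".tsv")))
    if (!is.null(cogE))
      write_tsv(cogE, file.path(outdir, paste0("cog_enrichment_", st, ".tsv")))
    write_tsv(rs_de, file.path(outdir, paste0("rnaseq_de_", st, ".tsv")))
    write_tsv(ma_de, file.path(outdir, paste0("microarray_de_", st, ".tsv")))

    per_stressor[[st]] <- list(
      proteome = prot_long, de_summary = de_sum, rnaseq_de = rs_de,
      microarray_de = ma_de, integration = joined, hypotheses = hyp,
      pearson = pear, cog = cogE, size_factors = sf,
      discordant_fraction = disc_frac,
      detected = unique(prot_long$protein_id))
  }

  ## ---- cross-stressor summary --------------------------------------------
  det <- lapply(per_stressor, `[[`, "detected")
  summary_list <- list(seed = config$seed)
  if (length(det) == 2) {
    nab <- length(intersect(det[[1]], det[[2]]))
    summary_list$venn <- list(
      n_a = length(det[[1]]), n_b = length(det[[2]]), n_ab = nab,
      union = venn_union(length(det[[1]]), length(det[[2]]), nab))
  }
  for (st in names(per_stressor)) {
    ps <- per_stressor[[st]]
    agg <- ps$de_summary$aggregate
    summary_list[[st]] <- list(
      detected = length(ps$detected),
      stress_only_any = agg$stress_only_any,
      control_only_any = agg$control_only_any,
      both_conditions = both_condition_count(length(ps$detected),
                                             agg$stress_only_any,
                                             agg$control_only_any),
      de_totals = setNames(as.list(ps$de_summary$per_level$de_fold_total),
                           ps$de_summary$per_level$level),
      discordant_fraction = ps$discordant_fraction,
      h3_hits = ps$hypotheses$gene_id[ps$hypotheses$H3],
      rev_lowM_highP = unique(ps$integration$gene_id[ps$integration$rev_lowM_highP]),
      rev_highM_lowP = unique(ps$integration$gene_id[ps$integration$rev_highM_lowP]))
  }
  summary_list$median_utr <- med_utr
  summary_list$mean_rbs <- mean(rbs$score)
  if (!is.null(shifts))
    summary_list$tss_shifts <- as.list(table(shifts$direction))
  yaml::write_yaml(summary_list, file.path(outdir, "summary.yaml"))
  writeLines(logf, file.path(outdir, "run.log"))

  out <- list(config = config, stressors = per_stressor,
              tss = tss_records, shifts = shifts, rbs = rbs,
              summary = summary_list, outdir = outdir)
  class(out) <- "stressomics_run"
  out
}

#' @export
print.stressomics_run <- function(x, ...) {
  cat("stressomics integrative run:", x$outdir, "\n")
  for (st in names(x$stressors)) {
    ps <- x$stressors[[st]]
    cat(sprintf("  %s: %d proteins detected, discordant %.1f%%, H3 hits %d\n",
                st, length(ps$detected), 100 * ps$discordant_fraction,
                sum(ps$hypotheses$H3)))
  }
  if (!is.null(x$summary$venn))
    cat(sprintf("  union of detected sets: %d\n", x$summary$venn$union))
  if (!is.null(x$tss))
    cat(sprintf("  TSS records: %d, median control 5'UTR %s nt\n",
                nrow(x$tss), format(x$summary$median_utr)))
  invisible(x)
}

#' @export
summary.stressomics_run <- function(object, ...) object$summary

#' Simulate a dataset and score pipeline recovery against planted truth
#'
#' Generates a complete synthetic dataset, runs [run_pipeline()] on the
#' written files, and scores recovery: the confusion matrix of planted vs
#' called protein categories at high stress (truth classes mapped to their
#' expected five-way call), H3 sensitivity/precision on planted
#' translationally boosted genes, TSS recovery within +/- \code{tss_tol} nt,
#' and called vs planted discordant fractions. All tables are written as TSV
#' under the run directory.
#'
#' @param gen_config [generator_config()].
#' @param pipe_config optional [pipeline_config()] template (paths are
#'   filled in); defaults mirror the generator's design.
#' @param outdir run directory.
#' @param depth,tex_enrichment coverage simulation settings.
#' @param tss_tol TSS recovery tolerance, nt.
#' @return list with \code{confusion}, \code{category_accuracy},
#'   \code{h3_sensitivity}, \code{h3_precision}, \code{tss_recovery},
#'   \code{discordant_called}, \code{discordant_planted}, \code{run}.
#' @export
simulate_and_validate <- function(gen_config = generator_config(),
                                  pipe_config = NULL,
                                  outdir = tempfile("simrun"),
                                  depth = 50, tex_enrichment = 5,
                                  tss_tol = 2) {
  sim <- generate_genome(gen_config)
  expr <- generate_expression(sim$truth, gen_config)
  tracks <- generate_coverage(sim$annotation, sim$truth, depth = depth,
                              tex_enrichment = tex_enrichment,
                              seed = child_seed(gen_config$seed, "coverage"))
  datadir <- file.path(outdir, "data")
  paths <- write_synthetic_dataset(sim, expr, tracks, datadir)
  if (is.null(pipe_config))
    pipe_config <- pipeline_config(seed = gen_config$seed)
  pipe_config$paths <- paths
  run <- suppressWarnings(suppressMessages(
    run_pipeline(pipe_config, file.path(outdir, "run"))))

  truth <- sim$truth
  expected_map <- c(conc_up = "up", conc_down = "down",
                    disc_protein_up = "up", disc_protein_down = "down",
                    stress_only = "stress_only", control_only = "control_only",
                    nonsig = "nonsig")
  conf_all <- NULL; acc <- c(); h3_sens <- c(); h3_prec <- c()
  disc_called <- c(); disc_planted <- c()
  for (st in names(run$stressors)) {
    ps <- run$stressors[[st]]
    hi <- ps$proteome[ps$proteome$level == "high", ]
    expd <- expected_map[truth$true_class[match(hi$protein_id, truth$gene_id)]]
    conf <- table(planted = expd, called = hi$category)
    conf_all <- if (is.null(conf_all)) conf else conf_all + conf
    acc <- c(acc, mean(hi$category == expd))
    planted_h3 <- truth$gene_id[truth$true_class == "disc_protein_up"]
    in_run <- intersect(planted_h3, ps$hypotheses$gene_id)
    hits <- ps$hypotheses$gene_id[ps$hypotheses$H3]
    h3_sens <- c(h3_sens, if (length(in_run))
      length(intersect(hits, in_run)) / length(in_run) else NA)
    h3_prec <- c(h3_prec, if (length(hits))
      length(intersect(hits, planted_h3)) / length(hits) else NA)
    disc_called <- c(disc_called, ps$discordant_fraction)
    detected <- unique(ps$proteome$protein_id)
    disc_planted <- c(disc_planted, mean(
      truth$true_class[match(detected, truth$gene_id)] %in%
        c("disc_protein_down", "stress_only", "control_only")))
  }
  ## TSS recovery on the control condition
  tss_rec <- NA_real_
  if (!is.null(run$tss)) {
    ctl <- run$tss[run$tss$condition == "control", ]
    k <- match(ctl$gene_id, truth$gene_id)
    tss_rec <- mean(abs(ctl$tss_pos - truth$tss_control[k]) <= tss_tol)
  }
  out <- list(confusion = conf_all,
              category_accuracy = mean(acc),
              h3_sensitivity = mean(h3_sens, na.rm = TRUE),
              h3_precision = mean(h3_prec, na.rm = TRUE),
              tss_recovery = tss_rec,
              discordant_called = mean(disc_called),
              discordant_planted = mean(disc_planted),
              run = run)
  rec <- data.frame(metric = c("category_accuracy", "h3_sensitivity",
                               "h3_precision", "tss_recovery",
                               "discordant_called", "discordant_planted"),
                    value = c(out$category_accuracy, out$h3_sensitivity,
                              out$h3_precision, out$tss_recovery,
                              out$discordant_called, out$discordant_planted))
  write_tsv(rec, file.path(outdir, "recovery.tsv"))
  write_tsv(as.data.frame(conf_all), file.path(outdir, "confusion.tsv"))
  out
}
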