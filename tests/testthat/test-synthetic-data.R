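test_that("generator config validates its inputs", {
  expect_error(generator_config(n_genes = 10), "too small")
  expect_error(generator_config(leaderless_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(class_fractions = c(conc_up = 1)), "named")
  bad <- c(conc_up = 0.5, conc_down = 0.5, disc_protein_up = 0.5,
           disc_protein_down = 0, stress_only = 0, control_only = 0,
           nonsig = 0)
  expect_error(generator_config(class_fractions = bad), "sum to 1")
})

test_that("every gene belongs to exactly one operon and coordinates are valid", {
  cfg <- generator_config(n_genes = 20, seed = 1)
  sim <- generate_genome(cfg)
  ann <- sim$annotation
  expect_equal(nrow(ann), 20)
  expect_true(all(table(ann$gene_id) == 1))
  expect_true(all(ann$operon_id %in% sim$truth$operon_id))
  expect_true(all(ann$cds_start <= ann$cds_end))
  ## exactly one leading gene per operon
  lead_per_op <- tapply(ann$first_in_operon, ann$operon_id, sum)
  expect_true(all(lead_per_op == 1))
})

test_that("leaderless_fraction = 1 plants all operon leaders with UTR 0", {
  cfg <- generator_config(n_genes = 40, leaderless_fraction = 1, seed = 3)
  tr <- generate_genome(cfg)$truth
  expect_true(all(tr$utr_control[tr$first_in_operon] == 0))
})

test_that("a fixed seed reproduces FASTA and GFF3 byte-identically", {
  cfg <- generator_config(n_genes = 30, seed = 7)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    sim <- generate_genome(cfg)
    expr <- generate_expression(sim$truth, cfg)
    write_synthetic_dataset(sim, expr, tracks = NULL, dir = d)
  }
  for (f in c("genome.fasta", "annotation.gff3", "truth.tsv",
              "rnaseq_counts.tsv", "protein_ratio.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted TSS sits at the true UTR distance and SD motif at its spacer", {
  sim <- small_sim()$sim
  tr <- sim$truth
  lead <- tr[tr$first_in_operon, ]
  plus <- lead[lead$strand == "+", ]
  expect_true(all(plus$tss_control ==
                    sim$annotation$cds_start[match(plus$gene_id,
                                                   sim$annotation$gene_id)] -
                    plus$utr_control))
  minus <- lead[lead$strand == "-", ]
  expect_true(all(minus$tss_control ==
                    sim$annotation$cds_end[match(minus$gene_id,
                                                 sim$annotation$gene_id)] +
                    minus$utr_control))
  ## planted SD motifs really are in the sequence at the configured spacer
  seqchr <- as.character(sim$genome[[1]])
  with_sd <- sim$annotation[match(tr$gene_id[tr$sd_motif_planted != ""],
                                  sim$annotation$gene_id), ]
  for (i in seq_len(min(10, nrow(with_sd)))) {
    g <- with_sd[i, ]
    found <- if (g$strand == "+")
      substr(seqchr, g$cds_start - 7 - 6, g$cds_start - 7 - 1)
    else
      stressomics:::revcomp(substr(seqchr, g$cds_end + 7 + 1, g$cds_end + 7 + 6))
    expect_identical(found, "AGGAGG")
  }
})

test_that("counts are overdispersed relative to Poisson when dispersion > 0", {
  expr <- small_sim()$expr
  meta <- parse_sample_names(colnames(expr$rnaseq))
  ctl <- meta$sample[meta$stressor == "BuOH" & meta$level == "ctrl"]
  m <- expr$rnaseq[, ctl]
  mu <- rowMeans(m); v <- apply(m, 1, var)
  hi <- mu > 100
  expect_true(mean(v[hi] > mu[hi]) > 0.9)
})

test_that("protein fold equals mRNA fold in the noiseless, boost-free limit", {
  cfg <- generator_config(n_genes = 20, noise_sd_protein = 0,
                          noise_sd_mrna = 0, detection_limit = 0, seed = 5,
                          class_fractions = c(conc_up = 0.5, conc_down = 0.5,
                                              disc_protein_up = 0,
                                              disc_protein_down = 0,
                                              stress_only = 0,
                                              control_only = 0, nonsig = 0))
  sim <- generate_genome(cfg)
  expr <- generate_expression(sim$truth, cfg)
  expect_true(all(sim$truth$true_translation_boost == 1))
  meta <- parse_sample_names(colnames(expr$protein_ratio))
  hi <- meta$sample[meta$stressor == "BuOH" & meta$level == "high"]
  ctl <- meta$sample[meta$stressor == "BuOH" & meta$level == "ctrl"]
  fold <- rowMeans(expr$protein_ratio[, hi]) / rowMeans(expr$protein_ratio[, ctl])
  expect_equal(unname(log2(fold)), sim$truth$mrna_log2fc_high,
               tolerance = 1e-10)
  expect_false(anyNA(expr$protein_ratio))
})

test_that("translationally boosted genes show protein fold >= 2 with flat mRNA", {
  ## closed-form expectation: boost 8x on protein only, so the replicate-mean
  ## protein fold concentrates near 8 while mRNA log2FC stays near 0
  folds <- c(); mfc <- c()
  for (s in 1:25) {
    cfg <- generator_config(n_genes = 40, seed = s)
    sim <- generate_genome(cfg)
    disc <- sim$truth$gene_id[sim$truth$true_class == "disc_protein_up"]
    if (!length(disc)) next
    expr <- generate_expression(sim$truth, cfg)
    meta <- parse_sample_names(colnames(expr$protein_ratio))
    hi <- meta$sample[meta$stressor == "BA" & meta$level == "high"]
    ctl <- meta$sample[meta$stressor == "BA" & meta$level == "ctrl"]
    f <- rowMeans(expr$protein_ratio[disc, hi, drop = FALSE], na.rm = TRUE) /
      rowMeans(expr$protein_ratio[disc, ctl, drop = FALSE], na.rm = TRUE)
    folds <- c(folds, f)
    mr <- parse_sample_names(colnames(expr$microarray))
    hm <- mr$sample[mr$stressor == "BA" & mr$level == "high"]
    mfc <- c(mfc, rowMeans(expr$microarray[disc, hm, drop = FALSE]))
  }
  expect_true(mean(folds >= 2, na.rm = TRUE) > 0.95)
  expect_true(mean(abs(mfc) < 1) > 0.95)
})

test_that("detection_limit 0 censors nothing and censoring is monotone", {
  base <- function(dl) {
    cfg <- generator_config(n_genes = 60, seed = 9, detection_limit = dl)
    generate_expression(small_sim()$sim$truth[1:60, ], cfg)$protein_ratio
  }
  r0 <- base(0)
  expect_false(anyNA(r0))
  expect_equal(count_exclusive(r0), 0L)
  counts <- vapply(c(0, 0.1, 0.2, 0.3), function(dl) count_exclusive(base(dl)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("truth table round-trips through TSV losslessly", {
  tr <- small_sim()$sim$truth
  f <- tempfile(fileext = ".tsv")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_equal(back, tr, tolerance = 1e-12)
})

test_that("coverage steps sharply at planted TSSs and is strand-specific", {
  sm <- small_sim()
  tracks <- generate_coverage(sm$sim$annotation, sm$sim$truth, depth = 50,
                              tex_enrichment = 5, seed = 2)
  tr <- sm$sim$truth
  lead <- tr[tr$first_in_operon, ]
  step_at <- function(track, pos, strand) {
    v <- track$values
    up <- if (strand == "+") pos - 1L else pos + 1L
    (v[pos] + 1) / (v[up] + 1)
  }
  steps <- vapply(seq_len(nrow(lead)), function(i) {
    step_at(tracks$control[[lead$strand[i]]][["TEX+"]],
            lead$tss_control[i], lead$strand[i])
  }, 0)
  expect_gt(mean(steps >= 3), 0.95)
  ## antisense strand shows no systematic step at the same positions
  anti <- vapply(seq_len(nrow(lead)), function(i) {
    s <- if (lead$strand[i] == "+") "-" else "+"
    step_at(tracks$control[[s]][["TEX+"]], lead$tss_control[i], s)
  }, 0)
  expect_lt(mean(anti >= 3), 0.1)
  ## TEX+ amplifies the 5' end relative to TEX-
  i <- which(lead$strand == "+")[1]
  pos <- lead$tss_control[i]
  expect_gte(tracks$control$`+`$`TEX+`$values[pos],
             tracks$control$`+`$`TEX-`$values[pos])
  expect_error(generate_coverage(sm$sim$annotation, sm$sim$truth, depth = 0),
               "positive")
})
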