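test_that("joining layers keeps detection first-class and rejects duplicates", {
  pr <- data.frame(protein_id = c("g1", "g2"), level = "high",
                   category = c("up", "nonsig"), fold_change = c(3, 1.1),
                   display_value = c(3, 1.1), fdr_pass = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  ma <- data.frame(gene_id = "g1", level = "high", log2fc = -1.2,
                   category = "down", stringsAsFactors = FALSE)
  j <- suppressMessages(join_omics(pr, mrna_de = list(microarray = ma)))
  expect_equal(nrow(j), 2)
  expect_equal(j$ma_category[j$gene_id == "g1"], "down")
  expect_true(is.na(j$ma_category[j$gene_id == "g2"]))  # absent, not imputed
  expect_true(all(is.na(j$rs_category)))

  dup <- rbind(pr, pr[1, ])
  expect_error(join_omics(dup), "duplicate")
  empty <- join_omics(pr[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("a full toy join carries every layer's fields", {
  recs <- toy_integration()
  pr <- data.frame(protein_id = recs$gene_id, level = "high",
                   category = recs$protein_category,
                   fold_change = recs$fold_change,
                   display_value = recs$display_value,
                   fdr_pass = recs$fdr_pass, stringsAsFactors = FALSE)
  ma <- data.frame(gene_id = recs$gene_id, level = "high",
                   log2fc = recs$ma_log2fc, category = recs$ma_category,
                   stringsAsFactors = FALSE)
  rs <- data.frame(gene_id = recs$gene_id, level = "high",
                   log2fc = recs$rs_log2fc, category = recs$rs_category,
                   stringsAsFactors = FALSE)
  rk_p <- cbind(ctrl = recs$protein_rank_ctrl, high = recs$protein_rank)
  rk_m <- cbind(ctrl = recs$mrna_rank_ctrl, high = recs$mrna_rank)
  rownames(rk_p) <- rownames(rk_m) <- recs$gene_id
  tss <- data.frame(gene_id = recs$gene_id,
                    condition = "stress", tss_pos = 1,
                    utr_len = recs$utr_len, leaderless = recs$utr_len <= 5,
                    step_score = 5, tex_enrichment_obs = 5,
                    stringsAsFactors = FALSE)
  rbs <- data.frame(gene_id = recs$gene_id, motif = "AGGAGG", spacer = 7,
                    score = recs$rbs_score, stringsAsFactors = FALSE)
  j <- join_omics(pr, list(microarray = ma, rnaseq = rs),
                  ranks = list(protein = rk_p, mrna = rk_m),
                  tss = tss, rbs = rbs)
  expect_equal(nrow(j), 5)
  expect_equal(j$utr_len, recs$utr_len)
  expect_equal(j$rbs_score, recs$rbs_score)
  expect_equal(j$mrna_rank, recs$mrna_rank)
  expect_equal(j$protein_rank_ctrl, recs$protein_rank_ctrl)
})

test_that("discordance clauses fire on opposite patterns and good-mRNA exclusives", {
  recs <- toy_integration()
  d <- call_discordance(recs)
  ## protein up vs mRNA down -> opposite_de
  expect_true(d$discordant[d$gene_id == "gA"])
  expect_equal(d$discordance_subtype[d$gene_id == "gA"], "opposite_de")
  ## stress_only with nonsig, well-ranked mRNA -> exclusive clause
  expect_true(d$discordant[d$gene_id == "gB"])
  expect_equal(d$discordance_subtype[d$gene_id == "gB"], "exclusive_good_mrna")
  ## protein down vs mRNA up -> opposite_de
  expect_true(d$discordant[d$gene_id == "gC"])
  ## concordant nonsig not flagged
  expect_false(d$discordant[d$gene_id == "gD"])
  ## below good_mrna_rank the exclusive clause must not fire
  low <- recs; low$mrna_rank[low$gene_id == "gB"] <- 30
  low$ma_category[low$gene_id == "gB"] <- "nonsig"
  expect_false(call_discordance(low)$discordant[low$gene_id == "gB"])
  ## protein up with mRNA up is concordant
  conc <- recs[recs$gene_id == "gA", ]
  conc$ma_category <- "up"
  expect_false(call_discordance(conc)$discordant)
})

test_that("hypothesis screens follow their clause definitions", {
  recs <- toy_integration()
  ## make gA a rubrerythrin-like H3 case: protein up, both mRNA nonsig,
  ## long 5'UTR (96 > median) and ceiling RBS score
  recs$ma_category[1] <- "nonsig"; recs$rs_category[1] <- "nonsig"
  h <- screen_hypotheses(recs)
  a <- h[h$gene_id == "gA", ]
  expect_true(a$H3); expect_true(a$long_utr); expect_true(a$strong_rbs)
  ## a record failing every clause gets no flags
  dflags <- h[h$gene_id == "gD", ]
  expect_false(any(unlist(dflags[, c("H1", "H2", "H3")])))
  ## H2 requires mRNA up with protein down/undetected at med AND high
  h2rec <- rbind(
    within(recs[recs$gene_id == "gC", ], level <- "med"),
    recs[recs$gene_id == "gC", ])
  h2 <- screen_hypotheses(h2rec)
  expect_true(h2$H2[h2$gene_id == "gC"])
  ## H1 needs extreme ranks in every condition including control
  h1rec <- recs[recs$gene_id == "gE", ]
  h1rec$mrna_rank <- 92; h1rec$mrna_rank_ctrl <- 95
  h1rec$protein_rank <- 5; h1rec$protein_rank_ctrl <- 10
  expect_true(screen_hypotheses(h1rec)$H1)
  h1rec$protein_rank_ctrl <- 50
  expect_false(screen_hypotheses(h1rec)$H1)
})

test_that("revised percentile screens use strict thresholds", {
  recs <- toy_integration()
  r <- screen_revised(recs)
  expect_true(r$rev_lowM_highP[r$gene_id == "gA"])   # mRNA 55 < 60, prot 85 > 80
  expect_true(r$rev_highM_lowP[r$gene_id == "gE"])   # mRNA 85 > 80, prot 15 < 60
  ## boundary: rank exactly 60 is not "< 60"
  b <- recs[recs$gene_id == "gA", ]
  b$mrna_rank <- 60
  expect_false(screen_revised(b)$rev_lowM_highP)
  ## undetected-under-stress protein with abundant mRNA
  e <- recs[recs$gene_id == "gE", ]
  e$protein_category <- "control_only"; e$mrna_rank <- 90; e$protein_rank <- 3
  expect_true(screen_revised(e)$rev_highM_lowP)
})

test_that("category correlations match a hand oracle and its invariances", {
  recs <- data.frame(
    gene_id = paste0("g", 1:5), level = "high",
    protein_category = "up",
    fold_change = c(2, 4, 8, 16, 32),
    ma_log2fc = c(1.2, 1.9, 3.2, 3.9, 5.1),
    rs_log2fc = c(1, 2, 3, 4, 5),
    stringsAsFactors = FALSE)
  pc <- pearson_by_category(recs, pairs = list(c("protein", "microarray")))
  hand <- cor(log2(recs$fold_change), recs$ma_log2fc)
  expect_equal(pc$r[pc$category == "up"], hand)
  expect_true(is.na(pc$r[pc$category == "down"]))     # < 3 pairs -> absent

  ident <- recs; ident$ma_log2fc <- log2(ident$fold_change)
  expect_equal(pearson_by_category(ident,
               pairs = list(c("protein", "microarray")))$r[1], 1)
  neg <- recs; neg$ma_log2fc <- -log2(neg$fold_change)
  expect_equal(pearson_by_category(neg,
               pairs = list(c("protein", "microarray")))$r[1], -1)
  ## invariant to gene order and affine rescaling of either axis
  sh <- recs[sample(5), ]
  expect_equal(pearson_by_category(sh,
               pairs = list(c("protein", "microarray")))$r[1], hand)
  aff <- recs; aff$ma_log2fc <- 3 * aff$ma_log2fc + 7
  expect_equal(pearson_by_category(aff,
               pairs = list(c("protein", "microarray")))$r[1], hand)
})

test_that("COG enrichment flags skewed categories only", {
  recs <- data.frame(
    gene_id = paste0("g", 1:108), level = "high",
    protein_category = c(rep("up", 8), rep(c("nonsig", "up"), c(90, 10))),
    stringsAsFactors = FALSE)
  cog <- setNames(c(rep("J", 8), rep("R", 100)), recs$gene_id)
  ce <- cog_enrichment(recs, cog)
  expect_equal(ce$label[ce$cog_letter == "J"], "up-enriched")
  ## oracle: one-sided Fisher on the 2x2 table
  ft <- fisher.test(matrix(c(8, 0, 10, 90), 2), alternative = "greater")
  expect_equal(ce$p_up[ce$cog_letter == "J"], ft$p.value)
  expect_equal(ce$label[ce$cog_letter == "R"], "none")

  ## uniform proportions: nothing enriched
  recs2 <- data.frame(gene_id = paste0("g", 1:100), level = "high",
                      protein_category = rep(c("up", "nonsig"), 50),
                      stringsAsFactors = FALSE)
  cog2 <- setNames(rep(c("C", "E"), each = 50), recs2$gene_id)
  expect_true(all(cog_enrichment(recs2, cog2)$label == "none"))

  ## both directions skewed in one letter
  recs3 <- data.frame(
    gene_id = paste0("g", 1:120), level = "high",
    protein_category = c(rep(c("up", "down"), 10), rep("nonsig", 100)),
    stringsAsFactors = FALSE)
  cog3 <- setNames(c(rep("O", 20), rep("S", 100)), recs3$gene_id)
  expect_equal(cog_enrichment(recs3, cog3)$label[1], "both")
})

test_that("screen relationships hold on synthetic data", {
  v <- cached_validation()
  for (st in names(v$run$stressors)) {
    ps <- v$run$stressors[[st]]
    jn <- ps$integration
    hyp <- ps$hypotheses
    ## H3 and rev_highM_lowP are mutually exclusive
    h3 <- hyp$gene_id[hyp$H3]
    rhml <- unique(jn$gene_id[jn$rev_highM_lowP])
    expect_length(intersect(h3, rhml), 0)
    ## H1 genes satisfy the relaxed revised-screen rank geometry
    h1 <- hyp$gene_id[hyp$H1]
    if (length(h1)) {
      rows <- jn[jn$gene_id %in% h1, ]
      expect_true(all(rows$mrna_rank > 80 & rows$protein_rank < 60))
    }
  }
})

test_that("planted discordance fraction is recovered within 0.05", {
  v <- cached_validation()
  expect_lt(abs(v$discordant_called - v$discordant_planted), 0.05)
})
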