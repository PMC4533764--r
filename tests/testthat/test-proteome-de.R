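test_that("ratio normalisation is log2 + per-sample median centring", {
  m <- cbind(s1 = c(1, 1, 1), s2 = c(2, 4, 8))
  out <- normalize_ratios(m)
  expect_equal(out[, "s1"], c(0, 0, 0))
  expect_equal(out[, "s2"], c(-1, 0, 1))

  m2 <- cbind(s1 = c(2, NA, 8), s2 = c(1, 1, 1))
  out2 <- normalize_ratios(m2)
  expect_true(is.na(out2[2, "s1"]))          # absent stays absent
  expect_error(normalize_ratios(cbind(s1 = c(NA_real_, NA_real_))),
               "no detected proteins")
  expect_error(normalize_ratios(cbind(s1 = c(1, -2))), "> 0")
})

test_that("SAM d matches a brute-force oracle on 3v3 toy vectors", {
  ## independent oracle: direct evaluation of the pooled-SE t-like formula
  a <- c(2.1, 1.7, 2.4); b <- c(0.3, -0.1, 0.5)
  x <- rbind(p1 = c(a, b),
             p2 = c(0.2, -0.3, 0.1, 0.25, -0.15, 0.05))
  res <- sam_test(x, 1:3, 4:6, s0_mode = "median", seed = 1)
  s0 <- attr(res, "s0")
  oracle_d <- function(v1, v2, s0) {
    ss <- sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)
    s <- sqrt((1 / 3 + 1 / 3) / 4 * ss)
    (mean(v1) - mean(v2)) / (s + s0)
  }
  expect_equal(res$d_i[res$protein_id == "p1"], oracle_d(a, b, s0),
               tolerance = 1e-12)
  expect_equal(res$d_i[res$protein_id == "p2"],
               oracle_d(x["p2", 1:3], x["p2", 4:6], s0), tolerance = 1e-12)
  ## antisymmetry under group swap
  swap <- sam_test(x, 4:6, 1:3, s0_mode = "median", seed = 1)
  expect_equal(swap$d_i, -res$d_i, tolerance = 1e-12)
})

test_that("identical group means give d = 0 and no calls", {
  x <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 4), nrow = 4,
              dimnames = list(paste0("p", 1:4), NULL))
  x <- x + matrix(rnorm(24, sd = 1e-3), 4)  # tiny jitter keeps s > 0
  x[, 4:6] <- x[, 1:3]                       # exactly equal groups
  res <- sam_test(x, 1:3, 4:6, seed = 2)
  expect_true(all(abs(res$d_i) < 1e-8))
  expect_equal(sum(res$called), 0L)
})

test_that("raising delta never adds calls (monotone calling)", {
  set.seed(42)
  x <- matrix(rnorm(200 * 6, sd = 0.3), 200,
              dimnames = list(paste0("p", 1:200), NULL))
  x[1:40, 1:3] <- x[1:40, 1:3] + 2
  res <- sam_test(x, 1:3, 4:6, seed = 3)
  ## recompute the called set over a grid of deltas from the attributes
  d <- res$d_i
  ds <- sort(d)
  ## use q as a proxy: proteins called at the chosen delta must be a superset
  ## of those called at any larger delta, i.e. q is monotone in |d - dbar|
  called <- res$called
  expect_gt(sum(called), 10)
  expect_true(all(res$q[called] <= 0.05 + 1e-12))
  ## every called protein has |d| >= the largest uncalled |d| on its side
  if (any(called & d > 0) && any(!called & d > 0))
    expect_gte(min(d[called & d > 0]), max(d[!called & d > 0]))
  if (any(called & d < 0) && any(!called & d < 0))
    expect_lte(max(d[called & d < 0]), min(d[!called & d < 0]))
})

test_that("SAM errors on degenerate all-zero variance with s0 = 0", {
  x <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = 3), nrow = 3,
              dimnames = list(paste0("p", 1:3), NULL))
  expect_error(sam_test(x, 1:3, 4:6, s0_mode = "median"), "s0")
})

test_that("null simulations stay uncalled at the 5% FDR target", {
  calls <- vapply(1:8, function(s) {
    set.seed(s)
    x <- matrix(rnorm(300 * 6, sd = 0.3), 300,
                dimnames = list(paste0("p", 1:300), NULL))
    sum(sam_test(x, 1:3, 4:6, seed = s)$called)
  }, 0)
  expect_lte(mean(calls > 0), 0.1)
})

test_that("five-category classification honours detection and sentinels", {
  up <- classify_protein(TRUE, TRUE, fold_change = 2.5, fdr_pass = TRUE)
  expect_equal(up$category, "up")
  so <- classify_protein(TRUE, FALSE)
  expect_equal(so$category, "stress_only")
  expect_identical(so$display_value, 6)
  co <- classify_protein(FALSE, TRUE)
  expect_equal(co$category, "control_only")
  expect_identical(co$display_value, -5)
  ns <- classify_protein(TRUE, TRUE, fold_change = 1.5, fdr_pass = TRUE)
  expect_equal(ns$category, "nonsig")
  dn <- classify_protein(TRUE, TRUE, fold_change = 0.4, fdr_pass = TRUE)
  expect_equal(dn$category, "down")
  expect_equal(dn$display_value, -2.5)
  expect_error(classify_protein(FALSE, FALSE), "excluded")
})

test_that("sentinel convention holds for every exclusive record in a run", {
  v <- cached_validation()
  for (st in names(v$run$stressors)) {
    pr <- v$run$stressors[[st]]$proteome
    expect_true(all(pr$display_value[pr$category == "stress_only"] == 6))
    expect_true(all(pr$display_value[pr$category == "control_only"] == -5))
  }
})

test_that("DE summary reproduces bookkeeping identities", {
  recs <- data.frame(
    protein_id = c(sprintf("u%02d", 1:15), sprintf("d%02d", 1:33),
                   sprintf("n%02d", 1:10), sprintf("s%02d", 1:5), "c01"),
    level = "low",
    category = c(rep("up", 15), rep("down", 33), rep("nonsig", 10),
                 rep("stress_only", 5), "control_only"),
    fold_change = c(runif(15, 2, 6), runif(33, 0.1, 0.5),
                    runif(10, 0.8, 1.2), rep(NA, 6)),
    fdr_pass = c(rep(TRUE, 48), rep(FALSE, 10), rep(NA, 6)),
    stringsAsFactors = FALSE)
  s <- summarize_de(recs)
  expect_equal(s$per_level$de_fold_total, 48)
  expect_equal(s$per_level$de_fold_up, 15)
  expect_equal(s$per_level$de_fold_down, 33)
  expect_equal(s$per_level$n_used, 58)
  expect_equal(s$aggregate$stress_only_any, 5)

  empty <- summarize_de(recs[0, ])
  expect_equal(nrow(empty$per_level), 0)
  expect_equal(empty$aggregate$detected_any, 0)
})

test_that("inclusion-exclusion helpers compute unions and differences", {
  expect_equal(venn_union(440, 589, 413), 616)
  expect_equal(both_condition_count(440, 90, 44), 306)
  expect_equal(both_condition_count(589, 120, 67), 402)
  expect_equal(de_total(15, 33), 48)
  expect_error(venn_union(5, 5, 9), "larger")
  expect_error(both_condition_count(10, 8, 5), "exceed")
})

test_that("planted effects are recovered and planted nulls stay quiet", {
  v <- cached_validation()
  truth <- read_truth(file.path(v$run$outdir, "..", "data", "truth.tsv"))
  sens <- c(); fcr <- c()
  for (st in names(v$run$stressors)) {
    hi <- v$run$stressors[[st]]$proteome
    hi <- hi[hi$level == "high", ]
    cls <- truth$true_class[match(hi$protein_id, truth$gene_id)]
    conc <- cls %in% c("conc_up", "conc_down")
    sens <- c(sens, mean(hi$category[conc] == expected_category(cls[conc])))
    nul <- cls == "nonsig" & hi$category %in% c("up", "down", "nonsig")
    fcr <- c(fcr, mean(hi$category[nul] %in% c("up", "down")))
  }
  expect_gte(mean(sens), 0.85)
  expect_lte(mean(fcr), 0.10)
})
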