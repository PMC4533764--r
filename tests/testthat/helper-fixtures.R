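## Shared fixtures, memoised so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

## small genome + expression draw used by many unit tests
small_sim <- function() memo("small_sim", {
  cfg <- generator_config(n_genes = 80, seed = 11)
  sim <- generate_genome(cfg)
  expr <- generate_expression(sim$truth, cfg)
  list(cfg = cfg, sim = sim, expr = expr)
})

## one full synthetic run scored against truth (shared by the recovery and
## integration-invariant tests)
cached_validation <- function() memo("cached_validation", {
  suppressWarnings(suppressMessages(
    simulate_and_validate(generator_config(n_genes = 300, seed = 101),
                          outdir = file.path(tempdir(), "sv_cache"))))
})

## minimal hand-built integration records for screen unit tests
toy_integration <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    level = "high",
    protein_category = c("up", "stress_only", "down", "nonsig", "control_only"),
    fold_change = c(3, NA, 0.3, 1.2, NA),
    display_value = c(3, 6, -3.33, 1.2, -5),
    fdr_pass = c(TRUE, NA, TRUE, FALSE, NA),
    ma_category = c("down", "nonsig", "up", "nonsig", "nonsig"),
    ma_log2fc = c(-1.3, 0.1, 1.5, 0, -0.2),
    rs_category = c("down", "nonsig", "up", "nonsig", "nonsig"),
    rs_log2fc = c(-1.1, 0.2, 1.4, 0.1, -0.1),
    protein_rank = c(85, 90, 10, 50, 15),
    protein_rank_ctrl = c(80, 15, 30, 50, 70),
    mrna_rank = c(55, 80, 90, 50, 85),
    mrna_rank_ctrl = c(60, 75, 88, 50, 84),
    utr_len = c(96, 20, 40, 42, 30),
    utr_len_ctrl = c(96, 20, 40, 42, 30),
    rbs_score = c(12.87, 7.68, 2.21, 9.25, 4.45),
    stringsAsFactors = FALSE)
}

expected_category <- function(true_class) {
  unname(c(conc_up = "up", conc_down = "down", disc_protein_up = "up",
           disc_protein_down = "down", stress_only = "stress_only",
           control_only = "control_only", nonsig = "nonsig")[true_class])
}

## count exclusive-detection (gene, stressor, level) patterns in a ratio table
count_exclusive <- function(ratio) {
  meta <- parse_sample_names(colnames(ratio))
  n <- 0L
  for (st in unique(meta$stressor)) {
    ctl <- meta$sample[meta$stressor == st & meta$level == "ctrl"]
    for (lv in setdiff(unique(meta$level), "ctrl")) {
      sc <- meta$sample[meta$stressor == st & meta$level == lv]
      ds <- rowSums(!is.na(ratio[, sc, drop = FALSE])) > 0
      dc <- rowSums(!is.na(ratio[, ctl, drop = FALSE])) > 0
      n <- n + sum(xor(ds, dc))
    }
  }
  n
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
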