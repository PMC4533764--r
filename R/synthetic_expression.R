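#' Generate multi-omic expression tables with planted truth
#'
#' Draws, for each stressor, (i) an RNAseq count matrix (negative binomial
#' around baseline x condition effect, with lognormal library size factors),
#' (ii) a microarray log2-ratio matrix (true mRNA log2 fold change plus
#' Gaussian noise), and (iii) an iTRAQ-style protein table: per-sample
#' reporter abundances (mRNA baseline x translation efficiency x condition
#' effect x lognormal noise) censored below the per-sample
#' \code{detection_limit} abundance quantile, and ratios of each sample to a
#' pooled reference formed as the mean over all of that stressor's samples.
#' Censoring is what produces the stress-only / control-only exclusive
#' detection patterns.
#'
#' Sample names follow \code{<stressor>_<level>_<time>_<rep>} with level
#' \code{ctrl} for the unstressed control.
#'
#' @param truth planted-truth table from [generate_genome()].
#' @param config the [generator_config()] used to generate it.
#' @return list with matrices \code{rnaseq} (integer counts),
#'   \code{microarray} (log2 ratios, stress samples only),
#'   \code{protein_ratio} (ratio to pool, NA = not detected),
#'   \code{protein_abundance} (censored reporter abundances), and
#'   \code{size_factors_true} (the planted library size factors).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(child_seed(config$seed, "expression"))
  n <- nrow(truth)
  reps <- seq_len(config$replicates)
  scale_of <- function(level) {
    if (level == "ctrl") 0 else unname(config$level_scaling[[level]])
  }

  rnaseq <- list(); marray <- list(); pratio <- list(); pabund <- list()
  sf_all <- numeric(0)

  for (st in config$stressors) {
    ## --- RNAseq counts -------------------------------------------------
    for (level in c("ctrl", config$stress_levels)) {
      mu_gene <- truth$baseline_mrna * 2^(truth$mrna_log2fc_high * scale_of(level))
      for (tp in config$time_points_mrna) {
        for (r in reps) {
          sf <- rlnorm(1, 0, 0.15)
          nm <- sprintf("%s_%s_%d_%d", st, level, tp, r)
          sf_all[nm] <- sf
          mu <- mu_gene * sf
          rnaseq[[nm]] <- if (config$dispersion > 0) {
            rnbinom(n, size = 1 / config$dispersion, mu = mu)
          } else {
            rpois(n, mu)
          }
        }
      }
    }
    ## --- microarray log2 ratios (stress vs control built in) -----------
    for (level in config$stress_levels) {
      lfc <- truth$mrna_log2fc_high * scale_of(level)
      for (tp in config$time_points_mrna) {
        for (r in reps) {
          nm <- sprintf("%s_%s_%d_%d", st, level, tp, r)
          marray[[nm]] <- lfc + rnorm(n, 0, config$noise_sd_mrna)
        }
      }
    }
    ## --- protein reporter abundances, censoring, ratios to pool --------
    ab_cols <- list()
    for (level in c("ctrl", config$stress_levels)) {
      p_eff <- truth$protein_log2fc_high * scale_of(level)
      for (tp in config$time_points_protein) {
        for (r in reps) {
          nm <- sprintf("%s_%s_%d_%d", st, level, tp, r)
          ab_cols[[nm]] <- truth$baseline_protein * 2^p_eff *
            2^rnorm(n, 0, config$noise_sd_protein)
        }
      }
    }
    ab <- do.call(cbind, ab_cols)
    pool <- rowMeans(ab)                      # pooled reference, this stressor
    ratio <- ab / pool
    if (config$detection_limit > 0) {
      for (j in seq_len(ncol(ab))) {
        cut <- quantile(ab[, j], config$detection_limit, names = FALSE)
        censored <- ab[, j] < cut
        ab[censored, j] <- NA_real_
        ratio[censored, j] <- NA_real_
      }
    }
    for (j in seq_len(ncol(ab))) {
      pabund[[colnames(ab)[j]]] <- ab[, j]
      pratio[[colnames(ab)[j]]] <- ratio[, j]
    }
  }

  mk <- function(cols, integer = FALSE) {
    m <- do.call(cbind, cols)
    rownames(m) <- truth$gene_id
    if (integer) storage.mode(m) <- "integer"
    m
  }
  list(rnaseq = mk(rnaseq, integer = TRUE),
       microarray = mk(marray),
       protein_ratio = mk(pratio),
       protein_abundance = mk(pabund),
       size_factors_true = sf_all)
}
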