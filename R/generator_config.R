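#' Configuration for the synthetic multi-omic data generator
#'
#' Bundles every tunable of the simulator that emulates the metabolite-stress
#' study design: a miniature genome organised in operons, strand-specific
#' TEX+/TEX- coverage with planted transcription start sites, negative-binomial
#' RNAseq counts, microarray log-ratios, and a censored iTRAQ-style protein
#' ratio table quantified against a pooled reference. Ground-truth gene classes
#' (concordant, discordant, exclusive-detection, null) are planted so that
#' recovery by the analysis modules can be scored.
#'
#' @param n_genes number of genes to simulate (>= 20).
#' @param leaderless_fraction proportion of operon-leading genes planted
#'   leaderless (5'UTR length 0).
#' @param utr_median median planted 5'UTR length in nt (lognormal model).
#' @param utr_sigma sdlog of the lognormal 5'UTR length distribution.
#' @param class_fractions named proportions over the planted gene classes
#'   \code{conc_up, conc_down, disc_protein_up, disc_protein_down,
#'   stress_only, control_only, nonsig}; must sum to 1.
#' @param detection_limit per-sample abundance quantile below which a protein
#'   is censored (not detected) in that sample.
#' @param noise_sd_protein,noise_sd_mrna replicate noise, sd in log2 units.
#' @param replicates biological replicates per condition.
#' @param dispersion shared negative-binomial dispersion for RNAseq counts.
#' @param operon_mean_size mean operon size (geometric model).
#' @param tss_shift_fraction fraction of operon-leading genes whose leaderless
#'   status switches between control and stress.
#' @param sd_spacer spacer (nt) between the planted Shine-Dalgarno motif and
#'   the start codon.
#' @param stressors,stress_levels labels used in sample names.
#' @param level_scaling multiplier applied to the high-stress log2 effect at
#'   each stress level.
#' @param time_points_protein,time_points_mrna sampling times (minutes).
#' @param baseline_meanlog,baseline_sdlog lognormal model of baseline mRNA
#'   abundance across genes (natural-log scale).
#' @param seed master seed; a fixed seed yields byte-identical outputs.
#' @return an object of class \code{generator_config} (a validated list).
#' @export
generator_config <- function(n_genes = 300,
                             leaderless_fraction = 0.2,
                             utr_median = 42,
                             utr_sigma = 0.8,
                             class_fractions = c(conc_up = 0.10,
                                                 conc_down = 0.10,
                                                 disc_protein_up = 0.07,
                                                 disc_protein_down = 0.07,
                                                 stress_only = 0.07,
                                                 control_only = 0.05,
                                                 nonsig = 0.54),
                             detection_limit = 0.15,
                             noise_sd_protein = 0.25,
                             noise_sd_mrna = 0.2,
                             replicates = 3,
                             dispersion = 0.05,
                             operon_mean_size = 2.5,
                             tss_shift_fraction = 0.06,
                             sd_spacer = 7,
                             stressors = c("BuOH", "BA"),
                             stress_levels = c("low", "med", "high"),
                             level_scaling = c(low = 0.7, med = 0.85, high = 1),
                             time_points_protein = c(15, 45, 75),
                             time_points_mrna = c(15, 30, 60, 75),
                             baseline_meanlog = log(200),
                             baseline_sdlog = 1.5,
                             seed = 1) {
  if (!is_count(n_genes, min = 20))
    abort("n_genes must be an integer >= 20 (got %s): too small to place operons",
          format(n_genes))
  for (p in c(leaderless_fraction = leaderless_fraction,
              detection_limit = detection_limit,
              tss_shift_fraction = tss_shift_fraction)) {
    if (!is_prob(p)) abort("proportions must lie in [0, 1]")
  }
  wanted <- c("conc_up", "conc_down", "disc_protein_up", "disc_protein_down",
              "stress_only", "control_only", "nonsig")
  if (!setequal(names(class_fractions), wanted))
    abort("class_fractions must be named exactly: %s",
          paste(wanted, collapse = ", "))
  class_fractions <- class_fractions[wanted]
  if (any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8)
    abort("class_fractions must be non-negative and sum to 1")
  if (utr_median <= 0 || utr_sigma <= 0) abort("utr distribution must be positive")
  if (!is_count(replicates, min = 2)) abort("replicates must be >= 2")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (operon_mean_size < 1) abort("operon_mean_size must be >= 1")
  if (!is_count(sd_spacer, min = 3) || sd_spacer > 15)
    abort("sd_spacer must be in [3, 15]")
  if (!setequal(names(level_scaling), stress_levels))
    abort("level_scaling must be named by stress_levels")
  if (noise_sd_protein < 0 || noise_sd_mrna < 0) abort("noise sds must be >= 0")
  if (!is_count(abs(seed), min = 0)) abort("seed must be an integer")

  cfg <- list(n_genes = as.integer(n_genes),
              leaderless_fraction = leaderless_fraction,
              utr_median = utr_median, utr_sigma = utr_sigma,
              class_fractions = class_fractions,
              detection_limit = detection_limit,
              noise_sd_protein = noise_sd_protein,
              noise_sd_mrna = noise_sd_mrna,
              replicates = as.integer(replicates),
              dispersion = dispersion,
              operon_mean_size = operon_mean_size,
              tss_shift_fraction = tss_shift_fraction,
              sd_spacer = as.integer(sd_spacer),
              stressors = stressors, stress_levels = stress_levels,
              level_scaling = level_scaling,
              time_points_protein = time_points_protein,
              time_points_mrna = time_points_mrna,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic multi-omic generator configuration\n")
  cat(sprintf("  genes: %d  replicates: %d  seed: %d\n",
              x$n_genes, x$replicates, x$seed))
  cat(sprintf("  leaderless fraction: %.2f  UTR lognormal(median %g, sdlog %g)\n",
              x$leaderless_fraction, x$utr_median, x$utr_sigma))
  cat("  class fractions:\n")
  print(round(x$class_fractions, 3))
  invisible(x)
}

## Per-class planted effect sizes (log2, at high stress) and the baseline
## abundance percentile windows that make each detection pattern attainable:
## exclusive-under-stress genes must sit below the detection-limit quantile in
## every control sample, concordant-down genes must stay above it under stress.
class_param_table <- function() {
  data.frame(
    class   = c("conc_up", "conc_down", "disc_protein_up", "disc_protein_down",
                "stress_only", "control_only", "nonsig"),
    m_high  = c( 2.5, -2.5, 0.0,  2.0,  0.0,  0.0, 0),
    p_high  = c( 2.5, -2.5, 3.0, -2.0,  6.0, -6.0, 0),
    u_m_lo  = c(0.50, 0.70, 0.30, 0.60, 0.65, 0.65, 0.02),
    u_m_hi  = c(0.95, 0.98, 0.90, 0.98, 0.95, 0.95, 0.98),
    u_p_lo  = c(  NA,   NA,   NA,   NA, 0.01, 0.40,   NA),
    u_p_hi  = c(  NA,   NA,   NA,   NA, 0.05, 0.90,   NA),
    stringsAsFactors = FALSE)
}
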