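#' Normalize iTRAQ ratio-to-pool values
#'
#' log2-transforms positive ratios and median-centres each sample column, a
#' stand-in for upstream bias correction. Missing cells (not detected) stay
#' missing; detection is first-class and never imputed.
#'
#' @param ratios numeric matrix of ratios to the pooled reference (proteins x
#'   samples); NA = not detected.
#' @return matrix of centred log2 ratios, same dimensions and NA pattern.
#' @export
normalize_ratios <- function(ratios) {
  if (any(ratios[!is.na(ratios)] <= 0)) abort("ratios must be > 0")
  all_absent <- colSums(!is.na(ratios)) == 0
  if (any(all_absent))
    abort("sample '%s' has no detected proteins", colnames(ratios)[all_absent][1])
  lg <- log2(ratios)
  med <- apply(lg, 2, median, na.rm = TRUE)
  sweep(lg, 2, med, "-")
}

#' SAM-style moderated permutation test
#'
#' Computes the SAM statistic d_i = (xbar_stress - xbar_control)/(s_i + s0)
#' per protein, with s_i the pooled standard error and s0 a small exchange
#' factor that stabilises low-variance proteins. Null order statistics are
#' taken from group-label permutations (all of them when their number is at
#' most \code{n_perm}, otherwise \code{n_perm} sampled with \code{seed}), and
#' the calling threshold delta is the smallest value whose estimated FDR is
#' at or below \code{fdr_target}.
#'
#' The default FDR estimate is an add-one-smoothed mean false-call count over
#' the non-identity permutations, \eqn{(1 + \sum_b F_b) / (B - 1) / m}, which
#' stays calibrated at small replicate numbers where a median-based estimate
#' collapses to zero; \code{fdr_method = "median"} gives the classical
#' median-false variant.
#'
#' @param x matrix of (centred) log2 ratios, proteins x samples; NA allowed
#'   where a protein was not quantified in a sample.
#' @param group_stress,group_control column names or indices of the two groups.
#' @param s0_mode \code{"tusher"} (minimise the coefficient of variation of d
#'   across s-percentile windows) or \code{"median"} (s0 = median s_i).
#' @param n_perm maximum number of permutations.
#' @param fdr_target target FDR for the delta cutoff.
#' @param seed seed for permutation sampling.
#' @param fdr_method \code{"smoothed"} (default) or \code{"median"}.
#' @param min_obs minimum quantified samples per group; rows below are
#'   dropped with a message.
#' @return object of class \code{sam_result}: a data.frame with columns
#'   \code{protein_id, xbar_stress, xbar_control, s_i, d_i, q, called},
#'   with attributes \code{s0}, \code{delta}, \code{fdr_at_delta},
#'   \code{n_perm_used}.
#' @export
sam_test <- function(x, group_stress, group_control,
                     s0_mode = c("tusher", "median"),
                     n_perm = 1000, fdr_target = 0.05, seed = 1,
                     fdr_method = c("smoothed", "median"),
                     min_obs = 2) {
  s0_mode <- match.arg(s0_mode)
  fdr_method <- match.arg(fdr_method)
  xs <- x[, group_stress, drop = FALSE]
  xc <- x[, group_control, drop = FALSE]
  if (ncol(xs) < 2 || ncol(xc) < 2) abort("need >= 2 replicates per group")

  n1 <- rowSums(!is.na(xs)); n2 <- rowSums(!is.na(xc))
  keep <- n1 >= min_obs & n2 >= min_obs
  if (!all(keep))
    message(sum(!keep), " proteins dropped (quantified in < ", min_obs,
            " samples of a group)")
  xs <- xs[keep, , drop = FALSE]; xc <- xc[keep, , drop = FALSE]
  if (nrow(xs) == 0) abort("no proteins quantified in both groups")
  xall <- cbind(xs, xc)
  g1 <- ncol(xs); g2 <- ncol(xc); nc <- g1 + g2

  sam_stat <- function(m, idx1) {
    a <- m[, idx1, drop = FALSE]
    b <- m[, -idx1, drop = FALSE]
    m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
    k1 <- rowSums(!is.na(a)); k2 <- rowSums(!is.na(b))
    ss <- rowSums((a - m1)^2, na.rm = TRUE) + rowSums((b - m2)^2, na.rm = TRUE)
    s <- sqrt((1 / k1 + 1 / k2) / (k1 + k2 - 2) * ss)
    list(r = m1 - m2, s = s, m1 = m1, m2 = m2)
  }
  obs <- sam_stat(xall, seq_len(g1))
  if (all(obs$s == 0) && s0_mode == "median")
    abort(paste("all pooled standard errors are zero and s0 = 0;",
                "use s0_mode = 'tusher' or add replicate noise"))
  s0 <- select_s0(obs$r, obs$s, s0_mode)
  if (all(obs$s + s0 == 0))
    abort("zero variance in both groups and s0 = 0; change s0_mode")
  d <- obs$r / (obs$s + s0)

  ## label permutations (balanced reassignments of the stress label)
  combos <- if (choose(nc, g1) <= n_perm) {
    utils::combn(nc, g1, simplify = FALSE)
  } else {
    local_seed(seed)
    c(list(seq_len(g1)),
      replicate(n_perm - 1, sort(sample.int(nc, g1)), simplify = FALSE))
  }
  identity_idx <- vapply(combos, function(ix) identical(ix, seq_len(g1)) ||
                           identical(as.integer(ix), seq_len(g1)), TRUE)
  D <- vapply(combos, function(ix) {
    st <- sam_stat(xall, ix)
    st$r / (st$s + s0)
  }, numeric(nrow(xall)))
  if (nrow(xall) == 1) D <- matrix(D, nrow = 1)
  ## a relabeling can isolate a protein's missing cells in one group; such a
  ## permutation carries no information for that protein
  D[!is.finite(D)] <- 0

  n <- nrow(xall)
  ord <- order(d)
  ds <- d[ord]
  dbar <- rowMeans(apply(D, 2, sort))
  if (n == 1) dbar <- mean(D)

  ## delta scan
  grid <- sort(unique(c(0, abs(ds - dbar))))
  perm_sorted <- lapply(which(!identity_idx), function(b) sort(D[, b]))
  B_non <- length(perm_sorted)
  B_all <- ncol(D)
  up_ok <- dbar >= 0
  lo_ok <- dbar <= 0

  cutup <- vapply(grid, function(del) {
    cand <- ds[up_ok & (ds - dbar) >= del]
    if (length(cand)) min(cand) else Inf
  }, 0)
  cutlow <- vapply(grid, function(del) {
    cand <- ds[lo_ok & (dbar - ds) >= del]
    if (length(cand)) max(cand) else -Inf
  }, 0)

  n_called <- vapply(seq_along(grid), function(k)
    sum(d >= cutup[k] | d <= cutlow[k]), 0L)

  false_tot <- numeric(length(grid))       # sum over non-identity perms
  false_med_mat <- matrix(0, nrow = B_all, ncol = length(grid))
  all_sorted <- lapply(seq_len(B_all), function(b) sort(D[, b]))
  for (b in seq_len(B_all)) {
    v <- all_sorted[[b]]
    f_up <- length(v) - findInterval(cutup, v, left.open = TRUE)
    f_up[is.infinite(cutup)] <- 0
    f_lo <- findInterval(cutlow, v)
    f_lo[is.infinite(cutlow)] <- 0
    false_med_mat[b, ] <- f_up + f_lo
  }
  if (B_non > 0)
    false_tot <- colSums(false_med_mat[!identity_idx, , drop = FALSE])

  fdr_grid <- if (fdr_method == "smoothed") {
    ifelse(n_called == 0, 0,
           (1 + false_tot) / max(1, B_non) / pmax(1, n_called))
  } else {
    ifelse(n_called == 0, 0,
           apply(false_med_mat, 2, median) / pmax(1, n_called))
  }

  ok <- which(fdr_grid <= fdr_target & n_called > 0)
  if (length(ok)) {
    k_star <- ok[1]                        # smallest delta meeting the target
    delta <- grid[k_star]
    called <- d >= cutup[k_star] | d <= cutlow[k_star]
    fdr_at <- fdr_grid[k_star]
  } else {
    delta <- Inf; called <- rep(FALSE, n); fdr_at <- NA_real_
  }

  ## per-protein q: the best achievable FDR over deltas at which it is called
  q <- rep(NA_real_, n)
  for (k in seq_along(grid)) {
    in_call <- d >= cutup[k] | d <= cutlow[k]
    q[in_call] <- pmin(q[in_call], fdr_grid[k], na.rm = TRUE)
  }
  q[is.na(q)] <- 1

  res <- data.frame(protein_id = rownames(xall) %||% as.character(seq_len(n)),
                    xbar_stress = obs$m1, xbar_control = obs$m2,
                    s_i = obs$s, d_i = d, q = q, called = called,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "s0") <- s0
  attr(res, "delta") <- delta
  attr(res, "fdr_at_delta") <- fdr_at
  attr(res, "n_perm_used") <- B_all
  attr(res, "fdr_method") <- fdr_method
  class(res) <- c("sam_result", "data.frame")
  res
}

## Tusher-style s0: the s-quantile minimising the coefficient of variation of
## window-wise spread of d across s-percentile bins.
select_s0 <- function(r, s, mode) {
  if (mode == "median") return(median(s))
  alphas <- seq(0, 1, by = 0.05)
  n <- length(s)
  nb <- max(2L, min(20L, floor(n / 10)))
  bins <- cut(rank(s, ties.method = "first"), breaks = nb, labels = FALSE)
  cvs <- vapply(alphas, function(a) {
    s0a <- as.numeric(quantile(s, a))
    da <- r / (s + s0a)
    if (any(!is.finite(da))) return(Inf)
    v <- tapply(da, bins, mad)
    if (mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, 0)
  if (all(!is.finite(cvs))) return(median(s))  # degenerate: d identically 0
  as.numeric(quantile(s, alphas[which.min(cvs)]))
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM permutation test: %d proteins, s0 = %.4g, delta = %.4g\n",
              nrow(x), attr(x, "s0"), attr(x, "delta")))
  cat(sprintf("  called: %d (estimated FDR %.3g, %d permutations, %s)\n",
              sum(x$called), attr(x, "fdr_at_delta") %||% NA,
              attr(x, "n_perm_used"), attr(x, "fdr_method")))
  invisible(x)
}

#' Five-category protein classification with sentinel display values
#'
#' A protein detected under both conditions is \code{up} (FDR pass and linear
#' fold change >= \code{fold_thresh}), \code{down} (FDR pass and fold <=
#' 1/\code{fold_thresh}) or \code{nonsig}. A protein detected exclusively
#' under stress is \code{stress_only} with display value \code{sentinel_up}
#' (+6.0); exclusively under control, \code{control_only} with
#' \code{sentinel_down} (-5.0) - the heat-map convention of assigning those
#' sets the maximum value observed among differentially regulated proteins.
#'
#' @param detected_stress,detected_control detection flags per condition.
#' @param fold_change linear replicate-mean ratio stress/control (NA for
#'   exclusive detection).
#' @param fdr_pass did the SAM call pass the FDR threshold?
#' @param fold_thresh fold-change requirement (default 2.0).
#' @param sentinel_up,sentinel_down display sentinels for exclusive detection.
#' @return one-row data.frame: \code{category, fold_change, display_value,
#'   fdr_pass}.
#' @export
classify_protein <- function(detected_stress, detected_control,
                             fold_change = NA_real_, fdr_pass = FALSE,
                             fold_thresh = 2, sentinel_up = 6,
                             sentinel_down = -5) {
  stopifnot(is_flag(detected_stress), is_flag(detected_control))
  if (!detected_stress && !detected_control)
    abort("protein undetected under both conditions: excluded from classification")
  if (detected_stress && !detected_control) {
    return(data.frame(category = "stress_only", fold_change = NA_real_,
                      display_value = sentinel_up, fdr_pass = NA,
                      stringsAsFactors = FALSE))
  }
  if (!detected_stress && detected_control) {
    return(data.frame(category = "control_only", fold_change = NA_real_,
                      display_value = sentinel_down, fdr_pass = NA,
                      stringsAsFactors = FALSE))
  }
  if (is.na(fold_change) || fold_change <= 0)
    abort("fold_change must be a positive number for both-detected proteins")
  category <- if (isTRUE(fdr_pass) && fold_change >= fold_thresh) "up"
  else if (isTRUE(fdr_pass) && fold_change <= 1 / fold_thresh) "down"
  else "nonsig"
  display <- if (fold_change >= 1) fold_change else -1 / fold_change
  data.frame(category = category, fold_change = fold_change,
             display_value = display, fdr_pass = isTRUE(fdr_pass),
             stringsAsFactors = FALSE)
}

#' Classify every protein of one stress level
#'
#' Vectorised wrapper around [classify_protein()]: establishes detection per
#' condition (quantified in at least \code{min_detect} samples), computes
#' replicate-mean linear fold changes, runs [sam_test()] on the
#' both-detected set, and returns one differential record per protein.
#' Proteins undetected in both conditions are excluded with a message.
#'
#' @param ratios ratio-to-pool matrix (NA = not detected) for one stressor.
#' @param stress_cols,control_cols sample columns of the stress level and its
#'   control.
#' @param min_detect samples required to call a protein detected (default 1).
#' @param fold_thresh,fdr_target,sentinel_up,sentinel_down see
#'   [classify_protein()].
#' @param ... passed to [sam_test()].
#' @return data.frame with one row per detected protein: \code{protein_id,
#'   category, fold_change, display_value, fdr_pass, d_i, q}.
#' @export
classify_proteins <- function(ratios, stress_cols, control_cols,
                              min_detect = 1, fold_thresh = 2,
                              fdr_target = 0.05, sentinel_up = 6,
                              sentinel_down = -5, ...) {
  rs <- ratios[, stress_cols, drop = FALSE]
  rc <- ratios[, control_cols, drop = FALSE]
  det_s <- rowSums(!is.na(rs)) >= min_detect
  det_c <- rowSums(!is.na(rc)) >= min_detect
  excluded <- !det_s & !det_c
  if (any(excluded))
    message(sum(excluded), " proteins undetected under both conditions: excluded")

  ids <- rownames(ratios)
  out <- data.frame(protein_id = ids, category = NA_character_,
                    fold_change = NA_real_, display_value = NA_real_,
                    fdr_pass = NA, d_i = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE)
  out$category[det_s & !det_c] <- "stress_only"
  out$display_value[det_s & !det_c] <- sentinel_up
  out$category[!det_s & det_c] <- "control_only"
  out$display_value[!det_s & det_c] <- sentinel_down

  both <- det_s & det_c
  if (any(both)) {
    lg <- normalize_ratios(ratios[, c(stress_cols, control_cols), drop = FALSE])
    lg <- lg[both, , drop = FALSE]
    sam <- sam_test(lg, seq_along(stress_cols),
                    length(stress_cols) + seq_along(control_cols),
                    fdr_target = fdr_target, ...)
    pass <- setNames(sam$called, sam$protein_id)
    qv <- setNames(sam$q, sam$protein_id)
    dv <- setNames(sam$d_i, sam$protein_id)
    fold <- rowMeans(rs[both, , drop = FALSE], na.rm = TRUE) /
      rowMeans(rc[both, , drop = FALSE], na.rm = TRUE)
    for (id in ids[both]) {
      in_sam <- id %in% names(pass)
      rec <- classify_protein(TRUE, TRUE, fold[[id]],
                              fdr_pass = in_sam && isTRUE(pass[[id]]),
                              fold_thresh = fold_thresh,
                              sentinel_up = sentinel_up,
                              sentinel_down = sentinel_down)
      k <- match(id, ids)
      out$category[k] <- rec$category
      out$fold_change[k] <- rec$fold_change
      out$display_value[k] <- rec$display_value
      out$fdr_pass[k] <- rec$fdr_pass
      out$d_i[k] <- if (in_sam) dv[[id]] else NA_real_
      out$q[k] <- if (in_sam) qv[[id]] else NA_real_
    }
  }
  out[!excluded, , drop = FALSE]
}
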