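#' Centered moving median
#'
#' Smooths a track with a centred moving median of odd length; near the
#' edges the window is clipped to the available values, so the output has
#' the same length as the input.
#'
#' @param x numeric vector.
#' @param window odd window length (number of variables).
#' @return Smoothed vector of the same length.
#' @examples
#' moving_median(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
#' @export
moving_median <- function(x, window = 21L) {
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive count")
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  if (n > window) {
    out <- as.numeric(runmed(x, window, endrule = "keep"))
  } else {
    out <- x
  }
  edge <- seq_len(min(half, n))
  for (i in edge) out[i] <- median(x[seq_len(min(n, i + half))])
  for (i in edge) out[n - i + 1L] <- median(x[max(1L, n - i + 1L - half):n])
  out
}

#' Call altered variables from a smoothed M-track
#'
#' A variable is called altered when its smoothed M-value lies strictly
#' above `factor * log2(delta)`, the conventional operating cut-off at 70%
#' of the expected log fold change.
#'
#' @param smoothed smoothed M-values.
#' @param delta effect size (> 1) defining the cut-off; for mixed-delta
#'   experiments use the smallest effect size present (a single,
#'   conservative operating threshold).
#' @param factor cut-off multiplier, default 0.7.
#' @return Logical call mask.
#' @export
call_altered <- function(smoothed, delta, factor = 0.7) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 1)
    stop("delta must be a single value > 1")
  smoothed > factor * log2(delta)
}

#' Sensitivity and specificity of a call set
#'
#' @param calls logical calls.
#' @param truth logical ground truth with at least one `TRUE` and one
#'   `FALSE`.
#' @return List with `sensitivity` (`TP / (TP + FN)`) and `specificity`
#'   (`TN / (TN + FP)`).
#' @export
confusion_metrics <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  if (length(calls) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("truth must contain both classes")
  list(sensitivity = sum(calls & truth) / sum(truth),
       specificity = sum(!calls & !truth) / sum(!truth))
}

#' Fold-change bias of the altered variables
#'
#' Mean shrinkage of the altered variables' (non-smoothed) M-values toward
#' zero: `mean over altered of sign(true_lr) * (true_lr - M)`.  For purely
#' positive alterations this is `mean(log2(delta) - M)`; the signed form
#' treats up- and down-alterations symmetrically, so positive bias always
#' means the observed fold change underestimates the true one.
#'
#' @param m_track numeric vector of non-smoothed M-values.
#' @param truth logical altered mask with at least one `TRUE`.
#' @param true_log_ratio per-variable true log2 ratios.
#' @return The bias (log2 units).
#' @export
fold_change_bias <- function(m_track, truth, true_log_ratio) {
  truth <- as.logical(truth)
  if (!any(truth)) stop("no altered variables")
  stopifnot(length(m_track) == length(truth),
            length(true_log_ratio) == length(truth))
  tl <- true_log_ratio[truth]
  mean(sign(tl) * (tl - m_track[truth]))
}

#' Performance relative to the ideal normalization
#'
#' @param method,ideal lists with elements `sensitivity`, `specificity`
#'   and `bias` (e.g. rows of [evaluate_normalizations()]).
#' @return List with `relative_sensitivity` and `relative_specificity`
#'   (ratios) and `relative_bias` (difference, method minus ideal).
#' @export
relative_metrics <- function(method, ideal) {
  if (!is.numeric(ideal$sensitivity) || ideal$sensitivity <= 0)
    stop("ideal sensitivity must be positive")
  list(relative_sensitivity = method$sensitivity / ideal$sensitivity,
       relative_specificity = method$specificity / ideal$specificity,
       relative_bias = method$bias - ideal$bias)
}

#' Sensitivity at a fixed false-positive rate
#'
#' The score threshold is the empirical `1 - fpr` quantile (type-7) of the
#' null (unaltered) scores; sensitivity is the fraction of truly altered
#' scores strictly above it.
#'
#' @param scores numeric score per variable (higher = more altered).
#' @param truth logical altered mask containing both classes.
#' @param fpr accepted false-positive rate, default 0.005.
#' @return The sensitivity.
#' @export
sensitivity_at_fpr <- function(scores, truth, fpr = 0.005) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth)) stop("truth must contain both classes")
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  thr <- quantile(scores[!truth], 1 - fpr, names = FALSE, type = 7L)
  mean(scores[truth] > thr)
}

#' Benchmark normalization strategies on one simulated experiment
#'
#' Runs the full downstream analysis for each requested normalization:
#' normalize, compute M-values, smooth with a moving median, call altered
#' variables above `factor * log2(min delta)`, and score sensitivity,
#' specificity and bias against the simulation truth.
#'
#' @param sim a [simulate_experiment()] result.
#' @param methods subset of `"standard"`, `"invariant"`, `"hmm"`,
#'   `"ideal"`.
#' @param window moving-median length.
#' @param factor cut-off multiplier.
#' @param fraction invariant subset fraction, see
#'   [rank_invariant_select()].
#' @param rho,region_length HMM pipeline settings, see [hmm_normalize()].
#' @param cutoff_delta effect size defining the calling cut-off; defaults
#'   to the smallest effect size present in the simulation.
#' @return A data frame with one row per method and columns `method`,
#'   `sensitivity`, `specificity`, `bias`, `cutoff`.
#' @export
evaluate_normalizations <- function(sim,
                                    methods = c("standard", "invariant",
                                                "hmm", "ideal"),
                                    window = 21L, factor = 0.7,
                                    fraction = 0.5, rho = 0.1,
                                    region_length = 50,
                                    cutoff_delta = NULL) {
  stopifnot(inherits(sim, "SimulatedExperiment"))
  methods <- match.arg(methods, several.ok = TRUE)
  lm <- to_log2(sim$matrix)
  if (is.null(cutoff_delta)) {
    if (!any(sim$truth))
      stop("no altered variables; supply cutoff_delta explicitly")
    cutoff_delta <- min(sim$delta[sim$truth])
  }
  rows <- lapply(methods, function(meth) {
    norm <- switch(meth,
      standard = quantile_normalize(lm, method = "standard"),
      invariant = quantile_normalize(
        lm, ref = rank_invariant_select(lm, sim$design, fraction),
        method = "invariant"),
      hmm = hmm_normalize(lm, sim$design, rho = rho,
                          region_length = region_length),
      ideal = quantile_normalize(lm, ref = ideal_reference(sim$truth),
                                 method = "ideal"))
    track <- m_values(norm$matrix, sim$design)
    sm <- moving_median(track$m, window)
    calls <- call_altered(sm, cutoff_delta, factor)
    cm <- confusion_metrics(calls, sim$truth)
    data.frame(method = meth, sensitivity = cm$sensitivity,
               specificity = cm$specificity,
               bias = fold_change_bias(track$m, sim$truth,
                                       sim$true_log_ratio),
               cutoff = factor * log2(cutoff_delta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Power of the DSE-test over a simulation grid
#'
#' For every grid row, experiments are simulated and tested with the
#' requested DSE-test variant; power is the fraction with `p < level`.
#' The `alpha = 0` rows estimate the empirical false-positive rate.  The
#' per-variable parameters are drawn once per grid row from the synthetic
#' prior and held fixed across replicates, mirroring parameters estimated
#' once from real reference data.
#'
#' @param grid data frame with columns `n`, `k`, `alpha`, `m`, `delta`.
#' @param variant `"dependent"` or `"independent"`.
#' @param n_sims simulated experiments per grid row (>= 1).
#' @param level significance level, default 0.05.
#' @param seed integer seed for the whole grid.
#' @return The grid with added columns `power`, `se` (binomial standard
#'   error) and `feasible` (`FALSE` e.g. for the independent variant with
#'   fewer than 4 samples per arm; power is `NA` there).
#' @export
dse_power <- function(grid, variant = c("dependent", "independent"),
                      n_sims = 100L, level = 0.05, seed = 1L) {
  variant <- match.arg(variant)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  need <- c("n", "k", "alpha", "m", "delta")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "))
  grid$power <- NA_real_
  grid$se <- NA_real_
  grid$feasible <- TRUE
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, ]
    cell_seed <- (seed + 7919L * (g - 1L)) %% .Machine$integer.max
    vp <- synth_variable_params(row$n, seed = cell_seed)
    rej <- logical(n_sims)
    feasible <- TRUE
    for (i in seq_len(n_sims)) {
      cfg <- simulation_config(row$n, row$k, row$alpha, row$m, row$delta,
                               seed = (cell_seed + i) %%
                                 .Machine$integer.max)
      sim <- simulate_experiment(cfg, vp)
      res <- tryCatch(
        dse_test(to_log2(sim$matrix), sim$design, variant,
                 pre_normalize = FALSE),
        error = function(e) e)
      if (inherits(res, "error")) {
        feasible <- FALSE
        break
      }
      rej[i] <- res$p_value < level
    }
    if (feasible) {
      p <- mean(rej)
      grid$power[g] <- p
      grid$se[g] <- sqrt(p * (1 - p) / n_sims)
    } else {
      grid$feasible[g] <- FALSE
    }
  }
  grid
}

#' M-value density summary for visual inspection
#'
#' Gaussian kernel density of the M-values (bandwidth `0.9 * min(sd,
#' IQR/1.34) * n^(-1/5)`, the classic rule-of-thumb default) together with
#' the quartiles.  For a non-skewed experiment the density is roughly
#' symmetric and `Q1 + Q3 - 2 * median` is near zero; a heavy right
#' shoulder suggests a positively skewed experiment.
#'
#' @param track an [m_values()] track (or numeric vector) of length >= 10.
#' @param n_grid number of evaluation points.
#' @return List with `grid`, `density` and `quartiles` (Q1, median, Q3).
#' @export
m_density <- function(track, n_grid = 512L) {
  x <- if (inherits(track, "MValueTrack")) track$m else as.numeric(track)
  if (length(x) < 10L) stop("need at least 10 values")
  if (sd(x) == 0) stop("zero spread")
  d <- density(x, bw = "nrd0", n = n_grid)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7L)
  list(grid = d$x, density = d$y,
       quartiles = setNames(q, c("q1", "median", "q3")))
}
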