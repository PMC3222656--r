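#' Bowley quartile-skewness coefficient
#'
#' `qs(x) = (Q3 + Q1 - 2 * median) / (Q3 - Q1)`, with quartiles computed by
#' linear interpolation of order statistics (type-7).  The coefficient is 0
#' for quartile-symmetric data, positive for right skew, and bounded in
#' \[-1, 1\].  Unlike moment skewness it only looks at the central half of
#' the distribution, which makes it robust for heavy-tailed log-ratio
#' tracks.
#'
#' @param x numeric vector of log-ratios, at least 4 finite values.
#' @return The quartile-skewness coefficient.
#' @examples
#' qs_coefficient(c(-2, -1, 0, 1, 2))  # 0
#' @export
qs_coefficient <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 finite values")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7L)
  iqr <- q[3L] - q[1L]
  if (iqr <= 0) stop("degenerate spread: Q3 equals Q1")
  (q[3L] + q[1L] - 2 * q[2L]) / iqr
}

#' Per-variable log-ratios of one sample pair
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @param a,b sample ids; the result is `a - b` per variable.
#' @return Numeric vector of log2 ratios.
#' @export
pair_log_ratios <- function(m, a, b) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("expects log2-scale data")
  for (id in c(a, b))
    if (!id %in% sample_ids(m)) stop("unknown sample id: ", id)
  m$values[, a] - m$values[, b]
}

#' Build heterogeneous and homogeneous sample pairs for the DSE-test
#'
#' Heterogeneous pairs couple one treatment with one reference sample;
#' homogeneous pairs couple two samples of the same arm.  Pairing is
#' non-overlapping within each list (each sample is used in at most one
#' heterogeneous and at most one homogeneous pair).
#'
#' *Dependent* variant: all samples are available to both lists, giving
#' `min(n_T, n_R)` heterogeneous and `floor(n_T/2) + floor(n_R/2)`
#' homogeneous pairs.  *Independent* variant: each arm is split in half
#' (first `ceiling(n/2)` samples by sorted id feed the heterogeneous pairs,
#' the rest the homogeneous pairs) so no sample appears in both lists and
#' the resulting qs-coefficients are independent; this halves the number of
#' observations and requires at least 4 samples per arm.
#'
#' Non-overlapping pairs can be formed in many ways; by default samples are
#' paired first-come in sorted-id order.  Supplying `seed` instead draws one
#' alternative at random (for sensitivity analysis).
#'
#' @param design a [group_design()].
#' @param variant `"dependent"` or `"independent"`.
#' @param seed optional integer; if given, sample order within arms is
#'   shuffled reproducibly before pairing.
#' @return A list of class `PairSet` with data frame `pairs` (columns
#'   `sample_a`, `sample_b`, `kind`) and the `variant`.
#' @export
build_pairs <- function(design, variant = c("dependent", "independent"),
                        seed = NULL) {
  variant <- match.arg(variant)
  tr <- sort(arm_ids(design, "treatment"))
  rf <- sort(arm_ids(design, "reference"))
  if (!is.null(seed)) {
    set.seed(seed)
    tr <- sample(tr)
    rf <- sample(rf)
  }
  nt <- length(tr)
  nr <- length(rf)
  if (variant == "dependent") {
    if (min(nt, nr) < 2L)
      stop("dependent DSE-test needs at least 2 samples per arm")
    het_t <- tr[seq_len(min(nt, nr))]
    het_r <- rf[seq_len(min(nt, nr))]
    hom <- rbind(arm_pairs(tr), arm_pairs(rf))
  } else {
    if (nt < 4L || nr < 4L)
      stop("independent DSE-test needs at least 4 samples per arm ",
           "(one heterogeneous and one homogeneous pair per arm half)")
    t_het <- tr[seq_len(ceiling(nt / 2))]
    r_het <- rf[seq_len(ceiling(nr / 2))]
    t_hom <- tr[-seq_len(ceiling(nt / 2))]
    r_hom <- rf[-seq_len(ceiling(nr / 2))]
    nhet <- min(length(t_het), length(r_het))
    het_t <- t_het[seq_len(nhet)]
    het_r <- r_het[seq_len(nhet)]
    hom <- rbind(arm_pairs(t_hom), arm_pairs(r_hom))
  }
  pairs <- rbind(
    data.frame(sample_a = het_t, sample_b = het_r,
               kind = "heterogeneous", stringsAsFactors = FALSE),
    hom)
  structure(list(pairs = pairs, variant = variant), class = "PairSet")
}

# consecutive disjoint same-arm pairs; label by arm of the first sample
arm_pairs <- function(ids) {
  np <- length(ids) %/% 2L
  if (np == 0L)
    return(data.frame(sample_a = character(), sample_b = character(),
                      kind = character(), stringsAsFactors = FALSE))
  i <- seq_len(np)
  data.frame(sample_a = ids[2L * i - 1L], sample_b = ids[2L * i],
             kind = "homogeneous", stringsAsFactors = FALSE)
}

#' Enumerate the admissible homogeneous pairings of a design
#'
#' For one arm with `n` samples, a maximal non-overlapping homogeneous
#' pairing is an unordered set of `floor(n/2)` disjoint pairs; this function
#' enumerates all such sets for both arms and returns every combination.
#' With 3 treatment and 3 reference samples there are `C(3,2) * C(3,2) = 9`
#' alternatives.  [build_pairs()] always uses the first one in sorted-id
#' order (or a seeded random choice).
#'
#' @param design a [group_design()].
#' @return A list of pairing alternatives; each element is a data frame with
#'   columns `sample_a`, `sample_b`.
#' @export
enumerate_homogeneous_pairings <- function(design) {
  tr <- sort(arm_ids(design, "treatment"))
  rf <- sort(arm_ids(design, "reference"))
  combine <- function(ta, ra) rbind(ta, ra)
  out <- list()
  for (ta in disjoint_pairings(tr))
    for (ra in disjoint_pairings(rf))
      out[[length(out) + 1L]] <- combine(ta, ra)
  out
}

# all unordered sets of floor(n/2) disjoint pairs from ids (recursion over
# the smallest remaining id keeps each set unique)
disjoint_pairings <- function(ids) {
  np <- length(ids) %/% 2L
  if (np == 0L)
    return(list(data.frame(sample_a = character(), sample_b = character(),
                           stringsAsFactors = FALSE)))
  recurse <- function(remaining, depth) {
    if (depth == 0L)
      return(list(data.frame(sample_a = character(), sample_b = character(),
                             stringsAsFactors = FALSE)))
    out <- list()
    # the lexicographically smallest remaining id may head a pair or sit out
    # (sitting out is only possible if enough samples remain)
    for (first in seq_along(remaining)) {
      if (length(remaining) - first < 2L * depth - 1L) break
      a <- remaining[first]
      rest0 <- remaining[-seq_len(first)]
      for (second in seq_along(rest0)) {
        b <- rest0[second]
        sub <- recurse(setdiff(rest0, b), depth - 1L)
        for (s in sub)
          out[[length(out) + 1L]] <-
            rbind(data.frame(sample_a = a, sample_b = b,
                             stringsAsFactors = FALSE), s)
      }
    }
    out
  }
  recurse(ids, np)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, as used to
#' compare the mean qs-coefficients of the heterogeneous and homogeneous
#' pair groups.
#'
#' @param a,b numeric vectors with at least 2 values each; at least one
#'   group must have nonzero variance.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group")
  if (var(a) == 0 && var(b) == 0)
    stop("both groups have zero variance")
  fit <- t.test(a, b, var.equal = FALSE, alternative = alternative)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' DSE-test: detection of skewed experiments
#'
#' Tests whether the distribution of the truly altered variables is skewed
#' (asymmetric around zero).  Per-variable log-ratios are formed for
#' heterogeneous (treatment vs reference) and homogeneous (same-arm) sample
#' pairs and their Bowley quartile-skewness coefficients are compared by
#' Welch's t-test.  Technical variation affects both pair kinds equally, so
#' a significant difference indicates genuine asymmetry of the treatment
#' effect; if significant, the experiment is called skewed and invariant
#' re-normalization (e.g. [hmm_normalize()]) is advised.
#'
#' The dependent variant reuses every sample in both pair groups (maximal
#' power, slightly anti-conservative for tiny designs); the independent
#' variant keeps the groups disjoint and controls the false-positive rate
#' at the cost of half the observations.
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @param design a [group_design()].
#' @param variant `"dependent"` or `"independent"`.
#' @param pre_normalize apply standard quantile normalization (all-variable
#'   reference) before testing.  Default `TRUE`; set `FALSE` when the input
#'   is already normalized.
#' @param alternative passed to [welch_t()]; two-sided by default.
#' @param seed optional seed forwarded to [build_pairs()].
#' @return A list of class `DseResult` with `p_value`, `t_statistic`,
#'   `satterthwaite_df`, `qs_het`, `qs_hom` and `variant`.
#' @examples
#' vp <- synth_variable_params(2000, seed = 1)
#' sim <- simulate_experiment(
#'   simulation_config(n = 2000, k = 4, alpha = 0.2, m = 50, delta = 2,
#'                     seed = 1), vp)
#' dse_test(to_log2(sim$matrix), sim$design, pre_normalize = FALSE)$p_value
#' @export
dse_test <- function(m, design, variant = c("dependent", "independent"),
                     pre_normalize = TRUE, alternative = "two.sided",
                     seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("expects log2-scale data")
  check_design(m, design)
  if (pre_normalize) m <- quantile_normalize(m)$matrix
  ps <- build_pairs(design, variant, seed = seed)
  qs <- vapply(seq_len(nrow(ps$pairs)), function(i) {
    qs_coefficient(pair_log_ratios(m, ps$pairs$sample_a[i],
                                   ps$pairs$sample_b[i]))
  }, 0)
  het <- qs[ps$pairs$kind == "heterogeneous"]
  hom <- qs[ps$pairs$kind == "homogeneous"]
  wt <- welch_t(het, hom, alternative = alternative)
  structure(list(p_value = wt$p, t_statistic = wt$t,
                 satterthwaite_df = wt$df, qs_het = het, qs_hom = hom,
                 variant = variant, pairs = ps$pairs),
            class = "DseResult")
}

#' @export
print.DseResult <- function(x, ...) {
  cat(sprintf("DSE-test (%s): t = %.3f, df = %.2f, p = %.4g\n",
              x$variant, x$t_statistic, x$satterthwaite_df, x$p_value))
  cat(sprintf("  qs heterogeneous: %s\n",
              paste(sprintf("%.3f", x$qs_het), collapse = ", ")))
  cat(sprintf("  qs homogeneous:   %s\n",
              paste(sprintf("%.3f", x$qs_hom), collapse = ", ")))
  invisible(x)
}
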