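#' Reference-set driven quantile normalization
#'
#' Generalizes one-channel quantile normalization to an arbitrary reference
#' (invariant) set of variables.  The target distribution is the
#' across-sample mean of each sample's sorted values restricted to the
#' reference variables.  For each sample, a monotone piecewise-linear map is
#' built from that sample's reference quantiles to the target quantiles and
#' applied to *all* variables; values outside the reference range are
#' extrapolated linearly with the outermost segment slopes.  Tied reference
#' values are collapsed to the mean of the target values their ranks span,
#' keeping the map well defined and monotone.
#'
#' With `ref = NULL` (all variables) this reduces to classic quantile
#' normalization: every sample's sorted value vector becomes the common
#' target distribution.
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @param ref logical vector over variables (`TRUE` = used to estimate the
#'   normalization function) with at least 2 `TRUE` entries, or `NULL` for
#'   all variables.
#' @param method label stored in the result, e.g. `"standard"`,
#'   `"invariant"`, `"hmm"`, `"ideal"`.
#' @return A list of class `NormalizationResult` with elements `matrix`
#'   (normalized `IntensityMatrix`), `reference_set` (logical mask) and
#'   `method`.
#' @examples
#' m <- intensity_matrix(cbind(s1 = c(1, 3), s2 = c(2, 4)), scale = "log2")
#' quantile_normalize(m)$matrix$values  # both samples -> (1.5, 3.5)
#' @export
quantile_normalize <- function(m, ref = NULL, method = NULL) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2")
    stop("quantile_normalize expects log2-scale data; call to_log2() first")
  n <- nrow(m$values)
  if (is.null(ref)) ref <- rep.int(TRUE, n)
  ref <- as.logical(ref)
  if (length(ref) != n) stop("reference mask length must equal nrow")
  if (anyNA(ref)) stop("reference mask must not contain NA")
  if (sum(ref) < 2L) stop("reference set must contain at least 2 variables")
  if (is.null(method)) method <- if (all(ref)) "standard" else "invariant"

  sorted_ref <- apply(m$values[ref, , drop = FALSE], 2L, sort)
  target <- rowMeans(sorted_ref)
  out <- m$values
  for (j in seq_len(ncol(out))) {
    knots_x <- sorted_ref[, j]
    if (knots_x[length(knots_x)] - knots_x[1L] <= 0)
      stop("constant sample '", colnames(out)[j],
           "' over the reference set: zero spread")
    out[, j] <- piecewise_quantile_map(knots_x, target, out[, j])
  }
  res <- m
  res$values <- out
  structure(list(matrix = res, reference_set = ref, method = method),
            class = "NormalizationResult")
}

# monotone piecewise-linear map through (x_sorted, y_sorted) with mean
# collapsing of tied x and linear tail extrapolation by end-segment slopes
piecewise_quantile_map <- function(x_sorted, y_sorted, xout) {
  ux <- unique(x_sorted)
  if (length(ux) < length(x_sorted)) {
    uy <- vapply(split(y_sorted, match(x_sorted, ux)), mean, 0)
  } else {
    uy <- y_sorted
  }
  k <- length(ux)
  if (k < 2L) stop("degenerate reference distribution: single unique value")
  inner <- approx(ux, uy, xout = xout, rule = 2L, ties = "ordered")$y
  lo <- xout < ux[1L]
  hi <- xout > ux[k]
  if (any(lo)) {
    s <- (uy[2L] - uy[1L]) / (ux[2L] - ux[1L])
    inner[lo] <- uy[1L] + s * (xout[lo] - ux[1L])
  }
  if (any(hi)) {
    s <- (uy[k] - uy[k - 1L]) / (ux[k] - ux[k - 1L])
    inner[hi] <- uy[k] + s * (xout[hi] - ux[k])
  }
  inner
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat(sprintf("NormalizationResult (%s): %d/%d reference variables\n",
              x$method, sum(x$reference_set), length(x$reference_set)))
  invisible(x)
}

#' Rank-invariant reference-set selection
#'
#' A transparent invariant-set comparator: for every variable the rank
#' instability is the absolute difference between its mean within-sample
#' rank across treatment samples and across reference samples.  The
#' `ceiling(fraction * n)` variables with the smallest instability form the
#' reference set, with ties broken by variable index.  Variables whose
#' abundance responds to treatment change rank systematically between the
#' arms and are excluded.
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @param design a [group_design()].
#' @param fraction proportion of variables to keep, in (0, 1]; 0.5 is the
#'   conventional subset size for invariant normalization.
#' @return Logical mask over variables (`TRUE` = selected).
#' @export
rank_invariant_select <- function(m, design, fraction = 0.5) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("expects log2-scale data")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  check_design(m, design)
  n <- nrow(m$values)
  ranks <- apply(m$values, 2L, rank)
  tr <- rowMeans(ranks[, arm_ids(design, "treatment"), drop = FALSE])
  rf <- rowMeans(ranks[, arm_ids(design, "reference"), drop = FALSE])
  instability <- abs(tr - rf)
  keep_n <- ceiling(fraction * n)
  sel <- order(instability, seq_len(n))[seq_len(keep_n)]
  mask <- rep.int(FALSE, n)
  mask[sel] <- TRUE
  mask
}

#' Oracle reference set from known truth
#'
#' For simulation controls only: the ideal normalization uses exactly the
#' truly unaltered variables as its reference set.
#'
#' @param truth logical mask of truly altered variables.
#' @return Logical mask, the complement of `truth`.
#' @export
ideal_reference <- function(truth) {
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("truth mask must not contain NA")
  if (all(truth)) stop("all variables altered: empty reference set")
  !truth
}
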