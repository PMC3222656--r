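#' Per-variable M-values (log2 ratio of group averages)
#'
#' For every variable the arithmetic mean of the log2 intensities is taken
#' within each arm and the M-value is the treatment minus the reference
#' mean, i.e. the log2 ratio of the arms' geometric-mean intensities.  The
#' M-value of an unaltered variable is centred at zero; an altered variable
#' with effect size `delta` is centred at `log2(delta)`.
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @param design a [group_design()] with at least one sample per arm.
#' @return A list of class `MValueTrack` with `m` (ordered numeric vector)
#'   and `blocks` (inherited order blocks).
#' @export
m_values <- function(m, design) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("expects log2-scale data")
  check_design(m, design)
  tr <- arm_ids(design, "treatment")
  rf <- arm_ids(design, "reference")
  if (length(tr) == 0L || length(rf) == 0L) stop("empty arm")
  mv <- rowMeans(m$values[, tr, drop = FALSE]) -
    rowMeans(m$values[, rf, drop = FALSE])
  structure(list(m = unname(mv), blocks = m$blocks, ids = variable_ids(m)),
            class = "MValueTrack")
}

#' @export
print.MValueTrack <- function(x, ...) {
  cat(sprintf("MValueTrack: %d variables, mean %.4f, sd %.4f\n",
              length(x$m), mean(x$m), sd(x$m)))
  invisible(x)
}

#' Initial HMM parameters by mixture moment matching
#'
#' Starting values for the two-state Gaussian HMM are derived by assuming
#' the M-values come from a mixture `(1 - rho) * N(0, s2) + rho * N(mu2,
#' s2)`: the unaltered state has mean 0, the altered-state mean follows
#' from the track mean (`mu2 = mean(M) / rho`), and the shared variance is
#' the track variance minus the between-component part, floored at half the
#' track variance if that subtraction turns non-positive.  `rho` itself is
#' a guess of the altered fraction.  Transition rates encode the expected
#' region length: altered regions exit at rate `1 / expected_region_length`
#' and the unaltered state enters altered regions at the rate that makes
#' `(1 - rho, rho)` the stationary distribution, which is also used as the
#' initial distribution.
#'
#' @param track an [m_values()] track.
#' @param rho guessed fraction of altered variables, in (0, 1).
#' @param expected_region_length expected number of consecutive altered
#'   variables per region.
#' @return A list of class `HmmParams` with `rho`, `mu`, `sigma`, `trans`
#'   and `init`.
#' @export
init_hmm <- function(track, rho = 0.1, expected_region_length = 50) {
  stopifnot(inherits(track, "MValueTrack"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("rho must be in (0, 1)")
  if (expected_region_length < 1) stop("expected_region_length must be >= 1")
  v <- var(track$m)
  if (!is.finite(v) || v <= 0) stop("M-value track has zero variance")
  mu2 <- mean(track$m) / rho
  s2 <- v - rho * (1 - rho) * mu2^2
  if (s2 <= 0) s2 <- v / 2
  p_exit <- 1 / expected_region_length
  p_enter <- rho / ((1 - rho) * expected_region_length)
  trans <- matrix(c(1 - p_enter, p_enter, p_exit, 1 - p_exit),
                  2L, 2L, byrow = TRUE)
  structure(list(rho = rho, mu = c(0, mu2), sigma = rep(sqrt(s2), 2L),
                 trans = trans, init = c(1 - rho, rho)),
            class = "HmmParams")
}

#' Fit a two-state Gaussian HMM to an M-value track
#'
#' Baum-Welch EM with a scaled forward-backward recursion (compiled), run
#' per order block as independent chains sharing one parameter set (joint
#' accumulators).  Iteration stops when the relative log-likelihood change
#' drops below `tol` or after `max_iter` iterations.  Emission standard
#' deviations are floored at `1e-4 * sd(track)` to prevent singular
#' components; a clamped fit is flagged, not fatal.  The state path is
#' obtained by Viterbi decoding by default (posterior decoding optional),
#' so that classified regions are contiguous.
#'
#' @param track an [m_values()] track with at least 10 variables.
#' @param init an [init_hmm()] parameter set (default: moment-matching
#'   initialization with `rho = 0.1`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param decode `"viterbi"` or `"posterior"`.
#' @return A list of class `HmmFit` with fitted `params`, integer `states`
#'   (1 and 2 as ordered in `params$mu`), `loglik` (per-iteration trace),
#'   `converged` and `sigma_clamped` flags.
#' @export
fit_hmm <- function(track, init = NULL, tol = 1e-6, max_iter = 500,
                    decode = c("viterbi", "posterior")) {
  stopifnot(inherits(track, "MValueTrack"))
  decode <- match.arg(decode)
  x <- track$m
  n <- length(x)
  if (n < 10L) stop("need at least 10 variables to fit the HMM")
  if (!all(is.finite(x))) stop("M-values must be finite")
  if (sd(x) == 0) stop("M-value track has zero variance")
  if (is.null(init)) init <- init_hmm(track)
  stopifnot(inherits(init, "HmmParams"))
  block_start <- c(1L, which(diff(track$blocks) != 0L) + 1L)

  sd_floor <- 1e-4 * sd(x)
  mu <- init$mu
  # Symmetry breaking: if the initial state means coincide (e.g. the track
  # was mean-centred by a preceding normalization, so the first-moment
  # mixture estimate of the altered mean collapses to zero), EM starts at
  # an exchangeable saddle point and cannot separate the states.  The
  # component separation is then re-estimated from the third central
  # moment, which symmetric noise leaves untouched: for a two-component
  # equal-variance mixture with altered fraction rho, kappa3 =
  # rho * (1 - rho) * (1 - 2 * rho) * separation^3.
  if (abs(mu[2L] - mu[1L]) < 1e-3 * sd(x)) {
    rho <- min(max(init$rho, 1e-3), 0.49)
    k3 <- mean((x - mean(x))^3)
    sep <- sign(k3) * (abs(k3) / (rho * (1 - rho) * (1 - 2 * rho)))^(1 / 3)
    if (!is.finite(sep) || abs(sep) < 0.5 * sd(x))
      sep <- if (k3 >= 0) sd(x) else -sd(x)
    mu[2L] <- mu[1L] + sep
  }
  sigma <- pmax(init$sigma, sd_floor)
  trans <- init$trans
  pi0 <- init$init
  trace <- numeric(0)
  converged <- FALSE
  clamped <- FALSE
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    e <- .hmm_estep(x, mu, sigma, trans, pi0, block_start)
    trace <- c(trace, e$loglik)
    gamma <- e$gamma
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(e$loglik - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    # M-step
    gs <- colSums(gamma)
    mu <- colSums(gamma * x) / gs
    sig2 <- colSums(gamma * (outer(x, mu, "-"))^2) / gs
    sigma <- sqrt(sig2)
    if (any(sigma < sd_floor)) {
      sigma <- pmax(sigma, sd_floor)
      clamped <- TRUE
    }
    trans <- e$xi_sum / rowSums(e$xi_sum)
    trans[trans < 1e-12] <- 1e-12
    trans <- trans / rowSums(trans)
    pi0 <- e$gamma_first / sum(e$gamma_first)
  }
  params <- structure(list(rho = init$rho, mu = mu, sigma = sigma,
                           trans = trans, init = pi0),
                      class = "HmmParams")
  states <- if (decode == "viterbi") {
    as.integer(.hmm_viterbi(x, mu, sigma, trans, pi0, block_start))
  } else {
    ifelse(gamma[, 2L] > gamma[, 1L], 2L, 1L)
  }
  structure(list(params = params, states = states, loglik = trace,
                 converged = converged, sigma_clamped = clamped,
                 decode = decode),
            class = "HmmFit")
}

#' @export
print.HmmFit <- function(x, ...) {
  cat(sprintf(
    "HmmFit: means (%.4f, %.4f), sds (%.4f, %.4f), %d iterations%s\n",
    x$params$mu[1L], x$params$mu[2L], x$params$sigma[1L], x$params$sigma[2L],
    length(x$loglik), if (x$converged) " (converged)" else ""))
  invisible(x)
}

# stationary distribution of a 2x2 transition matrix
stationary_2state <- function(trans) {
  p12 <- trans[1L, 2L]
  p21 <- trans[2L, 1L]
  if (p12 + p21 <= 0) return(c(0.5, 0.5))
  c(p21, p12) / (p12 + p21)
}

#' Classify unaltered variables from a fitted HMM
#'
#' Variables decoded into the state whose fitted mean is closest to zero
#' are classified as unaltered.  If the two means are equally close to
#' zero, the state with the larger stationary probability is taken as
#' unaltered (unaltered variables are assumed to be the majority).
#'
#' @param fit an [fit_hmm()] result.
#' @return Logical mask, `TRUE` for variables classified unaltered.
#' @export
unaltered_mask <- function(fit) {
  stopifnot(inherits(fit, "HmmFit"))
  am <- abs(fit$params$mu)
  if (am[1L] != am[2L]) {
    null_state <- which.min(am)
  } else {
    null_state <- which.max(stationary_2state(fit$params$trans))
  }
  fit$states == null_state
}

#' HMM-assisted invariant quantile normalization
#'
#' The full pipeline for normalizing skewed experiments with region
#' structure: (1) standard quantile normalization with the all-variable
#' reference; (2) M-values of the normalized data; (3) a two-state Gaussian
#' HMM on the ordered M-track, classifying variables in the near-zero-mean
#' state as unaltered; (4) quantile normalization of the *original* data
#' using only the unaltered variables as reference (all variables are
#' mapped).  Because the reference-set quantile map is non-linear, the
#' correction is not a constant shift of the M-values.
#'
#' @param m an `IntensityMatrix` on the log2 scale (already standard
#'   pre-processed; the pipeline applies its own quantile steps).
#' @param design a [group_design()].
#' @param rho guessed altered fraction for the HMM initialization.
#' @param region_length expected altered-region length (variables).
#' @param decode `"viterbi"` (default) or `"posterior"`.
#' @param tol,max_iter EM controls, see [fit_hmm()].
#' @return A `NormalizationResult` (method `"hmm"`) with two extra fields:
#'   `fit` (the `HmmFit`) and `mask` (the unaltered classification).
#' @export
hmm_normalize <- function(m, design, rho = 0.1, region_length = 50,
                          decode = "viterbi", tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("expects log2-scale data")
  check_design(m, design)
  std <- quantile_normalize(m)
  track <- m_values(std$matrix, design)
  if (sd(track$m) == 0) {
    # arms indistinguishable: nothing to segment, all variables unaltered
    fit <- NULL
    mask <- rep.int(TRUE, length(track$m))
  } else {
    fit <- fit_hmm(track, init_hmm(track, rho, region_length),
                   tol = tol, max_iter = max_iter, decode = decode)
    mask <- unaltered_mask(fit)
  }
  if (sum(mask) < 2L)
    stop("fewer than 2 variables classified unaltered; cannot normalize")
  out <- quantile_normalize(m, ref = mask, method = "hmm")
  out$fit <- fit
  out$mask <- mask
  out
}
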