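# shared fixture builders (all data generated in code)

log2_matrix <- function(values, ...) {
  intensity_matrix(as.matrix(values), scale = "log2", ...)
}

balanced_design <- function(k_t, k_r = k_t) {
  group_design(c(paste0("T", seq_len(k_t)), paste0("R", seq_len(k_r))),
               rep(c("treatment", "reference"), c(k_t, k_r)))
}

m_track <- function(x, blocks = NULL) {
  if (is.null(blocks)) blocks <- rep.int(1L, length(x))
  structure(list(m = as.numeric(x), blocks = as.integer(blocks),
                 ids = paste0("v", seq_along(x))),
            class = "MValueTrack")
}

# small simulated experiment with defaults tuned for fast unit tests
quick_sim <- function(n = 5000, k = 2, alpha = 0.2, m = 50, delta = 2,
                      seed = 1, vp_seed = seed + 1000) {
  vp <- synth_variable_params(n, seed = vp_seed)
  simulate_experiment(simulation_config(n, k, alpha, m, delta, seed = seed),
                      vp)
}

# independent evaluation of the piecewise-linear quantile map used as an
# oracle in normalization tests: explicit search of the bracketing segment
map_oracle <- function(knots_x, knots_y, x) {
  k <- length(knots_x)
  vapply(x, function(v) {
    if (v <= knots_x[1L]) {
      s <- (knots_y[2L] - knots_y[1L]) / (knots_x[2L] - knots_x[1L])
      return(knots_y[1L] + s * (v - knots_x[1L]))
    }
    if (v >= knots_x[k]) {
      s <- (knots_y[k] - knots_y[k - 1L]) / (knots_x[k] - knots_x[k - 1L])
      return(knots_y[k] + s * (v - knots_x[k]))
    }
    i <- max(which(knots_x <= v))
    w <- (v - knots_x[i]) / (knots_x[i + 1L] - knots_x[i])
    knots_y[i] + w * (knots_y[i + 1L] - knots_y[i])
  }, 0)
}
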