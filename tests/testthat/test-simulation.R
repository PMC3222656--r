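test_that("synthetic variable parameters are reproducible and plausible", {
  a <- synth_variable_params(500, seed = 7)
  b <- synth_variable_params(500, seed = 7)
  expect_identical(a, b)
  expect_error(synth_variable_params(0), "positive count")
  expect_error(synth_variable_params(10, cv_range = c(0.3, 0.1)),
               "cv_range")

  big <- synth_variable_params(10000, seed = 8)
  expect_true(all(big$mu > 0))
  expect_true(all(big$sigma > 0))
  cv <- big$sigma / big$mu
  expect_gt(median(cv), 0.13)  # Uniform(0.05, 0.25) median is 0.15
  expect_lt(median(cv), 0.17)
})

test_that("parameter estimation shrinks variances per the regularized formula", {
  # variable with zero sample variance, local prior variance 1, nu0 = 10,
  # 2 samples: sigma2 = (10 * 1 + 1 * 0) / (10 + 2 - 2) = 1
  set.seed(15)
  n <- 41
  centers <- seq(100, 300, length.out = n)
  vals <- cbind(s1 = centers - 1, s2 = centers + 1)  # s2 = 2 for all rows
  m <- intensity_matrix(vals, scale = "raw")
  vp <- suppressWarnings(estimate_variable_params(m, prior_df = 10,
                                                  window = 5))
  # only variables above the median average intensity are kept
  expect_equal(length(vp$mu), sum(centers > median(centers)))
  expect_equal(vp$mu, centers[centers > median(centers)],
               ignore_attr = TRUE)
  # all sample variances equal 2, so the prior is 2 and
  # sigma2 = (10 * 2 + 1 * 2) / 10 = 2.2 for every variable
  expect_equal(vp$sigma, rep(sqrt(2.2), length(vp$sigma)),
               tolerance = 1e-12)

  # two identical samples: all s2 = 0, prior 0, shrunken variance 0
  m0 <- intensity_matrix(cbind(s1 = centers, s2 = centers), scale = "raw")
  vp0 <- suppressWarnings(estimate_variable_params(m0, window = 5))
  expect_equal(vp0$sigma, rep(0, length(vp0$sigma)))

  expect_error(
    estimate_variable_params(
      intensity_matrix(cbind(s1 = centers), scale = "raw")),
    "at least 2")
  expect_warning(estimate_variable_params(m, window = 1000), "window")
})

test_that("shrunken variance reproduces the formula on a hand-built case", {
  # 11 variables with sample variance 1 each (values center +/- sqrt(0.5));
  # the 5 above the median average survive, the window covers all of them,
  # so the local prior is 1 and sigma2 = (nu0 * 1 + (2-1) * 1) / nu0
  centers <- seq(200, 220, length.out = 11)
  vals <- cbind(s1 = centers - sqrt(0.5), s2 = centers + sqrt(0.5))
  m <- intensity_matrix(vals, scale = "raw")
  vp <- suppressWarnings(
    estimate_variable_params(m, prior_df = 10, window = 11))
  expect_equal(length(vp$mu), 5L)
  expect_equal(vp$sigma^2, rep(11 / 10, 5), tolerance = 1e-12)
})

test_that("regions are equally spaced with the exact altered count", {
  mask <- place_regions(10000, 0.05, 50)
  expect_equal(sum(mask), 500L)
  runs <- rle(mask)
  expect_equal(sum(runs$values), 10L)
  expect_true(all(runs$lengths[runs$values] == 50L))
  starts <- which(mask & !c(FALSE, mask[-length(mask)]))
  expect_true(all(diff(starts) == 1000L))

  expect_equal(sum(place_regions(100, 0.5, 50)), 50L)
  expect_equal(sum(rle(place_regions(100, 0.5, 50))$values), 1L)
  expect_false(any(place_regions(1000, 0, 50)))
  # regions longer than half the spacing still fit inside the track
  for (n in c(100, 150, 1000)) {
    for (alpha in c(0.3, 0.5)) {
      for (m in c(49, 50, 60)) {
        mask <- place_regions(n, alpha, m)
        r <- round(alpha * n / m)
        expect_equal(sum(mask), as.integer(r * m))
        expect_length(mask, n)  # runs never spill past the track end
      }
    }
  }
  expect_error(place_regions(100, 0.6, 50), "alpha")
})

test_that("truth bookkeeping is exact over a parameter grid", {
  for (n in c(1000, 10000)) {
    for (alpha in c(0, 0.05, 0.15, 0.25)) {
      for (m in c(10, 50)) {
        mask <- place_regions(n, alpha, m)
        expect_identical(sum(mask), as.integer(round(alpha * n / m) * m))
      }
    }
  }
})

test_that("simulated experiments are bit-identical under the same seed", {
  vp <- synth_variable_params(2000, seed = 2)
  cfg <- simulation_config(2000, 3, 0.2, 50, 1.5, seed = 9)
  s1 <- simulate_experiment(cfg, vp)
  s2 <- simulate_experiment(cfg, vp)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
})

test_that("altered variables carry their configured effect size", {
  # nearly noise-free parameters: observed M approximates log2(delta)
  vp <- synth_variable_params(3000, seed = 4, cv_range = c(1e-4, 2e-4))
  sim <- simulate_experiment(
    simulation_config(3000, 16, 0.2, 50, 2, seed = 10), vp)
  mv <- m_values(to_log2(sim$matrix), sim$design)
  expect_equal(mean(mv$m[sim$truth]), 1, tolerance = 0.05)
  expect_equal(mean(abs(mv$m[!sim$truth])), 0, tolerance = 0.05)
  expect_equal(sim$true_log_ratio[sim$truth], rep(1, sum(sim$truth)))
  expect_equal(sim$true_log_ratio[!sim$truth], rep(0, sum(!sim$truth)))
})

test_that("null experiments have mean M near zero", {
  sim <- quick_sim(n = 10000, k = 4, alpha = 0, seed = 20)
  mv <- m_values(to_log2(sim$matrix), sim$design)$m
  expect_lt(abs(mean(mv)), 3 * sd(mv) / sqrt(length(mv)))
  expect_false(any(sim$truth))
})

test_that("several effect sizes cycle over regions in equal shares", {
  vp <- synth_variable_params(30000, seed = 6)
  sim <- simulate_experiment(
    simulation_config(30000, 2, 0.25, 50, c(1.5, 2, 4), seed = 12), vp)
  starts <- which(sim$truth & !c(FALSE, sim$truth[-30000]))
  region_delta <- sim$delta[starts]
  counts <- table(region_delta)
  expect_equal(length(counts), 3L)
  expect_true(max(counts) - min(counts) <= 1)
})

test_that("standardized reference residuals are consistent with N(0,1)", {
  vp <- synth_variable_params(10000, seed = 14)
  sim <- simulate_experiment(
    simulation_config(10000, 2, 0, 50, 2, seed = 13), vp)
  ref_cols <- arm <- sim$design$sample_id[sim$design$arm == "reference"]
  z <- (sim$matrix$values[, ref_cols] - vp$mu[1:10000]) / vp$sigma[1:10000]
  ks <- suppressWarnings(stats::ks.test(as.vector(z), "pnorm"))
  expect_gt(ks$p.value, 0.01)
})
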