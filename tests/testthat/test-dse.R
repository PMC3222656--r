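test_that("qs-coefficient matches the quartile-skewness definition", {
  expect_equal(qs_coefficient(c(-2, -1, 0, 1, 2)), 0)
  # type-7 quartiles of (0,0,0,1,10): Q1 = 0, median = 0, Q3 = 1
  expect_equal(qs_coefficient(c(0, 0, 0, 1, 10)), 1)
  expect_error(qs_coefficient(c(5, 5, 5, 5)), "degenerate spread")
  expect_error(qs_coefficient(c(1, 2, 3)), "at least 4")
})

test_that("qs-coefficient is location/scale invariant and bounded", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 5))^ifelse(i %% 2, 1, 3)
    q <- qs_coefficient(x)
    expect_true(abs(q) <= 1)
    expect_equal(qs_coefficient(3.7 + 2.5 * x), q, tolerance = 1e-12)
  }
})

test_that("pair log-ratios are per-variable differences and antisymmetric", {
  m <- log2_matrix(cbind(a = c(1, 2, 3), b = c(1, 1, 1)))
  expect_equal(pair_log_ratios(m, "a", "a"), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(pair_log_ratios(m, "a", "b"),
               -pair_log_ratios(m, "b", "a"), ignore_attr = TRUE)
  m2 <- log2_matrix(cbind(a = c(2, 3, 4), b = c(1, 2, 3)))
  expect_equal(unname(pair_log_ratios(m2, "a", "b")), c(1, 1, 1))
  expect_error(pair_log_ratios(m, "a", "zz"), "unknown sample")
})

test_that("dependent pairing obeys the count formulas", {
  ps <- build_pairs(balanced_design(3), "dependent")
  expect_equal(sum(ps$pairs$kind == "heterogeneous"), 3L)
  expect_equal(sum(ps$pairs$kind == "homogeneous"), 2L)

  ps2 <- build_pairs(balanced_design(2), "dependent")
  expect_equal(sum(ps2$pairs$kind == "heterogeneous"), 2L)
  expect_equal(sum(ps2$pairs$kind == "homogeneous"), 2L)

  # unbalanced arms: min(n_T, n_R) het, floor(n_T/2) + floor(n_R/2) hom
  d <- group_design(c(paste0("T", 1:5), paste0("R", 1:3)),
                    rep(c("treatment", "reference"), c(5, 3)))
  ps3 <- build_pairs(d, "dependent")
  expect_equal(sum(ps3$pairs$kind == "heterogeneous"), 3L)
  expect_equal(sum(ps3$pairs$kind == "homogeneous"), 2L + 1L)

  # no sample twice within each list
  het <- ps3$pairs[ps3$pairs$kind == "heterogeneous", ]
  hom <- ps3$pairs[ps3$pairs$kind == "homogeneous", ]
  expect_false(anyDuplicated(c(het$sample_a, het$sample_b)) > 0)
  expect_false(anyDuplicated(c(hom$sample_a, hom$sample_b)) > 0)
})

test_that("independent pairing keeps the lists disjoint and needs 4 per arm", {
  expect_error(build_pairs(balanced_design(2), "independent"),
               "independent")
  ps <- build_pairs(balanced_design(4), "independent")
  het <- ps$pairs[ps$pairs$kind == "heterogeneous", ]
  hom <- ps$pairs[ps$pairs$kind == "homogeneous", ]
  expect_equal(nrow(het), 2L)
  expect_equal(nrow(hom), 2L)
  expect_length(intersect(c(het$sample_a, het$sample_b),
                          c(hom$sample_a, hom$sample_b)), 0L)
})

test_that("heterogeneous pairs couple arms; homogeneous pairs stay within arms", {
  d <- balanced_design(4)
  arm_of <- setNames(d$arm, d$sample_id)
  for (variant in c("dependent", "independent")) {
    ps <- build_pairs(d, variant)
    for (i in seq_len(nrow(ps$pairs))) {
      p <- ps$pairs[i, ]
      expect_true(p$sample_a != p$sample_b)
      if (p$kind == "heterogeneous") {
        expect_true(arm_of[p$sample_a] != arm_of[p$sample_b])
      } else {
        expect_true(arm_of[p$sample_a] == arm_of[p$sample_b])
      }
    }
  }
})

test_that("Welch test agrees with the closed form at df = 2", {
  # a = (1,2), b = (3,4): equal variances of 0.5, t = -2/sqrt(0.5),
  # df = 2; with df = 2 the t CDF is F(t) = 1/2 + t / (2 * sqrt(2 + t^2))
  wt <- welch_t(c(1, 2), c(3, 4))
  t_exp <- -2 / sqrt(0.5)
  expect_equal(wt$t, t_exp, tolerance = 1e-12)
  expect_equal(wt$df, 2, tolerance = 1e-12)
  p_exp <- 2 * (0.5 + t_exp / (2 * sqrt(2 + t_exp^2)))
  expect_equal(wt$p, p_exp, tolerance = 1e-12)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(welch_t(c(0, 0), c(0, 0)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("identical qs groups give t = 0 and p = 1", {
  # with T2 = R1 = 0 the heterogeneous ratios (T1 - R1, T2 - R2) equal the
  # homogeneous ratios (T1 - T2, R1 - R2) vector by vector
  set.seed(8)
  a <- rnorm(200)
  r <- rnorm(200, sd = 2)
  m <- log2_matrix(cbind(T1 = a, T2 = 0, R1 = 0, R2 = r))
  res <- dse_test(m, balanced_design(2), pre_normalize = FALSE)
  expect_equal(res$t_statistic, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
})

test_that("arm relabelling negates heterogeneous qs-coefficients", {
  sim <- quick_sim(n = 4000, k = 3, alpha = 0.2, seed = 31)
  lm <- to_log2(sim$matrix)
  d <- sim$design
  flipped <- group_design(d$sample_id,
                          ifelse(d$arm == "treatment",
                                 "reference", "treatment"))
  r1 <- dse_test(lm, d, pre_normalize = FALSE)
  r2 <- dse_test(lm, flipped, pre_normalize = FALSE)
  expect_equal(sort(r2$qs_het), sort(-r1$qs_het), tolerance = 1e-12)
})

test_that("a strongly skewed simulated experiment is detected", {
  sim <- quick_sim(n = 20000, k = 2, alpha = 0.25, delta = 2, seed = 41)
  res <- dse_test(to_log2(sim$matrix), sim$design, "dependent",
                  pre_normalize = FALSE)
  expect_lt(res$p_value, 0.05)
  expect_gt(mean(res$qs_het), mean(res$qs_hom))
})

test_that("null p-values are approximately uniform (independent variant)", {
  vp <- synth_variable_params(10000, seed = 5)
  pv <- vapply(seq_len(1000), function(i) {
    sim <- simulate_experiment(
      simulation_config(10000, 8, 0, 50, 2, seed = 3000 + i), vp)
    dse_test(to_log2(sim$matrix), sim$design, "independent",
             pre_normalize = FALSE)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
})

test_that("pre-normalization runs standard quantile normalization first", {
  sim <- quick_sim(n = 2000, k = 2, alpha = 0, seed = 51)
  lm <- to_log2(sim$matrix)
  # pre_normalize = TRUE is exactly equivalent to normalizing explicitly
  res_pre <- dse_test(lm, sim$design, pre_normalize = TRUE)
  res_explicit <- dse_test(quantile_normalize(lm)$matrix, sim$design,
                           pre_normalize = FALSE)
  expect_equal(res_pre$qs_het, res_explicit$qs_het, tolerance = 1e-12)
  expect_equal(res_pre$qs_hom, res_explicit$qs_hom, tolerance = 1e-12)
  expect_equal(res_pre$p_value, res_explicit$p_value, tolerance = 1e-12)
  # and differs from testing the raw data
  res_raw <- dse_test(lm, sim$design, pre_normalize = FALSE)
  expect_false(isTRUE(all.equal(res_raw$qs_het, res_pre$qs_het)))
})
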