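test_that("pooled statistics match hand arithmetic", {
  # cases (2,4), controls (1,3): y = 3-2 = 1, s2 = (1+1+1+1)/2 = 2, v = 1
  st <- study_dataset(matrix(c(2, 4, 1, 3), 1), c("case", "case", "control", "control"))
  ps <- pooled_stats(st)
  expect_equal(unname(ps$y), 1)
  expect_equal(unname(ps$s2), 2)
  expect_equal(ps$v, 1)
  expect_equal(ps$df_resid, 2)

  # constant groups: zero variance detected as degenerate only when universal
  st2 <- study_dataset(matrix(c(1, 1, 1, 0, 0, 0, 2, 1, 3, 0, 1, 2), 2,
                              byrow = TRUE),
                       rep(c("case", "control"), each = 3))
  ps2 <- pooled_stats(st2)
  expect_equal(unname(ps2$y[1]), 1)
  expect_equal(unname(ps2$s2[1]), 0)
  expect_equal(ps2$v, 2 / 3)
  expect_equal(ps2$df_resid, 4)
  st3 <- study_dataset(matrix(rep(c(1, 1, 1, 0, 0, 0), 2), 2, byrow = TRUE),
                       rep(c("case", "control"), each = 3))
  expect_error(pooled_stats(st3), "degenerate")
})

test_that("pooled statistics are invariant to replicate order within groups", {
  set.seed(3)
  x <- matrix(rnorm(40), 4, 10)
  g <- rep(c("case", "control"), each = 5)
  a <- pooled_stats(study_dataset(x, g))
  perm <- c(sample(1:5), sample(6:10))
  b <- pooled_stats(study_dataset(x[, perm], g[perm]))
  expect_equal(a$y, b$y)
  expect_equal(a$s2, b$s2)
})

test_that("moderated t interpolates between pooled t and prior-only limits", {
  st <- study_dataset(matrix(rnorm(5 * 6, sd = 0.4), 5, 6),
                      rep(c("case", "control"), each = 3))
  ps <- pooled_stats(st)
  # hand example: y=1, s2=2, v=1, n0=4, s0^2=2 -> s2_tilde=2, t = 1/sqrt(2)
  hand <- structure(list(y = 1, s2 = 2, v = 1, df_resid = 4),
                    class = "pooled_stats")
  expect_equal(moderated_t(hand, n0 = 4, s0_sq = 2), 1 / sqrt(2))
  # n0 = 0: ordinary two-sample pooled t
  expect_equal(moderated_t(ps, n0 = 0, s0_sq = 1),
               ps$y / sqrt(ps$v * ps$s2))
  # n0 = Inf: all variances collapse to s0^2
  expect_equal(moderated_t(ps, n0 = Inf, s0_sq = 0.1),
               ps$y / sqrt(ps$v * 0.1))
  # linearity in y
  ps2 <- ps
  ps2$y <- 2 * ps$y
  expect_equal(moderated_t(ps2, 4, 0.02), 2 * moderated_t(ps, 4, 0.02))
})

test_that("variance prior estimation recovers the generating parameters", {
  set.seed(11)
  G <- 100000
  s2_gene <- 4 * 0.02 / rchisq(G, 4)          # sigma^2 from the prior
  s2 <- s2_gene * rchisq(G, 4) / 4            # sampling given sigma^2
  vp <- fit_variance_prior(s2, df_resid = 4)
  expect_lt(abs(vp$n0 - 4) / 4, 0.05)
  expect_lt(abs(vp$s0_sq - 0.02) / 0.02, 0.05)
  # scale equivariance
  vp2 <- fit_variance_prior(s2 * 10, df_resid = 4)
  expect_equal(vp2$n0, vp$n0, tolerance = 1e-8)
  expect_equal(vp2$s0_sq, vp$s0_sq * 10, tolerance = 1e-8)
})

test_that("identical sample variances take the infinite-prior branch", {
  vp <- fit_variance_prior(rep(0.5, 200), df_resid = 4)
  expect_true(is.infinite(vp$n0))
  hand <- structure(list(y = rep(1, 3), s2 = c(0.1, 0.5, 0.9), v = 1,
                         df_resid = 4), class = "pooled_stats")
  expect_equal(moderated_t(hand, vp$n0, vp$s0_sq), rep(1 / sqrt(0.5), 3),
               tolerance = 1e-6)
  expect_error(fit_variance_prior(rep(1, 5), 4), "too few genes")
})

test_that("null and alternative densities integrate to one and collapse at w = 0", {
  for (cc in c(1, 2, 5)) {
    z <- integrate(function(t) exp(alt_logdensity(t, df = 6, scale_alt = cc)),
                   -Inf, Inf, rel.tol = 1e-9)
    expect_lt(abs(z$value - 1), 1e-6)
  }
  tt <- seq(-8, 8, length.out = 41)
  expect_equal(alt_logdensity(tt, 6, 1), null_logdensity(tt, 6))
  expect_equal(alt_logdensity(0, 6, 2), null_logdensity(0, 6) - log(2))
})

test_that("alt/null likelihood ratio is even and increasing in |t|", {
  tt <- seq(0.1, 30, by = 0.35)
  lr <- alt_logdensity(tt, df = 8, scale_alt = 3) - null_logdensity(tt, 8)
  expect_true(all(diff(lr) > 0))
  expect_equal(
    alt_logdensity(-tt, 8, 3) - null_logdensity(-tt, 8), lr
  )
})

test_that("scale-mixture estimation of w finds the null and signal regimes", {
  set.seed(5)
  # pure null: the fitted mixture density collapses onto the null density
  # (p0 and c are only weakly identified on null data, so compare densities,
  # not the individual parameters)
  t_null <- rt(20000, df = 6)
  est <- estimate_w(t_null, df = 6, v = 1)
  grid <- seq(-8, 8, length.out = 200)
  mix <- est$p0 * dt(grid, 6) +
    (1 - est$p0) * dt(grid / est$scale, 6) / est$scale
  expect_lt(max(abs(mix - dt(grid, 6))), 0.01)
  expect_lt(est$scale, 2)
  # 10% of genes from 3 * t6
  t_mix <- c(3 * rt(5000, 6), rt(45000, 6))
  est2 <- estimate_w(t_mix, df = 6, v = 1)
  expect_lt(abs(est2$scale - 3) / 3, 0.1)
  expect_error(estimate_w(rt(20, 6), 6, 1), "too few")
})

test_that("a supplied w bypasses estimation and sets the alternative scale", {
  fx <- small_sim_tstat(G = 400, D = 2, seed = 2)
  ms <- fx$sim$data
  ts <- moderate_studies(ms, w = c(3, 8))
  v <- 2 / 3
  expect_equal(ts$scale_alt, sqrt(1 + c(3, 8) / v))
  ts2 <- moderate_studies(ms, w = setNames(c(5), "study2"), n0 = 4,
                          s0_sq = 0.02)
  expect_equal(ts2$scale_alt[2], sqrt(1 + 5 / v))
})

test_that("null genes from the hierarchical model yield t distributed as t_df", {
  spec <- preset_simulation(1, seed = 1)
  sim <- simulate_model_based(spec)
  ts <- moderate_studies(sim$data, w = spec$w0^2)  # n0, s0 estimated
  null1 <- sim$truth_a[, 1] == 0
  ks <- suppressWarnings(ks.test(ts$t[null1, 1], pt, df = ts$df[1]))
  expect_gt(ks$p.value, 0.01)
})
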