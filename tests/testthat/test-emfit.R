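test_that("gene_class_loglik matches direct scalar evaluation", {
  # D = 1, q = 0.3: log(0.3 f1 + 0.7 f0)
  t <- 1.7
  f1 <- exp(alt_logdensity(t, 6, 3))
  f0 <- exp(null_logdensity(t, 6))
  expect_equal(gene_class_loglik(t, 0.3, 6, 3), log(0.3 * f1 + 0.7 * f0))
  # densities collapse when scale_alt = 1
  expect_equal(gene_class_loglik(c(1, -2), c(0.5, 0.2), 6, 1),
               sum(null_logdensity(c(1, -2), 6)))
  # monotone in q when f1(t) > f0(t) (large |t|)
  vals <- vapply(c(0.2, 0.5, 0.8),
                 function(q) gene_class_loglik(4, q, 6, 3), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("E-step posteriors and likelihood equal exhaustive enumeration", {
  cases <- expand.grid(G = c(3, 6), D = c(1, 2, 4), K = 1:3)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ts <- make_tstat(cs$G, cs$D, df = 5, scale_alt = 2.5, seed = i)
    model <- random_model(cs$K, cs$D, seed = i + 100)
    got <- e_step(ts, model)
    want <- enum_oracle(ts, model)
    expect_equal(got$class_post, want$class_post, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$diff_post, want$diff_post, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_equal(log_likelihood(ts, model), want$loglik, tolerance = 1e-10)
    # rows normalize; decomposition identity holds by construction
    expect_equal(rowSums(got$class_post), rep(1, cs$G), tolerance = 1e-10)
    recon <- matrix(0, cs$G, cs$D)
    for (k in seq_len(cs$K)) {
      recon <- recon + got$class_post[, k] *
        matrix(got$within_class_diff[, k, ], cs$G, cs$D)
    }
    expect_equal(recon, unname(got$diff_post), tolerance = 1e-12)
  }
})

test_that("single-class E-step collapses to the per-study mixture posterior", {
  ts <- make_tstat(8, 3, df = 7, scale_alt = 2, seed = 2)
  model <- motif_model(1, matrix(c(0.1, 0.4, 0.7), 1))
  got <- e_step(ts, model)
  expect_equal(unname(got$class_post[, 1]), rep(1, 8))
  for (d in 1:3) {
    f1 <- exp(alt_logdensity(ts$t[, d], 7, 2))
    f0 <- exp(null_logdensity(ts$t[, d], 7))
    q <- model$Q[1, d]
    expect_equal(unname(got$diff_post[, d]),
                 unname(q * f1 / (q * f1 + (1 - q) * f0)),
                 tolerance = 1e-12)
  }
})

test_that("M-step applies the posterior-mode pseudocounts", {
  # all mass in class 1 with certain differential states: q = (G+1)/(G+2)
  G <- 40
  post <- structure(list(
    class_post = cbind(rep(1, G), 0),
    within_class_diff = array(1, dim = c(G, 2, 3))
  ), class = "posterior_summary")
  m <- m_step(post)
  expect_equal(unname(m$Q[1, ]), rep((G + 1) / (G + 2), 3))
  expect_equal(unname(m$Q[2, ]), rep(1 / 2, 3))   # empty class: prior mode
  expect_equal(m$pi, c(G + 1, 1) / (G + 2))
  # no data at all: pure prior mode
  m0 <- m_step(structure(list(
    class_post = matrix(numeric(0), 0, 2),
    within_class_diff = array(0, dim = c(0, 2, 3))
  ), class = "posterior_summary"))
  expect_equal(m0$pi, c(0.5, 0.5))
  expect_true(all(m0$Q == 0.5))
})

test_that("one EM step never decreases the MAP objective", {
  for (i in 1:25) {
    ts <- make_tstat(G = 30, D = 3, df = 6, scale_alt = 2.5, seed = i)
    model <- random_model(K = 1 + i %% 3, D = 3, seed = i + 50)
    before <- log_posterior(ts, model)
    after <- log_posterior(ts, m_step(e_step(ts, model)))
    expect_gte(after, before - 1e-8)
  }
})

test_that("objectives are invariant under motif label permutation", {
  ts <- make_tstat(10, 3, seed = 4)
  model <- random_model(3, 3, seed = 9)
  perm <- c(3, 1, 2)
  permuted <- motif_model(model$pi[perm], model$Q[perm, ])
  expect_equal(log_likelihood(ts, model), log_likelihood(ts, permuted))
  expect_equal(log_posterior(ts, model), log_posterior(ts, permuted))
})

test_that("the C++ EM step agrees with the R e_step/m_step composition", {
  ts <- make_tstat(25, 3, df = 8, scale_alt = 2, seed = 6)
  model <- random_model(2, 3, seed = 7)
  dens <- cormotif:::density_matrices(ts)
  res <- cormotif:::cm_em_cpp(dens$lf0, dens$lf1, model$pi, model$Q,
                              tol = 0, max_iter = 1,
                              1e-10, 1 - 1e-10, 1e-12)
  stepped <- m_step(e_step(ts, model))
  expect_equal(as.numeric(res$pi), stepped$pi, tolerance = 1e-12)
  expect_equal(unname(res$Q), unname(stepped$Q), tolerance = 1e-12)
  expect_equal(res$trace[1], log_posterior(ts, model), tolerance = 1e-10)
})

test_that("fitting is deterministic under a fixed seed and validates K", {
  fx <- small_sim_tstat(G = 300, D = 2, seed = 5)
  f1 <- fit_cormotif(fx$tstat, K = 2, n_starts = 3, seed = 11)
  f2 <- fit_cormotif(fx$tstat, K = 2, n_starts = 3, seed = 11)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$diff_post, f2$diff_post)
  expect_identical(f1$trace, f2$trace)
  expect_error(fit_cormotif(fx$tstat, K = 0), "K must be")
  expect_error(fit_cormotif(make_tstat(3, 2), K = 5), "number of genes")
})

test_that("EM traces are non-decreasing across random instances", {
  worst <- 0
  for (i in 1:100) {
    set.seed(i)
    G <- sample(20:60, 1)
    D <- sample(1:4, 1)
    K <- sample(1:3, 1)
    ts <- make_tstat(G, D, df = 4 + (i %% 5), scale_alt = 1.5 + (i %% 3),
                     seed = i)
    fit <- fit_cormotif(ts, K = K, n_starts = 1, seed = i, max_iter = 300)
    drops <- diff(fit$trace)
    worst <- min(worst, min(drops))
    expect_gte(min(drops), -1e-8 * max(1, abs(fit$log_posterior)))
  }
})

test_that("motifs are reported sorted by descending abundance", {
  fx <- small_sim_tstat(G = 500, D = 3, seed = 9)
  fit <- fit_cormotif(fx$tstat, K = 3, n_starts = 4, seed = 2)
  expect_true(all(diff(fit$model$pi) <= 0))
  expect_equal(sum(fit$model$pi), 1, tolerance = 1e-12)
  expect_true(all(fit$model$Q > 0 & fit$model$Q < 1))
})

test_that("joint configuration probability differs from the product of marginals iff K > 1", {
  model <- random_model(3, 4, seed = 21)
  joint <- joint_config_prob(model, rep(1, 4))
  marg <- prod(colSums(model$pi * model$Q))
  expect_gt(abs(joint - marg), 1e-6)
  one <- motif_model(1, matrix(c(0.2, 0.6, 0.3, 0.8), 1))
  expect_equal(joint_config_prob(one, rep(1, 4)),
               prod(one$Q[1, ]), tolerance = 1e-12)
})
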