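# Shared fixtures and independent oracles for the test suite.

# Small random t-statistic matrix with fixed density parameters.
make_tstat <- function(G = 6, D = 2, df = 6, scale_alt = 3, seed = 1) {
  set.seed(seed)
  tstat_matrix(matrix(rnorm(G * D, sd = 1.5), G, D),
               df = df, scale_alt = scale_alt)
}

random_model <- function(K, D, seed = 1) {
  set.seed(seed)
  pi <- rgamma(K, 1) + 0.1
  motif_model(pi / sum(pi), matrix(runif(K * D, 0.1, 0.9), K, D))
}

# Brute-force posteriors by exhaustive enumeration of the joint latent space
# (class label x all 2^D binary configurations), written directly from the
# generative model with stats::dt; independent of the package's E-step.
enum_oracle <- function(tstat, model) {
  t <- tstat$t
  G <- nrow(t)
  D <- ncol(t)
  K <- model$K
  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), D)))
  lf0 <- sapply(seq_len(D), function(d) dt(t[, d], tstat$df[d], log = TRUE))
  lf1 <- sapply(seq_len(D), function(d) {
    dt(t[, d] / tstat$scale_alt[d], tstat$df[d], log = TRUE) -
      log(tstat$scale_alt[d])
  })
  lf0 <- matrix(lf0, G, D)
  lf1 <- matrix(lf1, G, D)
  class_post <- matrix(0, G, K)
  diff_post <- matrix(0, G, D)
  loglik <- 0
  for (g in seq_len(G)) {
    w <- matrix(0, K, nrow(configs))   # joint density over (b_g = k, a_g = c)
    for (k in seq_len(K)) {
      for (ci in seq_len(nrow(configs))) {
        a <- configs[ci, ]
        w[k, ci] <- model$pi[k] * prod(
          (model$Q[k, ]^a * (1 - model$Q[k, ])^(1 - a)) *
            exp(a * lf1[g, ] + (1 - a) * lf0[g, ])
        )
      }
    }
    tot <- sum(w)
    loglik <- loglik + log(tot)
    class_post[g, ] <- rowSums(w) / tot
    for (d in seq_len(D)) {
      diff_post[g, d] <- sum(w[, configs[, d] == 1]) / tot
    }
  }
  list(class_post = class_post, diff_post = diff_post, loglik = loglik)
}

# Small simulated multi-study experiment pushed through moderation with the
# generative parameters supplied (fast; avoids per-study w estimation).
small_sim_tstat <- function(G = 600, D = 2, seed = 1) {
  spec <- sim_spec(
    patterns = c(list(rep(1, D)), list(rep(0, D))),
    counts = c(round(G * 0.1), G - round(G * 0.1)),
    seed = seed
  )
  sim <- simulate_model_based(spec)
  list(sim = sim,
       tstat = moderate_studies(sim$data, w = spec$w0^2, n0 = spec$n0,
                                s0_sq = spec$s0_sq))
}
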