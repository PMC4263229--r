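#' Construct a correlation-motif model
#'
#' A motif model is a mixture over K latent gene classes: `pi[k]` is the
#' probability that a gene belongs to class k, and `Q[k, d]` is the
#' probability that a class-k gene is differentially expressed in study d.
#' Each row of `Q` is a "correlation motif".
#'
#' @param pi K-vector of mixing proportions (summing to 1).
#' @param Q K x D matrix of motif probabilities, entries strictly in (0, 1).
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(pi, Q) {
  Q <- rbind(Q)
  pi <- as.numeric(pi)
  stopifnot(length(pi) == nrow(Q))
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(pi <= 0)) stop("all mixing proportions must be positive")
  Q[] <- pmin(pmax(Q, 1e-10), 1 - 1e-10)
  structure(list(K = length(pi), pi = pi / sum(pi), Q = Q),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> K = %d motifs, D = %d studies\n", x$K, ncol(x$Q)))
  tab <- cbind(pi = round(x$pi, 4), round(x$Q, 3))
  rownames(tab) <- paste0("motif", seq_len(x$K))
  print(tab)
  invisible(x)
}

#' Per-gene per-class collapsed log-likelihood
#'
#' For one gene with t-statistics `t_row` and one motif `q_row`, returns
#' `sum_d log(q_d f_d1(t_d) + (1 - q_d) f_d0(t_d))`, i.e. the class-conditional
#' likelihood with the binary differential states summed out, computed in log
#' space.
#'
#' @param t_row D-vector of t-statistics.
#' @param q_row D-vector of motif probabilities.
#' @param df,scale_alt Per-study density parameters (recycled to length D).
#' @return Scalar log-likelihood.
#' @export
gene_class_loglik <- function(t_row, q_row, df, scale_alt) {
  D <- length(t_row)
  df <- rep_len(df, D)
  scale_alt <- rep_len(scale_alt, D)
  out <- 0
  for (d in seq_len(D)) {
    a <- log(q_row[d]) + alt_logdensity(t_row[d], df[d], scale_alt[d])
    b <- log1p(-q_row[d]) + null_logdensity(t_row[d], df[d])
    m <- max(a, b)
    out <- out + m + log(exp(a - m) + exp(b - m))
  }
  out
}

# Vectorized E-step machinery shared by e_step()/log-objective helpers.
# Returns class_loglik (G x K), class_post (G x K), within (G x K x D),
# loglik (scalar observed-data log-likelihood).
e_step_core <- function(lf0, lf1, model) {
  G <- nrow(lf0); D <- ncol(lf0); K <- model$K
  L <- matrix(0, G, K)
  within <- array(0, dim = c(G, K, D))
  for (k in seq_len(K)) {
    A <- lf1 + rep(log(model$Q[k, ]), each = G)
    B <- lf0 + rep(log1p(-model$Q[k, ]), each = G)
    m <- pmax(A, B)
    ea <- exp(A - m)
    eb <- exp(B - m)
    L[, k] <- rowSums(m + log(ea + eb))
    within[, k, ] <- ea / (ea + eb)
  }
  lw <- L + rep(log(model$pi), each = G)
  mx <- apply(lw, 1L, max)
  zs <- exp(lw - mx)
  tot <- rowSums(zs)
  list(class_loglik = L,
       class_post = zs / tot,
       within = within,
       loglik = sum(mx + log(tot)))
}

#' E-step: posterior summaries at fixed model parameters
#'
#' Computes, for every gene, the posterior class membership
#' `Pr(b_g = k | T)`, the within-class differential posteriors
#' `Pr(a_gd = 1 | T, b_g = k)`, and their mixture, the per-study marginal
#' differential posterior `Pr(a_gd = 1 | T)` used for ranking and calls.
#'
#' @param tstat A [tstat_matrix()].
#' @param model A [motif_model()].
#' @return A list of class `posterior_summary` with `class_post` (G x K),
#'   `diff_post` (G x D), `within_class_diff` (G x K x D), `loglik`.
#' @export
e_step <- function(tstat, model) {
  dens <- density_matrices(tstat)
  core <- e_step_core(dens$lf0, dens$lf1, model)
  G <- nrow(dens$lf0); D <- ncol(dens$lf0)
  diff_post <- matrix(0, G, D, dimnames = list(tstat$gene_ids, tstat$study_ids))
  for (k in seq_len(model$K)) {
    diff_post <- diff_post +
      core$class_post[, k] * matrix(core$within[, k, ], G, D)
  }
  structure(
    list(class_post = core$class_post, diff_post = diff_post,
         within_class_diff = core$within, loglik = core$loglik),
    class = "posterior_summary"
  )
}

#' M-step: posterior-mode parameter updates
#'
#' Maximises the expected complete-data log posterior under the
#' Dirichlet(2,...,2) prior on the mixing proportions and Beta(2, 2) priors
#' on the motif entries: `pi[k] = (sum_g z[g,k] + 1) / (G + K)`,
#' `q[k,d] = (sum_g z[g,k] r[g,k,d] + 1) / (sum_g z[g,k] + 2)`.
#'
#' @param posterior A `posterior_summary` from [e_step()] (an empty model,
#'   G = 0, returns the pure prior mode: uniform pi, q = 1/2).
#' @param K Number of classes (defaults to `ncol(class_post)`).
#' @return A [motif_model()].
#' @export
m_step <- function(posterior, K = ncol(posterior$class_post)) {
  z <- posterior$class_post
  G <- nrow(z)
  D <- dim(posterior$within_class_diff)[3L]
  if (is.null(G) || G == 0L) {
    return(motif_model(rep(1 / K, K), matrix(0.5, K, D)))
  }
  Sz <- colSums(z)
  pi <- (Sz + 1) / (G + K)
  pi <- pmax(pi, 1e-12)
  pi <- pi / sum(pi)
  Q <- matrix(0, K, D)
  for (k in seq_len(K)) {
    r_k <- matrix(posterior$within_class_diff[, k, ], G, D)
    Q[k, ] <- (colSums(z[, k] * r_k) + 1) / (Sz[k] + 2)
  }
  motif_model(pi, Q)
}

#' Observed-data log-likelihood and MAP objective
#'
#' `log_likelihood` is `sum_g log sum_k pi_k exp(L[g,k])` with the latent
#' states summed out; `log_posterior` adds the log prior terms
#' `sum_k log pi_k + sum_{k,d} log(q_kd (1 - q_kd))` (constant of
#' proportionality fixed at 0). BIC uses the likelihood, never the
#' prior-inclusive objective.
#'
#' @param tstat A [tstat_matrix()].
#' @param model A [motif_model()].
#' @return Scalar.
#' @export
log_likelihood <- function(tstat, model) {
  dens <- density_matrices(tstat)
  e_step_core(dens$lf0, dens$lf1, model)$loglik
}

#' @rdname log_likelihood
#' @export
log_posterior <- function(tstat, model) {
  log_likelihood(tstat, model) + log_prior(model)
}

log_prior <- function(model) {
  sum(log(model$pi)) + sum(log(model$Q) + log1p(-model$Q))
}

# Random starting values: pi ~ symmetric Dirichlet(1), q ~ U(0.05, 0.95).
init_model <- function(K, D) {
  pi <- rgamma(K, 1)
  pi <- pi / sum(pi)
  motif_model(pmax(pi, 1e-12) / sum(pmax(pi, 1e-12)),
              matrix(runif(K * D, 0.05, 0.95), K, D))
}

#' Fit the correlation-motif model by MAP-EM
#'
#' Runs `n_starts` EM chains from random initializations (chain c is seeded
#' with `seed + c`) and keeps the chain with the highest final log posterior.
#' A class whose posterior mass drops below 1e-6 is re-initialized once per
#' chain. Reported motifs are sorted by descending mixing proportion, ties
#' broken by lexicographic order of the motif rows.
#'
#' @param tstat A [tstat_matrix()].
#' @param K Number of motifs (1 <= K <= number of genes).
#' @param n_starts Number of EM chains.
#' @param tol Relative convergence tolerance on the log posterior.
#' @param max_iter Maximum EM iterations per chain.
#' @param seed Integer seed controlling all chains.
#' @return An object of class `cormotif_fit`: `model`, `class_post`,
#'   `diff_post`, `within_class_diff`, `log_posterior`, `log_likelihood`,
#'   `n_iter`, `converged`, `trace`, `seed`, plus gene/study ids.
#' @export
fit_cormotif <- function(tstat, K, n_starts = 10L, tol = 1e-8,
                         max_iter = 2000L, seed = 1L) {
  stopifnot(inherits(tstat, "tstat_matrix"))
  G <- nrow(tstat$t)
  D <- ncol(tstat$t)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > G) stop("K must not exceed the number of genes")
  dens <- density_matrices(tstat)
  best <- NULL
  for (chain in seq_len(n_starts)) {
    set.seed(seed + chain)
    model <- init_model(K, D)
    res <- cm_em_accel_cpp(dens$lf0, dens$lf1, model$pi, model$Q,
                     tol, max_iter, 1e-10, 1 - 1e-10, 1e-12)
    if (any(res$Sz < 1e-6)) {
      # one re-initialization of emptied classes, then continue the chain
      Q <- res$Q
      empty <- which(res$Sz < 1e-6)
      Q[empty, ] <- matrix(runif(length(empty) * D, 0.05, 0.95),
                           length(empty), D)
      pi <- res$pi
      pi[empty] <- 1 / K
      pi <- pi / sum(pi)
      res2 <- cm_em_accel_cpp(dens$lf0, dens$lf1, pi, Q,
                        tol, max_iter, 1e-10, 1 - 1e-10, 1e-12)
      res2$trace <- c(res$trace, res2$trace)
      res2$n_iter <- res$n_iter + res2$n_iter
      res <- res2
    }
    if (is.null(best) || res$log_posterior > best$log_posterior) {
      best <- res
      best$chain_seed <- seed + chain
    }
  }
  model <- motif_model(best$pi, best$Q)
  ord <- do.call(order, c(list(-model$pi),
                          lapply(seq_len(D), function(d) model$Q[, d])))
  model <- motif_model(model$pi[ord], model$Q[ord, , drop = FALSE])
  post <- e_step(tstat, model)
  lp <- post$loglik + log_prior(model)
  structure(
    list(model = model,
         class_post = post$class_post,
         diff_post = post$diff_post,
         within_class_diff = post$within_class_diff,
         log_posterior = lp,
         log_likelihood = post$loglik,
         n_iter = best$n_iter,
         converged = best$converged,
         trace = c(best$trace, lp),
         seed = seed,
         gene_ids = tstat$gene_ids,
         study_ids = tstat$study_ids,
         method = "cormotif"),
    class = "cormotif_fit"
  )
}

#' @export
print.cormotif_fit <- function(x, ...) {
  cat(sprintf(
    "<cormotif_fit> K = %d motifs over %d genes x %d studies\n",
    x$model$K, length(x$gene_ids), length(x$study_ids)
  ))
  cat(sprintf("  log posterior %.2f, log likelihood %.2f, %d iterations%s\n",
              x$log_posterior, x$log_likelihood, x$n_iter,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  print(x$model)
  invisible(x)
}
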