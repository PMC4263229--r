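#' Per-study mixture baseline ("separate limma")
#'
#' Analyses each study separately under the same density machinery as the
#' motif model: this is exactly the single-class (K = 1) correlation-motif
#' fit, whose objective decomposes over studies. Gene ranking within a study
#' coincides with ranking by |t|.
#'
#' @inheritParams fit_cormotif
#' @return A `cormotif_fit` with `method = "separate_limma"`.
#' @export
fit_separate_limma <- function(tstat, n_starts = 10L, tol = 1e-8,
                               max_iter = 2000L, seed = 1L) {
  fit <- fit_cormotif(tstat, K = 1L, n_starts = n_starts, tol = tol,
                      max_iter = max_iter, seed = seed)
  fit$method <- "separate_limma"
  fit
}

#' Concordance-model baseline ("all concord")
#'
#' Assumes every gene is differential in all studies or in none: a
#' two-configuration mixture over the all-ones and all-zeros states, with a
#' Beta(2, 2) prior on the all-differential weight `p1`. The mixture weight
#' update is a closed form, so EM needs no restarts (the likelihood is
#' concave in `p1`). The per-gene posterior is shared across studies.
#'
#' @inheritParams fit_cormotif
#' @return A list of class `concord_fit` with `p1`, `posterior` (per-gene
#'   probability of being differential everywhere), `diff_post` (that
#'   posterior replicated across the D study columns), `log_likelihood`,
#'   `log_posterior`, `n_iter`, `converged`, `trace`.
#' @export
fit_all_concord <- function(tstat, tol = 1e-8, max_iter = 2000L) {
  stopifnot(inherits(tstat, "tstat_matrix"))
  dens <- density_matrices(tstat)
  L1 <- rowSums(dens$lf1)
  L0 <- rowSums(dens$lf0)
  G <- length(L1)
  p1 <- 0.5
  lp_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a <- log(p1) + L1
    b <- log1p(-p1) + L0
    m <- pmax(a, b)
    ll <- sum(m + log(exp(a - m) + exp(b - m)))
    lp <- ll + log(p1) + log1p(-p1)
    trace <- c(trace, lp)
    z1 <- exp(a - m) / (exp(a - m) + exp(b - m))
    if (iter > 1L && abs(lp - lp_old) < tol * (abs(lp_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    lp_old <- lp
    p1 <- (sum(z1) + 1) / (G + 2)
    p1 <- min(max(p1, 1e-10), 1 - 1e-10)
  }
  diff_post <- matrix(z1, G, ncol(tstat$t),
                      dimnames = list(tstat$gene_ids, tstat$study_ids))
  structure(
    list(p1 = p1, posterior = z1, diff_post = diff_post,
         log_likelihood = ll, log_posterior = lp,
         n_iter = iter, converged = converged, trace = trace,
         gene_ids = tstat$gene_ids, study_ids = tstat$study_ids,
         method = "all_concord"),
    class = "concord_fit"
  )
}

#' @export
print.concord_fit <- function(x, ...) {
  cat(sprintf(
    "<concord_fit> p(all-differential) = %.4g over %d genes x %d studies\n",
    x$p1, length(x$gene_ids), length(x$study_ids)
  ))
  invisible(x)
}

#' Saturated configuration-mixture baseline ("full motif")
#'
#' Enumerates all 2^D binary differential configurations and fits a
#' categorical mixture over them with a Dirichlet(2,...,2) prior on the
#' weights. The component densities are fixed, so the likelihood is concave
#' in the weights and a single EM chain suffices. Guarded at D <= 12: the
#' class count grows as 2^D, which is the scalability barrier the
#' correlation-motif model removes.
#'
#' @inheritParams fit_cormotif
#' @return A list of class `fullmotif_fit` with `configs` (2^D x D binary
#'   matrix), `weights`, `config_post` (G x 2^D), `diff_post` (G x D),
#'   `log_likelihood`, `log_posterior`, `n_iter`, `converged`, `trace`.
#' @export
fit_full_motif <- function(tstat, tol = 1e-8, max_iter = 2000L) {
  stopifnot(inherits(tstat, "tstat_matrix"))
  D <- ncol(tstat$t)
  if (D > 12L) {
    stop("full motif infeasible for D > 12 (2^D configuration classes); ",
         "use the correlation-motif model")
  }
  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), D)))[, D:1, drop = FALSE]
  dimnames(configs) <- NULL
  C <- 2^D
  dens <- density_matrices(tstat)
  G <- nrow(dens$lf0)
  L <- dens$lf1 %*% t(configs) + dens$lf0 %*% t(1 - configs)  # G x C
  w <- rep(1 / C, C)
  lp_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lw <- L + rep(log(w), each = G)
    m <- apply(lw, 1L, max)
    zs <- exp(lw - m)
    tot <- rowSums(zs)
    ll <- sum(m + log(tot))
    lp <- ll + sum(log(w))
    trace <- c(trace, lp)
    z <- zs / tot
    if (iter > 1L && abs(lp - lp_old) < tol * (abs(lp_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    lp_old <- lp
    w <- (colSums(z) + 1) / (G + C)
    w <- pmax(w, 1e-12)
    w <- w / sum(w)
  }
  diff_post <- z %*% configs
  dimnames(diff_post) <- list(tstat$gene_ids, tstat$study_ids)
  structure(
    list(configs = configs, weights = w, config_post = z,
         diff_post = diff_post,
         log_likelihood = ll, log_posterior = lp,
         n_iter = iter, converged = converged, trace = trace,
         gene_ids = tstat$gene_ids, study_ids = tstat$study_ids,
         method = "full_motif"),
    class = "fullmotif_fit"
  )
}

#' @export
print.fullmotif_fit <- function(x, ...) {
  cat(sprintf(
    "<fullmotif_fit> %d configuration classes over %d genes x %d studies\n",
    nrow(x$configs), length(x$gene_ids), length(x$study_ids)
  ))
  invisible(x)
}
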