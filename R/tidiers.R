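#' Tidy a correlation-motif fit
#'
#' Returns one row per motif-study pair with the motif probability and the
#' motif's mixing proportion (and implied gene count `pi * G`).
#'
#' @param x A `cormotif_fit`.
#' @param ... Unused.
#' @return A tibble with columns `motif`, `study`, `q`, `pi`, `genes`.
#' @export
tidy.cormotif_fit <- function(x, ...) {
  K <- x$model$K
  D <- ncol(x$model$Q)
  G <- length(x$gene_ids)
  tibble::tibble(
    motif = rep(seq_len(K), each = D),
    study = rep(x$study_ids, K),
    q = as.vector(t(x$model$Q)),
    pi = rep(x$model$pi, each = D),
    genes = rep(x$model$pi * G, each = D)
  )
}

#' @rdname tidy.cormotif_fit
#' @export
glance.cormotif_fit <- function(x, ...) {
  tibble::tibble(
    K = x$model$K,
    log_likelihood = x$log_likelihood,
    log_posterior = x$log_posterior,
    bic = bic_cormotif(x),
    n_iter = x$n_iter,
    converged = x$converged,
    seed = x$seed
  )
}

#' Tidy a BIC scan over the motif number
#'
#' @param x A `cormotif_scan`.
#' @param ... Unused.
#' @return A tibble with one row per K: `K`, `bic`, `log_likelihood`,
#'   `converged`, `best` flag.
#' @export
tidy.cormotif_scan <- function(x, ...) {
  ll <- vapply(x$fits, function(f) {
    if (is.null(f)) NA_real_ else f$log_likelihood
  }, numeric(1))
  conv <- vapply(x$fits, function(f) {
    if (is.null(f)) NA else isTRUE(f$converged)
  }, logical(1))
  tibble::tibble(
    K = x$k_grid, bic = x$bic, log_likelihood = ll,
    converged = conv, best = x$k_grid == x$best_k
  )
}

#' @rdname tidy.cormotif_scan
#' @export
glance.cormotif_scan <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, min_bic = min(x$bic, na.rm = TRUE),
                 n_models = length(x$k_grid), seed = x$seed)
}

#' Per-gene differential posteriors as a tibble
#'
#' @param fit A fitted object carrying a `diff_post` matrix (`cormotif_fit`,
#'   `concord_fit` or `fullmotif_fit`).
#' @return A long tibble with columns `gene_id`, `study`, `posterior`.
#' @export
posterior_tbl <- function(fit) {
  dp <- fit$diff_post
  tibble::tibble(
    gene_id = rep(fit$gene_ids, times = ncol(dp)),
    study = rep(fit$study_ids, each = nrow(dp)),
    posterior = as.vector(dp)
  )
}

#' Confusion table as a tibble
#'
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return A long tibble with `called`, `true`, `n`.
#' @export
tidy.confusion_table <- function(x, ...) {
  counts <- x$counts
  tibble::tibble(
    called = rep(rownames(counts), times = ncol(counts)),
    true = rep(colnames(counts), each = nrow(counts)),
    n = as.integer(counts)
  )
}
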