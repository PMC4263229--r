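#' Bayesian information criterion for a motif fit
#'
#' `BIC = -2 logL + p log(G)` with `p = (K - 1) + K * D` free parameters
#' (mixing proportions on the simplex plus motif entries) and genes as the
#' independent sampling units. The observed-data log-likelihood is used,
#' never the prior-inclusive MAP objective.
#'
#' @param fit A `cormotif_fit`.
#' @param G Number of genes.
#' @return Scalar BIC; smaller is better.
#' @export
bic_cormotif <- function(fit, G = length(fit$gene_ids)) {
  K <- fit$model$K
  D <- ncol(fit$model$Q)
  p <- (K - 1) + K * D
  -2 * fit$log_likelihood + p * log(G)
}

#' Select the motif number by a BIC scan over K
#'
#' Fits the correlation-motif model for every K in the grid (each K uses the
#' same seed policy, so the scan is reproducible) and selects the K with
#' minimal BIC, ties broken toward smaller K. A fit failure for one K is
#' recorded without aborting the other K.
#'
#' @param tstat A [tstat_matrix()].
#' @param k_grid Integer grid of candidate motif numbers; defaults to
#'   `1:min(2^D, 10)`.
#' @inheritParams fit_cormotif
#' @return An object of class `cormotif_scan`: `k_grid`, `fits`, `bic`,
#'   `best_k`, `best_fit`, `errors`.
#' @export
scan_cormotif <- function(tstat, k_grid = NULL, n_starts = 10L, tol = 1e-8,
                          max_iter = 2000L, seed = 1L) {
  D <- ncol(tstat$t)
  if (is.null(k_grid)) k_grid <- seq_len(min(2^D, 10))
  k_grid <- as.integer(k_grid)
  stopifnot(length(k_grid) >= 1L, all(k_grid >= 1L))
  fits <- vector("list", length(k_grid))
  errors <- vector("list", length(k_grid))
  bic <- rep(NA_real_, length(k_grid))
  for (i in seq_along(k_grid)) {
    res <- tryCatch(
      fit_cormotif(tstat, K = k_grid[i], n_starts = n_starts, tol = tol,
                   max_iter = max_iter, seed = seed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[i]] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      bic[i] <- bic_cormotif(res)
    }
  }
  if (all(is.na(bic))) stop("every K in the grid failed to fit")
  best_i <- which(bic == min(bic, na.rm = TRUE))[1L]  # ties -> smaller K
  structure(
    list(k_grid = k_grid, fits = fits, bic = bic,
         best_k = k_grid[best_i], best_fit = fits[[best_i]], errors = errors,
         seed = seed),
    class = "cormotif_scan"
  )
}

#' @export
print.cormotif_scan <- function(x, ...) {
  cat(sprintf("<cormotif_scan> K in {%s}; best K = %d by BIC\n",
              paste(x$k_grid, collapse = ", "), x$best_k))
  print(data.frame(K = x$k_grid, BIC = round(x$bic, 2)), row.names = FALSE)
  invisible(x)
}
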