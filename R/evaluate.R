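#' Rank genes within one study by differential posterior
#'
#' Orders genes by descending posterior probability of differential
#' expression in the chosen study; ties are broken by descending |t| and then
#' by gene id (stable).
#'
#' @param diff_post G x D matrix of per-study differential posteriors (or a
#'   fitted object with a `diff_post` element).
#' @param study Study index (column).
#' @param t Optional G x D t-statistic matrix for tie-breaking.
#' @param gene_ids Optional gene ids for the final tie-break; defaults to row
#'   names.
#' @return Integer permutation of gene indices (best first).
#' @export
rank_genes <- function(diff_post, study = 1L, t = NULL, gene_ids = NULL) {
  if (is.list(diff_post) && !is.null(diff_post$diff_post)) {
    diff_post <- diff_post$diff_post
  }
  p <- diff_post[, study]
  if (is.null(gene_ids)) gene_ids <- rownames(diff_post)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%09d", seq_along(p))
  tt <- if (is.null(t)) rep(0, length(p)) else abs(t[, study])
  order(-p, -tt, gene_ids)
}

#' Binary differential calls from posteriors
#'
#' A gene is called differential in a study when its posterior strictly
#' exceeds the cutoff (a posterior exactly at the cutoff is called
#' non-differential). The default cutoff is 0.5.
#'
#' @param diff_post G x D posterior matrix (or fitted object carrying one).
#' @param cutoff Posterior cutoff in (0, 1).
#' @return G x D binary matrix of calls.
#' @export
call_differential <- function(diff_post, cutoff = 0.5) {
  if (is.list(diff_post) && !is.null(diff_post$diff_post)) {
    diff_post <- diff_post$diff_post
  }
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  (diff_post > cutoff) + 0
}

#' True-positive curve for a ranked gene list
#'
#' `TP(r)` counts the truly differential genes among the top r genes of the
#' ranking, for r = 1, ..., r_max.
#'
#' @param ranking Integer permutation of gene indices (e.g. [rank_genes()]).
#' @param truth Binary vector of true differential states (one study).
#' @param r_max Largest rank evaluated (defaults to all genes).
#' @return Integer vector of length `r_max`.
#' @export
tp_curve <- function(ranking, truth, r_max = length(ranking)) {
  stopifnot(length(ranking) == length(truth),
            all(sort(ranking) == seq_along(truth)))
  cumsum(truth[ranking] != 0)[seq_len(r_max)]
}

#' Configuration confusion matrix
#'
#' Cross-tabulates true differential configurations (columns) against called
#' configurations (rows). A gene whose call vector exactly matches one of the
#' true patterns is counted in that row; any other call vector falls into the
#' `"other"` row. Column sums therefore equal the true gene counts per
#' pattern.
#'
#' @param calls G x D binary call matrix (e.g. [call_differential()]).
#' @param truth A `sim_data` object, or a list with `truth_a` and
#'   `truth_pattern`.
#' @param patterns Optional list of the true patterns; defaults to the
#'   patterns stored in `truth$spec`.
#' @return An object of class `confusion_table` with a `counts` matrix
#'   (`length(patterns) + 1` rows) and the pattern list.
#' @export
confusion_table <- function(calls, truth, patterns = NULL) {
  if (is.null(patterns)) patterns <- truth$spec$patterns
  stopifnot(nrow(calls) == nrow(truth$truth_a),
            ncol(calls) == ncol(truth$truth_a))
  key <- vapply(patterns, paste, character(1), collapse = "")
  call_key <- apply(calls, 1L, paste, collapse = "")
  row_idx <- match(call_key, key, nomatch = length(key) + 1L)
  col_idx <- truth$truth_pattern
  counts <- matrix(0L, length(key) + 1L, length(key))
  for (g in seq_along(row_idx)) {
    counts[row_idx[g], col_idx[g]] <- counts[row_idx[g], col_idx[g]] + 1L
  }
  lab <- paste0("[", vapply(patterns, paste, character(1), collapse = ","), "]")
  dimnames(counts) <- list(called = c(lab, "other"), true = lab)
  structure(list(counts = counts, patterns = patterns),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> called configuration (rows) vs truth (columns)\n")
  print(x$counts)
  invisible(x)
}

#' Sum of diagonal entries of a confusion table
#'
#' The number of genes whose full called configuration equals their true
#' pattern, totalled over all true patterns.
#'
#' @param x A [confusion_table()].
#' @return Integer count.
#' @export
diag_total <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  sum(diag(x$counts[seq_along(x$patterns), , drop = FALSE]))
}

#' Prior probability of a differential configuration under a motif model
#'
#' `Pr(a_g = config) = sum_k pi_k prod_d q_kd^a_d (1 - q_kd)^(1 - a_d)`.
#' Because the class label is shared across studies, this generally differs
#' from the product of the per-study marginals (they agree only at K = 1):
#' the motif mixture is what encodes cross-study correlation.
#'
#' @param model A [motif_model()].
#' @param config Binary D-vector.
#' @return Probability in (0, 1).
#' @export
joint_config_prob <- function(model, config) {
  config <- as.numeric(config)
  stopifnot(length(config) == ncol(model$Q), all(config %in% c(0, 1)))
  per_class <- apply(model$Q, 1L, function(q) {
    prod(q^config * (1 - q)^(1 - config))
  })
  sum(model$pi * per_class)
}

#' Expected false discovery rate along a posterior ranking
#'
#' Optional direct-posterior error report: for the top r genes of a ranking,
#' the expected FDR is the mean of (1 - posterior) over those genes. This is
#' a reporting convenience; ranking and calling operate on raw posteriors.
#'
#' @param diff_post G x D posterior matrix (or fitted object carrying one).
#' @param study Study index.
#' @param t Optional t matrix for tie-breaking, as in [rank_genes()].
#' @return Numeric vector: expected FDR at each rank r.
#' @export
expected_fdr <- function(diff_post, study = 1L, t = NULL) {
  if (is.list(diff_post) && !is.null(diff_post$diff_post)) {
    diff_post <- diff_post$diff_post
  }
  ord <- rank_genes(diff_post, study = study, t = t)
  cummean <- cumsum(1 - diff_post[ord, study]) / seq_len(nrow(diff_post))
  cummean
}
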