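#' Pooled two-group statistics for one study
#'
#' Computes, per gene, the mean expression difference between cases and
#' controls and the pooled sample variance on `n - 2` degrees of freedom,
#' along with the design constants `v = 1/n_case + 1/n_control` and the
#' residual degrees of freedom.
#'
#' @param study A [study_dataset()].
#' @return A list of class `pooled_stats` with `y` (mean differences), `s2`
#'   (pooled variances), `v`, `df_resid`, `n`.
#' @export
pooled_stats <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  case <- study$values[, study$group == "case", drop = FALSE]
  control <- study$values[, study$group == "control", drop = FALSE]
  n1 <- study$n_case
  n2 <- study$n_control
  m1 <- rowMeans(case)
  m2 <- rowMeans(control)
  ss <- rowSums((case - m1)^2) + rowSums((control - m2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- ss / df_resid
  if (all(s2 == 0)) stop("degenerate input: zero pooled variance for every gene")
  structure(
    list(y = m1 - m2, s2 = s2, v = 1 / n1 + 1 / n2, df_resid = df_resid,
         n = n1 + n2, gene_ids = study$gene_ids),
    class = "pooled_stats"
  )
}

#' Estimate the inverse-chi-squared variance prior
#'
#' Fits the hierarchical variance model `1/sigma^2 ~ chi^2(n0) / (n0 s0^2)`
#' by Smyth's moment matching on `log(s2)` (digamma/trigamma identities),
#' delegating to [limma::fitFDist()]. When the empirical spread of `log(s2)`
#' does not exceed its theoretical sampling spread the prior degrees of
#' freedom are infinite and all moderated variances collapse to `s0^2`.
#'
#' @param s2 Vector of pooled sample variances (one per gene).
#' @param df_resid Residual degrees of freedom of `s2`.
#' @return A list with `n0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df_resid) {
  if (length(s2) < 10L) stop("too few genes for stable variance-prior estimation")
  s2 <- pmax(s2, 1e-12)
  fit <- limma::fitFDist(s2, df1 = df_resid)
  list(n0 = fit$df2, s0_sq = fit$scale)
}

#' Moderated t-statistics
#'
#' Shrinks each gene's pooled variance toward the prior value,
#' `s2_tilde = (n0 s0^2 + df_resid * s2) / (n0 + df_resid)`, and returns
#' `t = y / sqrt(v * s2_tilde)`. With `n0 = Inf` the moderated variance is
#' `s0^2` for every gene; with `n0 = 0` the ordinary two-sample pooled t is
#' recovered.
#'
#' @param stats A [pooled_stats()] object.
#' @param n0,s0_sq Variance-prior parameters, e.g. from
#'   [fit_variance_prior()].
#' @return Numeric vector of moderated t-statistics.
#' @export
moderated_t <- function(stats, n0, s0_sq) {
  stopifnot(inherits(stats, "pooled_stats"))
  s2_tilde <- if (is.infinite(n0)) {
    rep_len(s0_sq, length(stats$s2))
  } else {
    (n0 * s0_sq + stats$df_resid * stats$s2) / (n0 + stats$df_resid)
  }
  stats$y / sqrt(stats$v * s2_tilde)
}

#' Null and alternative log-densities of the moderated t
#'
#' Under the hierarchical model a non-differential gene's moderated t follows
#' a Student t with `df = n0 + n - 2` degrees of freedom; a differential
#' gene's t follows the same t scaled by `c = sqrt(1 + w/v) >= 1`. Degrees of
#' freedom are capped at 1e6 (the normal regime) for evaluation.
#'
#' @param t Numeric vector of t-statistics.
#' @param df Total degrees of freedom.
#' @param scale_alt Alternative scale `c >= 1`.
#' @return Log-density values.
#' @export
null_logdensity <- function(t, df) {
  dt(t, df = min(df, 1e6), log = TRUE)
}

#' @rdname null_logdensity
#' @export
alt_logdensity <- function(t, df, scale_alt) {
  dt(t / scale_alt, df = min(df, 1e6), log = TRUE) - log(scale_alt)
}

# Per-study log-density matrices for a tstat_matrix: lf0, lf1 (G x D).
density_matrices <- function(tstat) {
  t <- tstat$t
  lf0 <- t
  lf1 <- t
  for (d in seq_len(ncol(t))) {
    lf0[, d] <- null_logdensity(t[, d], tstat$df[d])
    lf1[, d] <- alt_logdensity(t[, d], tstat$df[d], tstat$scale_alt[d])
  }
  list(lf0 = lf0, lf1 = lf1)
}

#' Estimate the differential-effect variance ratio w
#'
#' Fits, to one study's moderated t-statistics, a two-component scale mixture
#' `p0 * t(df) + (1 - p0) * c * t(df)` over the unknown alternative scale
#' `c >= 1` and null proportion `p0` by EM (the scale update is a
#' one-dimensional weighted likelihood maximisation). Returns the implied
#' effect-variance ratio `w = (c^2 - 1) * v`.
#'
#' @param t Vector of moderated t-statistics (one study).
#' @param df Total degrees of freedom of the null t density.
#' @param v Design constant `1/n_case + 1/n_control`.
#' @param max_iter,tol EM control.
#' @return List with `w`, `scale` (c), `p0`, `converged`, `n_iter`.
#' @export
estimate_w <- function(t, df, v, max_iter = 200L, tol = 1e-8) {
  if (length(t) < 100L) stop("too few genes to estimate w")
  df <- min(df, 1e6)
  lf0 <- dt(t, df = df, log = TRUE)
  p0 <- 0.9
  cc <- 2
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lf1 <- dt(t / cc, df = df, log = TRUE) - log(cc)
    a <- log(p0) + lf0
    b <- log1p(-p0) + lf1
    m <- pmax(a, b)
    ll <- sum(m + log(exp(a - m) + exp(b - m)))
    gamma1 <- exp(b - m) / (exp(a - m) + exp(b - m))   # P(alt | t)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    p0 <- min(max(1 - mean(gamma1), 1e-6), 1 - 1e-6)
    obj <- function(ci) sum(gamma1 * (dt(t / ci, df = df, log = TRUE) - log(ci)))
    cc <- optimize(obj, interval = c(1, 100), maximum = TRUE, tol = 1e-7)$maximum
  }
  if (!converged) warning("estimate_w did not converge; returning best iterate")
  list(w = (cc^2 - 1) * v, scale = cc, p0 = p0,
       converged = converged, n_iter = iter)
}

#' Moderate a multi-study dataset into a t-statistic matrix
#'
#' Runs, per study, the full empirical-Bayes pipeline: pooled statistics,
#' variance-prior estimation, moderated t, and estimation of the
#' differential-effect variance ratio `w` (unless overridden). The result
#' carries everything the mixture models need: the G x D t matrix, per-study
#' total degrees of freedom and alternative scales.
#'
#' @param ms A [multistudy()] object.
#' @param w Optional override for the effect-variance ratio: a single value
#'   or a vector/named vector per study. When supplied, the per-study scale
#'   mixture estimation of `w` is skipped.
#' @param n0,s0_sq Optional overrides for the variance-prior parameters
#'   (single values or per-study vectors); by default estimated from the data.
#' @return A [tstat_matrix()].
#' @export
moderate_studies <- function(ms, w = NULL, n0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(ms, "multistudy"))
  D <- length(ms$studies)
  G <- length(ms$gene_ids)
  tmat <- matrix(NA_real_, G, D)
  df <- scale_alt <- numeric(D)
  params <- vector("list", D)
  get_override <- function(x, d, id) {
    if (is.null(x)) return(NULL)
    if (!is.null(names(x))) {
      if (id %in% names(x)) return(unname(x[[id]])) else return(NULL)
    }
    rep_len(x, D)[d]
  }
  for (d in seq_len(D)) {
    st <- ms$studies[[d]]
    ps <- pooled_stats(st)
    n0_d <- get_override(n0, d, st$study_id)
    s0_d <- get_override(s0_sq, d, st$study_id)
    if (is.null(n0_d) || is.null(s0_d)) {
      vp <- fit_variance_prior(ps$s2, ps$df_resid)
      if (is.null(n0_d)) n0_d <- vp$n0
      if (is.null(s0_d)) s0_d <- vp$s0_sq
    }
    tmat[, d] <- moderated_t(ps, n0_d, s0_d)
    df[d] <- n0_d + ps$df_resid
    w_d <- get_override(w, d, st$study_id)
    w_fit <- NULL
    if (is.null(w_d)) {
      w_fit <- estimate_w(tmat[, d], df[d], ps$v)
      w_d <- w_fit$w
    }
    scale_alt[d] <- sqrt(1 + w_d / ps$v)
    params[[d]] <- list(study_id = st$study_id, n0 = n0_d, s0_sq = s0_d,
                        w = w_d, v = ps$v, df_resid = ps$df_resid,
                        w_fit = w_fit)
  }
  tstat_matrix(tmat, df = df, scale_alt = scale_alt,
               gene_ids = ms$gene_ids,
               study_ids = vapply(ms$studies, `[[`, character(1), "study_id"),
               params = params)
}
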