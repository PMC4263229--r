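#' Specification of a model-based multi-study simulation
#'
#' Describes a simulated multi-study experiment: the true differential
#' configurations ("patterns"), how many genes carry each pattern, the
#' replicate counts, and the variance/effect hyperparameters of the
#' generating hierarchical model. Defaults follow the model-based study
#' conditions: prior df `n0 = 4`, prior variance `s0_sq = 0.02`, effect
#' variance ratio `w0 = 4`, three cases and three controls per study.
#'
#' @param patterns List of distinct binary D-vectors (or a matrix with one
#'   pattern per row).
#' @param counts Genes per pattern (same length as `patterns`).
#' @param n_case,n_control Replicates per group in every study.
#' @param n0 Prior degrees of freedom of the gene variances.
#' @param s0_sq Prior variance scale.
#' @param w0 Case-shift standard deviation of differential genes, as a
#'   multiple of the gene's replicate standard deviation (the implied
#'   effect-variance ratio is `w0^2`).
#' @param seed Integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(patterns, counts, n_case = 3L, n_control = 3L,
                     n0 = 4, s0_sq = 0.02, w0 = 4, seed = 1L) {
  if (is.matrix(patterns)) {
    patterns <- lapply(seq_len(nrow(patterns)), function(i) patterns[i, ])
  }
  patterns <- lapply(patterns, as.numeric)
  D <- length(patterns[[1L]])
  stopifnot(
    all(lengths(patterns) == D),
    all(unlist(patterns) %in% c(0, 1)),
    length(counts) == length(patterns),
    all(counts >= 0), sum(counts) >= 1,
    n_case >= 2, n_control >= 2,
    n0 > 0, s0_sq > 0, w0 >= 0
  )
  if (anyDuplicated(vapply(patterns, paste, character(1), collapse = ""))) {
    stop("patterns must be distinct")
  }
  structure(
    list(patterns = patterns, counts = as.integer(counts), D = D,
         G = sum(as.integer(counts)),
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         n0 = n0, s0_sq = s0_sq, w0 = w0, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> G = %d genes, D = %d studies, %dv%d replicates, n0 = %g, s0^2 = %g, w0 = %g\n",
    x$G, x$D, x$n_case, x$n_control, x$n0, x$s0_sq, x$w0
  ))
  for (i in seq_along(x$patterns)) {
    cat(sprintf("  [%s] x %d\n", paste(x$patterns[[i]], collapse = ","),
                x$counts[i]))
  }
  invisible(x)
}

#' Preset simulation specifications
#'
#' Preset 1 is the reference four-study design: 10 000 genes of which 100 are
#' differential in all four studies ([1,1,1,1]), 400 in studies 1-2 only
#' ([1,1,0,0]), 400 in studies 2-3 only ([0,1,1,0]) and 9100 nowhere, with
#' three cases and three controls per study and hyperparameters `n0 = 4`,
#' `s0_sq = 0.02`, `w0 = 4`. Presets 2-4 are documented reconstructions with
#' D = 4, 8 and 20 studies respectively, mixing concordant and study-specific
#' patterns at the same gene counts and hyperparameters.
#'
#' @param n Preset number, 1-4.
#' @param seed Integer seed stored in the spec.
#' @return A [sim_spec()].
#' @export
preset_simulation <- function(n, seed = 1L) {
  ones <- function(D, idx) {
    p <- rep(0, D)
    p[idx] <- 1
    p
  }
  spec <- switch(as.character(n),
    "1" = sim_spec(
      patterns = list(c(1, 1, 1, 1), c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 0, 0)),
      counts = c(100L, 400L, 400L, 9100L), seed = seed
    ),
    "2" = sim_spec(
      patterns = list(ones(4, 1:4), ones(4, 1:2), ones(4, 3:4), rep(0, 4)),
      counts = c(100L, 400L, 400L, 9100L), seed = seed
    ),
    "3" = sim_spec(
      patterns = list(ones(8, 1:8), ones(8, 1:4), ones(8, 5:8), rep(0, 8)),
      counts = c(100L, 400L, 400L, 9100L), seed = seed
    ),
    "4" = sim_spec(
      patterns = list(ones(20, 1:20), ones(20, 1:10), ones(20, 11:20), rep(0, 20)),
      counts = c(100L, 400L, 400L, 9100L), seed = seed
    ),
    stop("preset must be 1, 2, 3 or 4")
  )
  spec
}

#' Generate multi-study data from the hierarchical model
#'
#' Per gene and study: a variance is drawn from the scaled inverse
#' chi-squared prior `n0 * s0_sq / chisq(n0)`; all replicate values are drawn
#' `N(0, sigma^2)`; where the gene's true configuration has `a_gd = 1` a mean
#' shift `mu ~ N(0, (w0 * sigma)^2)` is added to the case replicates only,
#' i.e. `w0` multiplies the gene's replicate standard deviation, so the
#' implied effect-variance ratio of the alternative moderated-t density is
#' `w0^2`. Genes are assigned to patterns in deterministic count blocks and
#' the gene order is then shuffled under the seed.
#'
#' @param spec A [sim_spec()] (carries the seed).
#' @return An object of class `sim_data` with `data` (a [multistudy()]),
#'   `truth_a` (G x D binary matrix of true differential states),
#'   `truth_pattern` (per-gene pattern index) and `spec`.
#' @export
simulate_model_based <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  G <- spec$G
  D <- spec$D
  block <- rep(seq_along(spec$patterns), spec$counts)
  truth_pattern <- block[sample.int(G)]
  truth_a <- do.call(rbind, spec$patterns)[truth_pattern, , drop = FALSE]
  gene_ids <- sprintf("g%05d", seq_len(G))
  rownames(truth_a) <- gene_ids
  n1 <- spec$n_case
  n2 <- spec$n_control
  studies <- vector("list", D)
  for (d in seq_len(D)) {
    sigma2 <- spec$n0 * spec$s0_sq / rchisq(G, df = spec$n0)
    x <- matrix(rnorm(G * (n1 + n2)), G, n1 + n2) * sqrt(sigma2)
    diff <- truth_a[, d] == 1
    if (any(diff)) {
      mu <- rnorm(sum(diff), 0, spec$w0 * sqrt(sigma2[diff]))
      x[diff, seq_len(n1)] <- x[diff, seq_len(n1)] + mu
    }
    rownames(x) <- gene_ids
    colnames(x) <- c(paste0("case", seq_len(n1)), paste0("ctrl", seq_len(n2)))
    studies[[d]] <- study_dataset(
      x, group = rep(c("case", "control"), c(n1, n2)),
      study_id = paste0("study", d), gene_ids = gene_ids
    )
  }
  structure(
    list(data = multistudy(studies), truth_a = truth_a,
         truth_pattern = truth_pattern, spec = spec),
    class = "sim_data"
  )
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d genes x %d studies (seed %d)\n",
              nrow(x$truth_a), ncol(x$truth_a), x$spec$seed))
  invisible(x)
}

#' Spike differential signal into an existing background
#'
#' Emulates spike-in style benchmarks: selected genes receive i.i.d.
#' `N(0, shift_sd^2)` deviates added to their case replicates in the studies
#' named by their pattern, leaving the background noise structure intact.
#' Pattern gene sets are disjoint; truth is recorded.
#'
#' @param background A [multistudy()] background dataset.
#' @param patterns List of binary D-vectors.
#' @param counts Genes per pattern.
#' @param shift_sd Standard deviation of the spiked shifts (default 1).
#' @param seed Integer seed.
#' @return A `sim_data` object wrapping the spiked data.
#' @export
spike_in <- function(background, patterns, counts, shift_sd = 1, seed = 1L) {
  stopifnot(inherits(background, "multistudy"))
  if (is.matrix(patterns)) {
    patterns <- lapply(seq_len(nrow(patterns)), function(i) patterns[i, ])
  }
  patterns <- lapply(patterns, as.numeric)
  D <- length(background$studies)
  G <- length(background$gene_ids)
  stopifnot(all(lengths(patterns) == D), length(counts) == length(patterns))
  if (sum(counts) > G) stop("pattern gene counts exceed the number of genes")
  set.seed(seed)
  chosen <- sample.int(G, sum(counts))
  assign_idx <- split(chosen, rep(seq_along(patterns), counts))
  truth_a <- matrix(0, G, D, dimnames = list(background$gene_ids, NULL))
  truth_pattern <- rep(length(patterns) + 1L, G)  # sentinel: background
  for (i in seq_along(patterns)) {
    truth_a[assign_idx[[i]], ] <- matrix(patterns[[i]], length(assign_idx[[i]]),
                                         D, byrow = TRUE)
    truth_pattern[assign_idx[[i]]] <- i
  }
  studies <- background$studies
  for (d in seq_len(D)) {
    st <- studies[[d]]
    case_cols <- which(st$group == "case")
    diff <- which(truth_a[, d] == 1)
    if (length(diff)) {
      st$values[diff, case_cols] <- st$values[diff, case_cols] +
        matrix(rnorm(length(diff) * length(case_cols), 0, shift_sd),
               length(diff), length(case_cols))
    }
    studies[[d]] <- st
  }
  structure(
    list(data = multistudy(studies), truth_a = truth_a,
         truth_pattern = truth_pattern,
         spec = list(patterns = patterns, counts = counts,
                     shift_sd = shift_sd, seed = seed)),
    class = "sim_data"
  )
}
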