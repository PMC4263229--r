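#' Construct a single-study two-group expression dataset
#'
#' A `study_dataset` holds one study's normalized, log-scale expression matrix
#' (genes x samples) together with its two-group design. Case columns always
#' precede control columns internally.
#'
#' @param values Numeric matrix, genes x samples, normalized log-scale
#'   expression. Row names are used as gene ids when `gene_ids` is `NULL`.
#' @param group Character or factor of length `ncol(values)` with values
#'   `"case"` / `"control"`.
#' @param study_id Study identifier.
#' @param gene_ids Optional character vector of gene identifiers.
#'
#' @return An object of class `study_dataset` with elements `study_id`,
#'   `values`, `gene_ids`, `group`, `n_case`, `n_control`.
#' @export
study_dataset <- function(values, group, study_id = "study1", gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  group <- as.character(group)
  if (!all(group %in% c("case", "control"))) {
    stop("unknown sample label: group labels must be 'case' or 'control'")
  }
  if (length(group) != ncol(values)) {
    stop("length(group) must equal ncol(values)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression matrix contains missing or non-finite values")
  }
  n_case <- sum(group == "case")
  n_control <- sum(group == "control")
  if (n_case < 2L || n_control < 2L) {
    stop("insufficient replicates: need at least 2 cases and 2 controls")
  }
  ord <- order(factor(group, levels = c("case", "control")))
  structure(
    list(
      study_id = as.character(study_id),
      values = values[, ord, drop = FALSE],
      gene_ids = gene_ids,
      group = group[ord],
      n_case = n_case,
      n_control = n_control
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %s: %d genes, %d cases vs %d controls\n",
    x$study_id, nrow(x$values), x$n_case, x$n_control
  ))
  invisible(x)
}

#' Bundle several studies sharing one gene universe
#'
#' Aligns the studies on the intersection of their gene ids (joint modelling
#' requires every gene to be measured in every study). Gene order follows the
#' first study after intersection. A warning reports dropped genes.
#'
#' @param studies List of [study_dataset()] objects.
#' @return An object of class `multistudy` with elements `studies` and
#'   `gene_ids`.
#' @export
multistudy <- function(studies) {
  stopifnot(length(studies) >= 1L)
  if (!all(vapply(studies, inherits, logical(1), "study_dataset"))) {
    stop("all elements must be study_dataset objects")
  }
  common <- Reduce(intersect, lapply(studies, `[[`, "gene_ids"))
  if (length(common) == 0L) {
    stop("gene universes have an empty intersection")
  }
  n_total <- length(studies[[1L]]$gene_ids)
  keep <- studies[[1L]]$gene_ids[studies[[1L]]$gene_ids %in% common]
  dropped <- sum(!vapply(studies, function(s) {
    length(s$gene_ids) == length(keep)
  }, logical(1))) > 0 || length(keep) < n_total
  if (dropped) {
    warning(sprintf(
      "gene universes differ; keeping the %d genes common to all studies",
      length(keep)
    ))
  }
  studies <- lapply(studies, function(s) {
    idx <- match(keep, s$gene_ids)
    s$values <- s$values[idx, , drop = FALSE]
    s$gene_ids <- keep
    s
  })
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("duplicate study ids")
  structure(list(studies = studies, gene_ids = keep), class = "multistudy")
}

#' @export
print.multistudy <- function(x, ...) {
  cat(sprintf(
    "<multistudy> %d studies, %d common genes\n",
    length(x$studies), length(x$gene_ids)
  ))
  for (s in x$studies) print(s)
  invisible(x)
}

#' Load multi-study expression data from delimited text files
#'
#' Each file is a delimited gene x sample table whose first column holds gene
#' ids and whose header row holds sample ids. The design names, per study,
#' which sample columns are cases and which are controls.
#'
#' @param design Either a list of per-study specifications, each a list with
#'   elements `file`, `case` (sample ids or column indices) and `control`,
#'   optionally `id`, or a path to a YAML file with a top-level `studies` list
#'   of the same shape.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A [multistudy()] object.
#' @export
load_multistudy <- function(design, sep = "\t") {
  if (is.character(design) && length(design) == 1L) {
    design <- yaml::read_yaml(design)$studies
  }
  studies <- lapply(seq_along(design), function(i) {
    spec <- design[[i]]
    tab <- read.delim(spec$file, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- gene_ids
    pick <- function(cols) {
      if (is.numeric(cols)) return(colnames(mat)[cols])
      missing <- setdiff(cols, colnames(mat))
      if (length(missing)) {
        stop(sprintf("unknown sample label(s): %s", paste(missing, collapse = ", ")))
      }
      cols
    }
    case <- pick(spec$case)
    control <- pick(spec$control)
    id <- if (!is.null(spec$id)) spec$id else paste0("study", i)
    study_dataset(
      mat[, c(case, control), drop = FALSE],
      group = rep(c("case", "control"), c(length(case), length(control))),
      study_id = id
    )
  })
  multistudy(studies)
}

#' Construct a moderated t-statistic matrix
#'
#' The G x D matrix of per-study moderated t-statistics together with the
#' per-study density parameters: total degrees of freedom (prior + residual)
#' and the alternative scale `sqrt(1 + w/v)` of the scaled-t density for
#' differential genes.
#'
#' @param t Numeric G x D matrix of moderated t-statistics.
#' @param df Per-study positive degrees of freedom (length D).
#' @param scale_alt Per-study alternative-density scale, each >= 1.
#' @param gene_ids,study_ids Optional identifiers.
#' @param params Optional list of per-study moderation parameter lists
#'   (carried along for provenance; not used by the mixture models).
#' @return An object of class `tstat_matrix`.
#' @export
tstat_matrix <- function(t, df, scale_alt, gene_ids = NULL, study_ids = NULL,
                         params = NULL) {
  t <- as.matrix(t)
  D <- ncol(t)
  if (is.null(gene_ids)) gene_ids <- rownames(t)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(t)))
  if (is.null(study_ids)) study_ids <- colnames(t)
  if (is.null(study_ids)) study_ids <- paste0("study", seq_len(D))
  df <- rep_len(as.numeric(df), D)
  scale_alt <- rep_len(as.numeric(scale_alt), D)
  if (any(!is.finite(t))) {
    bad <- which(!is.finite(t), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite t-statistic at gene %s, study %s",
                 gene_ids[bad[1L]], study_ids[bad[2L]]))
  }
  if (any(df <= 0)) stop("df must be positive")
  if (any(scale_alt < 1)) stop("scale_alt must be >= 1 for every study")
  dimnames(t) <- list(gene_ids, study_ids)
  structure(
    list(t = t, df = df, scale_alt = scale_alt,
         gene_ids = as.character(gene_ids), study_ids = as.character(study_ids),
         params = params),
    class = "tstat_matrix"
  )
}

#' @export
print.tstat_matrix <- function(x, ...) {
  cat(sprintf("<tstat_matrix> %d genes x %d studies\n",
              nrow(x$t), ncol(x$t)))
  cat("  df:        ", paste(signif(x$df, 4), collapse = ", "), "\n")
  cat("  scale_alt: ", paste(signif(x$scale_alt, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tstat_matrix <- function(x) dim(x$t)

#' Write / read a moderated t-statistic matrix as annotated TSV
#'
#' The file is a tab-separated gene x study table preceded by commented header
#' lines (`#`) recording the per-study degrees of freedom and alternative
#' scales, so that a round trip preserves the full object.
#'
#' @param x A [tstat_matrix()].
#' @param path File path.
#' @return `write_tstat` invisibly returns `path`; `read_tstat` returns the
#'   reconstructed [tstat_matrix()].
#' @export
write_tstat <- function(x, path) {
  stopifnot(inherits(x, "tstat_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# cormotif tstat v1",
    paste0("# study_ids\t", paste(x$study_ids, collapse = "\t")),
    paste0("# df\t", paste(format(x$df, digits = 17), collapse = "\t")),
    paste0("# scale_alt\t", paste(format(x$scale_alt, digits = 17), collapse = "\t"))
  ), con)
  tab <- data.frame(gene_id = x$gene_ids,
                    format(x$t, digits = 17, trim = TRUE),
                    check.names = FALSE)
  colnames(tab) <- c("gene_id", x$study_ids)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tstat
#' @export
read_tstat <- function(path) {
  lines <- readLines(path, n = 4L)
  if (length(lines) < 4L || lines[1L] != "# cormotif tstat v1") {
    stop("malformed header: not a cormotif tstat file")
  }
  parse_header <- function(key) {
    line <- lines[startsWith(lines, paste0("# ", key, "\t"))]
    if (length(line) != 1L) stop(sprintf("malformed header: missing field '%s'", key))
    strsplit(sub(paste0("^# ", key, "\t"), "", line), "\t")[[1L]]
  }
  study_ids <- parse_header("study_ids")
  df <- as.numeric(parse_header("df"))
  scale_alt <- as.numeric(parse_header("scale_alt"))
  tab <- read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  tstat_matrix(mat, df = df, scale_alt = scale_alt,
               gene_ids = rownames(mat), study_ids = study_ids)
}
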