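test_that("study_dataset validates its design", {
  x <- matrix(rnorm(12), 3, 4)
  expect_error(
    study_dataset(x, group = c("case", "case", "case", "control")),
    "insufficient replicates"
  )
  expect_error(
    study_dataset(x, group = c("case", "case", "treated", "control")),
    "unknown sample label"
  )
  x[1, 1] <- NA
  expect_error(
    study_dataset(x, group = rep(c("case", "control"), each = 2)),
    "missing"
  )
})

test_that("multistudy aligns on the gene intersection, first-study order", {
  mk <- function(ids, id) {
    m <- matrix(rnorm(length(ids) * 4), length(ids), 4)
    rownames(m) <- ids
    study_dataset(m, rep(c("case", "control"), each = 2), study_id = id)
  }
  ms <- multistudy(list(mk(c("a", "b", "c"), "s1"), mk(c("a", "b", "c"), "s2")))
  expect_identical(ms$gene_ids, c("a", "b", "c"))
  expect_warning(
    ms2 <- multistudy(list(mk(c("c", "a", "b"), "s1"), mk(c("b", "c"), "s2"))),
    "common"
  )
  expect_identical(ms2$gene_ids, c("c", "b"))  # order of first study, intersected
  expect_identical(ms2$studies[[2]]$gene_ids, c("c", "b"))
  expect_error(
    multistudy(list(mk(c("a", "b"), "s1"), mk(c("x", "y"), "s2"))),
    "empty intersection"
  )
})

test_that("load_multistudy reads delimited tables against a design", {
  dir <- withr::local_tempdir()
  write_study <- function(path, ids, samples) {
    m <- matrix(round(rnorm(length(ids) * length(samples)), 4),
                length(ids), length(samples),
                dimnames = list(NULL, samples))
    tab <- data.frame(gene_id = ids, m, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  f1 <- file.path(dir, "s1.tsv")
  f2 <- file.path(dir, "s2.tsv")
  write_study(f1, c("g1", "g2", "g3"), c("c1", "c2", "c3", "n1", "n2", "n3"))
  write_study(f2, c("g1", "g2", "g3"), c("c1", "c2", "n1", "n2"))
  design <- list(
    list(file = f1, case = c("c1", "c2", "c3"), control = c("n1", "n2", "n3"),
         id = "studyA"),
    list(file = f2, case = c("c1", "c2"), control = c("n1", "n2"))
  )
  ms <- load_multistudy(design)
  expect_s3_class(ms, "multistudy")
  expect_length(ms$gene_ids, 3L)
  expect_identical(ms$studies[[1]]$study_id, "studyA")
  expect_identical(ms$studies[[1]]$n_case, 3L + 0L)
  expect_error(
    load_multistudy(list(list(file = f2, case = c("c1", "zz"),
                              control = c("n1", "n2")))),
    "unknown sample label"
  )
  expect_error(
    load_multistudy(list(list(file = f2, case = "c1",
                              control = c("n1", "n2")))),
    "insufficient replicates"
  )
  # YAML design file round trip
  yfile <- file.path(dir, "design.yaml")
  yaml::write_yaml(list(studies = design), yfile)
  ms_yaml <- load_multistudy(yfile)
  expect_equal(ms_yaml$studies[[1]]$values, ms$studies[[1]]$values)
})

test_that("tstat files round-trip losslessly", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- tstat_matrix(matrix(rnorm(15), 5, 3), df = runif(3, 4, 20),
                      scale_alt = runif(3, 1, 6))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_tstat(x, path)
    y <- read_tstat(path)
    expect_equal(y$t, x$t, tolerance = 1e-12)
    expect_identical(y$df, x$df)
    expect_identical(y$scale_alt, x$scale_alt)
    expect_identical(y$study_ids, x$study_ids)
  }
})

test_that("malformed tstat files are rejected with a clear message", {
  x <- make_tstat(4, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tstat(x, path)
  lines <- readLines(path)
  writeLines(lines[-4], path)   # drop the scale_alt header line
  expect_error(read_tstat(path), "scale_alt")
  lines2 <- lines
  lines2[6] <- sub("\t[^\t]+$", "\tNaN", lines2[6])
  writeLines(lines2, path)
  expect_error(read_tstat(path), "non-finite")
})

test_that("tstat_matrix enforces its invariants", {
  expect_error(tstat_matrix(matrix(1, 2, 2), df = 5, scale_alt = 0.5), ">= 1")
  expect_error(tstat_matrix(matrix(c(1, Inf, 0, 0), 2, 2), df = 5,
                            scale_alt = 2), "non-finite")
})
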