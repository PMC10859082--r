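test_that("constructor enforces the container invariants", {
  expr <- matrix(1:6, nrow = 2,
                 dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  meta <- data.frame(sample_id = "s1", age = 3)

  ok <- cell_dataset(expr, c("s1", "s1"), meta)
  expect_s3_class(ok, "cell_dataset")
  expect_identical(ok$gene_ids, c("g1", "g2", "g3"))

  # unmatched cell sample label is named in the error
  expect_error(cell_dataset(expr, c("s1", "ghost"), meta), "ghost")
  # duplicate gene ids
  expect_error(cell_dataset(expr, c("s1", "s1"), meta,
                            gene_ids = c("g1", "g1", "g3")), "unique")
  # non-numeric age names the sample
  expect_error(cell_dataset(expr, c("s1", "s1"),
                            data.frame(sample_id = "s1", age = "old")),
               "s1")
  # missing sample labels rejected rather than dropped
  expect_error(cell_dataset(expr, c("s1", NA), meta), "missing")
})

test_that("datasets round-trip through every supported format", {
  ds <- annotated_dataset()
  files <- c(dense_tsv = withr::local_tempfile(fileext = ".tsv"),
             mtx = withr::local_tempfile(fileext = ".mtx"),
             h5ad = withr::local_tempfile(fileext = ".h5ad"))
  for (fmt in names(files)) {
    write_dataset(ds, files[[fmt]], fmt)
    back <- read_dataset(files[[fmt]], fmt)
    expect_identical(back$expression, ds$expression, label = fmt)
    expect_equal(back$sample_metadata, ds$sample_metadata, label = fmt)
    expect_equal(back$cell_metadata$cell_type, ds$cell_metadata$cell_type,
                 label = fmt)
    expect_identical(back$cell_sample_ids, ds$cell_sample_ids, label = fmt)
  }
})

test_that("mtx reader rejects a cell whose sample lacks metadata", {
  ds <- annotated_dataset()
  f <- withr::local_tempfile(fileext = ".mtx")
  write_dataset(ds, f, "mtx")
  # drop one sample from the metadata sidecar
  samples <- read.delim(sub("\\.mtx$", "_samples.tsv", f))
  write.table(samples[samples$sample_id != "f1", ],
              sub("\\.mtx$", "_samples.tsv", f),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(f, "mtx"), "f1")
})

test_that("reader errors name a missing annotation column", {
  ds <- annotated_dataset()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f, "dense_tsv")
  expect_error(read_dataset(f, "dense_tsv", sample_key = "donor"), "donor")
  expect_error(read_dataset(f, "dense_tsv", age_key = "months"), "months")
})

test_that("string ages with unit suffixes are coerced to numeric", {
  ds <- annotated_dataset()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f, "dense_tsv")
  samples <- read.delim(sub("\\.tsv$", "_samples.tsv", f))
  samples$age <- c("3m", "18m")
  write.table(samples, sub("\\.tsv$", "_samples.tsv", f),
              sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_dataset(f, "dense_tsv")
  expect_equal(sort(back$sample_metadata$age), c(3, 18))
})

test_that("subset_dataset restricts cells and drops emptied samples", {
  ds <- annotated_dataset()

  males <- subset_dataset(ds, sex == "male")
  expect_equal(length(males$cell_ids), 3)
  expect_equal(males$sample_metadata$sample_id, "m1")

  gran <- subset_dataset(ds, cell_type == "granulocyte")
  expect_true(all(gran$cell_metadata$cell_type == "granulocyte"))
  expect_equal(length(gran$cell_ids), 3)

  # string predicates (the CLI pathway) behave identically
  expect_equal(subset_dataset(ds, 'sex == "male"')$cell_ids,
               males$cell_ids)

  expect_error(subset_dataset(ds, genotype == "ko"), "predicate")
  expect_error(subset_dataset(ds, sex == "unknown"), "every cell")
})

test_that("filter_top_genes ranks by mean expression", {
  # one age category, per-gene means 2, 5, 1 -> k = 1 keeps the middle gene
  expr <- matrix(c(2, 2, 5, 5, 1, 1), nrow = 2,
                 dimnames = list(c("c1", "c2"), c("lo", "hi", "min")))
  ds <- cell_dataset(expr, c("s1", "s1"),
                     data.frame(sample_id = "s1", age = 1))
  expect_identical(filter_top_genes(ds, k = 1)$gene_ids, "hi")

  # k >= n_genes is the identity
  expect_identical(filter_top_genes(ds, k = 10)$gene_ids, ds$gene_ids)

  # per-age union keeps a gene that is top only at one age
  expr2 <- rbind(c(10, 1), c(10, 1), c(1, 10), c(1, 10))
  dimnames(expr2) <- list(paste0("c", 1:4), c("young_hi", "old_hi"))
  ds2 <- cell_dataset(expr2, c("a", "a", "b", "b"),
                      data.frame(sample_id = c("a", "b"), age = c(1, 2)))
  expect_identical(filter_top_genes(ds2, k = 1, per_age = TRUE)$gene_ids,
                   c("young_hi", "old_hi"))
  expect_identical(filter_top_genes(ds2, k = 1, per_age = FALSE)$gene_ids,
                   "young_hi")

  expect_equal(formals(filter_top_genes)$k, 3000)
})

test_that("subset and overall-mean filter commute on an order-stable fixture", {
  # per-gene means identical in every sample, so subsetting cannot change
  # the overall ranking and the two operation orders agree
  expr <- matrix(rep(c(3, 1, 2), each = 4), nrow = 4,
                 dimnames = list(paste0("c", 1:4), c("gA", "gB", "gC")))
  ds <- cell_dataset(expr, c("m", "m", "f", "f"),
                     data.frame(sample_id = c("m", "f"), age = c(1, 1),
                                sex = c("male", "female")))
  a <- filter_top_genes(subset_dataset(ds, sex == "male"), k = 2,
                        per_age = FALSE)
  b <- subset_dataset(filter_top_genes(ds, k = 2, per_age = FALSE),
                      sex == "male")
  expect_identical(a$expression, b$expression)
})

test_that("result tables are written deterministically and round-trip", {
  tbl <- data.frame(
    gene_id = c("b", "a", "c", "d"),
    rho = c(0.5, 0.5, NA, 0.9),
    mantel_p = c(0.01, 0.01, 1, 0.001),
    adjusted_p = c(0.02, 0.02, 1, 0.004),
    n_samples = 4L, n_permutations = 100L,
    metric = "hellinger",
    passed_cutoff = c(FALSE, FALSE, FALSE, TRUE))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(tbl, f)
  back <- read_results(f)
  # descending rho, ties lexicographic, undefined scores last
  expect_identical(back$gene_id, c("d", "a", "b", "c"))
  expect_equal(back$rho, c(0.9, 0.5, 0.5, NA))
  expect_identical(back$passed_cutoff, c(TRUE, FALSE, FALSE, FALSE))

  # empty table -> header-only file
  write_results(tbl[0, ], f)
  expect_equal(nrow(read_results(f)), 0)
  expect_match(readLines(f)[1], "gene_id\trho")
})

test_that("SummarizedExperiment input coerces to a cell_dataset", {
  skip_if_not_installed("SingleCellExperiment")
  counts <- matrix(rpois(20, 5), nrow = 4,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = counts),
    colData = S4Vectors::DataFrame(sample_id = c("a", "a", "b", "b", "b"),
                                   age = c(3, 3, 24, 24, 24)))
  ds <- as_cell_dataset(sce)
  expect_s3_class(ds, "cell_dataset")
  expect_equal(dim(ds$expression), c(5, 4))
  expect_equal(ds$sample_metadata$age, c(3, 24))
})
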