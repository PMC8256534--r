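test_that("count table TSV parsing, validation and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB\tC", "s1\t5\t0\t1", "s2\t2\t3\t0"), tmp)
  ct <- read_count_table(tmp)
  expect_identical(rownames(ct), c("s1", "s2"))
  expect_equal(unname(rowSums(ct)), c(6, 5))

  # duplicated taxon column is an identifier error
  writeLines(c("sample_id\tA\tA", "s1\t1\t2"), tmp)
  expect_error(read_count_table(tmp), "duplicate identifiers")

  # random table round-trips bit-exactly
  x <- random_table(10, 50, seed = 3)
  write_count_table(x, tmp)
  expect_identical(read_count_table(tmp), x)

  # orientation auto-detection from known sample ids
  df <- data.frame(taxon = colnames(x), t(x), check.names = FALSE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_table(tmp, sample_ids = rownames(x))
  expect_identical(back[rownames(x), colnames(x)], x)

  expect_error(validate_count_table(x - 1), "non-negative")
  expect_error(validate_count_table(x + 0.5), "non-negative integers")
  expect_error(validate_count_table(x[, 1, drop = FALSE]), "2 taxa")
})

test_that("BIOM JSON tables read as samples-by-taxa counts", {
  tmp <- withr::local_tempfile(fileext = ".biom")
  j <- jsonlite::toJSON(list(
    id = "x", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org", type = "OTU table",
    generated_by = "test", date = "2026-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int", shape = c(2, 3),
    rows = list(list(id = "tA", metadata = NULL),
                list(id = "tB", metadata = NULL)),
    columns = list(list(id = "s1", metadata = NULL),
                   list(id = "s2", metadata = NULL),
                   list(id = "s3", metadata = NULL)),
    data = list(c(5, 0, 1), c(2, 3, 0))), auto_unbox = TRUE, null = "null")
  writeLines(j, tmp)
  ct <- read_count_table(tmp, format = "biom-json")
  expect_identical(rownames(ct), c("s1", "s2", "s3"))
  expect_equal(ct[, "tA"], c(s1 = 5L, s2 = 0L, s3 = 1L))
})

test_that("newick trees parse with validation and exact patristic distances", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["A", "A"], 0)
  expect_true(isSymmetric(D))

  # a missing branch length is a parse error, not a default of 0 or 1
  expect_error(read_tree(text = "((A:1,B:1):1,C);"), "branch length")
  expect_error(read_tree(text = "((A,B),C);"), "branch length")
  expect_error(read_tree(text = "((A:1,B:-1):1,C:2);"), "negative branch")
  expect_error(read_tree(text = "((A:1,A:1):1,C:2);"), "duplicate tip")
})

test_that("patristic distances match brute-force root-path summation", {
  for (seed in 1:50) {
    tr <- random_tip_tree(10, seed)
    expect_equal(patristic_distances(tr)[tr$tip.label, tr$tip.label],
                 oracle_patristic(tr), tolerance = 1e-10)
  }
})

test_that("align_inputs intersects, reports drops, and is idempotent", {
  x <- random_table(4, 3, seed = 1)
  colnames(x) <- c("A", "B", "X")
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  meta <- data.frame(sample_id = rownames(x), site = "g",
                     environment = "city", land_class = "campus",
                     local_type = "built", phenotype_alleles = 0L,
                     sex = "F", stringsAsFactors = FALSE)
  al <- suppressMessages(align_inputs(x, tr, meta))
  expect_identical(sort(colnames(al$table)), c("A", "B"))
  expect_identical(al$dropped$taxa, "X")
  expect_identical(al$dropped$tips, "C")

  al2 <- suppressMessages(align_inputs(al$table, al$tree, al$meta))
  expect_identical(al2$table, al$table)
  expect_identical(ape::write.tree(al2$tree), ape::write.tree(al$tree))

  colnames(x) <- c("P", "Q", "R")
  expect_error(align_inputs(x, tr), "disjoint")
})

test_that("sample metadata validation enforces the design contract", {
  meta <- data.frame(sample_id = c("s1", "s2"), site = "g",
                     environment = "city",
                     land_class = c("campus", "urban_forest"),
                     local_type = c("built", "forest"),
                     phenotype_alleles = c(0L, 2L), sex = c("F", "M"),
                     stringsAsFactors = FALSE)
  expect_silent(validate_sample_metadata(meta))
  bad <- meta; bad$local_type <- c("forest", "forest")
  expect_error(validate_sample_metadata(bad), "inconsistent")
  bad <- meta; bad$phenotype_alleles <- c(0L, 3L)
  expect_error(validate_sample_metadata(bad), "phenotype")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, tmp)
  expect_identical(read_sample_metadata(tmp), meta)
})
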