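counts3x2 <- matrix(c(1, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE)

test_that("dense and sparse BIOM encodings parse identically", {
  dense <- tempfile(fileext = ".biom")
  sparse <- tempfile(fileext = ".biom")
  tax <- c("k__Bacteria; p__Firmicutes", "k__Bacteria; p__Bacteroidetes",
           "k__Bacteria")
  write_raw_biom(dense, counts3x2, c("f1", "f2", "f3"), c("s1", "s2"),
                 matrix_type = "dense", taxonomy = tax)
  write_raw_biom(sparse, counts3x2, c("f1", "f2", "f3"), c("s1", "s2"),
                 matrix_type = "sparse", taxonomy = tax)

  td <- read_biom_table(dense)
  ts <- read_biom_table(sparse)
  expect_equal(unname(td$counts), counts3x2)
  expect_identical(td$feature_ids, c("f1", "f2", "f3"))
  expect_identical(td$sample_ids, c("s1", "s2"))
  expect_identical(td$taxonomy, tax)
  expect_identical(unname(td$counts), unname(ts$counts))
  expect_identical(td$feature_ids, ts$feature_ids)
  expect_identical(td$taxonomy, ts$taxonomy)

  expect_error(read_biom_table(tempfile()), "not found")
  bad <- tempfile(fileext = ".biom")
  writeLines('{"id": "x", "format": "oops"', bad)
  expect_error(read_biom_table(bad), "parse")
})

test_that("read -> write -> read is the identity", {
  p1 <- tempfile(fileext = ".biom")
  write_raw_biom(p1, counts3x2, c("f1", "f2", "f3"), c("s1", "s2"),
                 taxonomy = c("k__B; p__F", "k__B", "k__B; p__X"),
                 sample_md = data.frame(DIET = c("Omnivore", "Vegetarian")))
  t1 <- read_biom_table(p1)
  p2 <- tempfile(fileext = ".biom")
  write_biom_table(t1, p2)
  t2 <- read_biom_table(p2)
  expect_equal(unname(t2$counts), unname(t1$counts))
  expect_identical(t2$feature_ids, t1$feature_ids)
  expect_identical(t2$sample_ids, t1$sample_ids)
  expect_identical(t2$taxonomy, t1$taxonomy)
  expect_identical(t2$metadata$DIET, t1$metadata$DIET)
})

test_that("mapping files parse with and without the # dialect", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tDIET\tAGE", "s1\tOmnivore\t33",
               "s2\tVegetarian\t41"), p)
  md <- read_mapping(p)
  expect_identical(rownames(md), c("s1", "s2"))
  expect_identical(md$DIET, c("Omnivore", "Vegetarian"))

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("SampleID\tDIET\tAGE", "s1\tOmnivore\t33",
               "s2\tVegetarian\t41"), p2)
  expect_identical(unname(as.matrix(read_mapping(p2))),
                   unname(as.matrix(md)))

  ragged <- tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tDIET", "s1\tOmnivore\textra", "s2\tVeg"), ragged)
  expect_error(read_mapping(ragged), "line 2")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tDIET", "s1\tA", "s1\tB"), dup)
  expect_error(read_mapping(dup), "duplicate")
})

test_that("extract_labels intersects, preserves order, and validates", {
  tab <- abundance_table(matrix(1:12, nrow = 4,
                                dimnames = list(paste0("f", 1:4),
                                                c("s1", "s2", "s3"))))
  md <- data.frame(DIET = c("Omnivore", "Vegetarian"),
                   row.names = c("s3", "s1"))
  out <- extract_labels(tab, md, "DIET")
  expect_identical(out$table$sample_ids, c("s1", "s3"))
  expect_identical(out$labels$values, c("Vegetarian", "Omnivore"))
  expect_identical(out$labels$classes, c("Omnivore", "Vegetarian"))

  # empty-string and NA phenotypes are dropped, not errored
  md2 <- data.frame(DIET = c("Omnivore", "", "Vegetarian"),
                    row.names = c("s1", "s2", "s3"))
  out2 <- extract_labels(tab, md2, "DIET")
  expect_identical(out2$table$sample_ids, c("s1", "s3"))

  md3 <- data.frame(DIET = c("Omnivore", "Omnivore", "NA"),
                    row.names = c("s1", "s2", "s3"))
  expect_error(extract_labels(tab, md3, "DIET"), "fewer than two classes")
  expect_error(extract_labels(tab, md, "MISSING"), "not found")
  md4 <- data.frame(DIET = c("A", "B"), row.names = c("zz", "yy"))
  expect_error(extract_labels(tab, md4, "DIET"), "no overlapping")

  # label mapping collapses subcategories before the class check
  md5 <- data.frame(DIET = c("omni_no_red_meat", "omnivore", "vegetarian"),
                    row.names = c("s1", "s2", "s3"))
  out5 <- extract_labels(tab, md5, "DIET",
                         label_map = c(omni_no_red_meat = "omnivore"))
  expect_identical(out5$labels$classes, c("omnivore", "vegetarian"))
})

test_that("metadata embedded in the BIOM file works like a map file", {
  p <- tempfile(fileext = ".biom")
  write_raw_biom(p, counts3x2, c("f1", "f2", "f3"), c("s1", "s2"),
                 sample_md = data.frame(DIET = c("Omnivore", "Vegetarian")))
  tab <- read_biom_table(p)
  expect_false(is.null(tab$metadata))
  via_embedded <- extract_labels(tab, NULL, "DIET")

  m <- tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tDIET", "s1\tOmnivore", "s2\tVegetarian"), m)
  via_map <- extract_labels(tab, read_mapping(m), "DIET")
  expect_identical(via_embedded$labels$values, via_map$labels$values)
  expect_identical(via_embedded$table$sample_ids, via_map$table$sample_ids)
})

test_that("write_results emits a parseable ranked TSV", {
  tab <- abundance_table(matrix(1:8, nrow = 4,
                                dimnames = list(paste0("f", 1:4),
                                                c("s1", "s2"))),
                         taxonomy = paste0("tax", 1:4))
  res <- selection_result(c(3L, 1L), c("f3", "f1"), c(0.9, 0.5), "MIM")
  p <- tempfile(fileext = ".tsv")
  write_results(res, tab, p)
  got <- read.delim(p, stringsAsFactors = FALSE)
  expect_identical(got$rank, 1:2)
  expect_identical(got$feature_id, c("f3", "f1"))
  expect_identical(got$taxonomy, c("tax3", "tax1"))
  expect_equal(got$score, c(0.9, 0.5))

  empty <- selection_result(integer(0), character(0), numeric(0), "MIM")
  p2 <- tempfile(fileext = ".tsv")
  write_results(empty, tab, p2)
  expect_identical(nrow(read.delim(p2)), 0L)
})
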