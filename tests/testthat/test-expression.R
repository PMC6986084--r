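test_that("FPKM matches the closed form and handles degenerate inputs", {
  counts <- expression_matrix(
    matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    unit = "count")
  # force N = 1e6 by adding a filler transcript
  filler <- expression_matrix(
    rbind(counts, filler = 1e6 - 10), unit = "count")
  lens <- c(g1 = 1000, g2 = 500, filler = 100)
  f <- fpkm_from_counts(filler, lens)
  expect_equal(f["g1", "s1"], 10.0)
  expect_equal(f["g2", "s1"], 0.0)

  # cell-wise oracle on a random matrix
  x <- small_matrix(50, 6)
  lens <- setNames(sample(200:3000, 50), rownames(x))
  f <- fpkm_from_counts(x, lens)
  N <- colSums(x)
  for (g in sample(rownames(x), 10)) {
    for (s in colnames(x)) {
      expect_equal(f[g, s], 1e9 * x[g, s] / (N[[s]] * lens[[g]]),
                   tolerance = 1e-12)
    }
  }

  # scale equivariance: doubling all counts of one sample leaves its FPKM
  # unchanged (its library size doubles too)
  x2 <- x
  x2[, 3] <- 2 * x2[, 3]
  f2 <- fpkm_from_counts(expression_matrix(x2, "count"), lens)
  expect_equal(f2[, 3], f[, 3], tolerance = 1e-12)

  expect_error(fpkm_from_counts(x, lens[-1]), "missing transcript lengths")
  x0 <- x; x0[, 2] <- 0
  expect_error(fpkm_from_counts(expression_matrix(x0, "count"), lens), "s02")
})

test_that("low-expression filter applies a strict zero-fraction rule", {
  x <- matrix(1, 3, 12, dimnames = list(c("mostly0", "half0", "none0"),
                                        sprintf("s%02d", 1:12)))
  x["mostly0", 1:7] <- 0   # 7/12 > 0.5 -> dropped
  x["half0", 1:6] <- 0     # 6/12 == 0.5 -> kept (strict inequality)
  out <- filter_low_expression(expression_matrix(x, "count"), theta = 0.5)
  expect_identical(rownames(out), c("half0", "none0"))
  expect_error(filter_low_expression(expression_matrix(x, "count"), 1.5))
})

test_that("class specificity requires detection in every genotype of a class", {
  meta <- toy_metadata(clones = 2)
  x <- matrix(0, 4, nrow(meta),
              dimnames = list(c("onlyX", "both", "partialX", "onlyY"),
                              meta$sample_id))
  x["onlyX", meta$phenotypic_class == "X"] <- 5
  x["both", ] <- 5
  x["partialX", meta$genotype == "g1"] <- 5    # misses genotype g2
  x["onlyY", meta$phenotypic_class == "Y"] <- 5
  part <- classify_specific(expression_matrix(x, "count"), meta)
  expect_setequal(part$specific[["X"]], "onlyX")
  expect_setequal(part$specific[["Y"]], "onlyY")
  expect_setequal(part$cells[["X+Y"]], "both")
  # detected in only one of X's genotypes -> expressed in no group at all
  expect_false("partialX" %in% unlist(part$cells))

  # the looser any-sample rule admits it as X-specific
  part2 <- classify_specific(expression_matrix(x, "count"), meta,
                             rule = "any_sample")
  expect_true("partialX" %in% part2$specific[["X"]])

  expect_error(classify_specific(expression_matrix(x, "count"), meta[1:3, ]),
               "samples without metadata")
})

test_that("venn cells partition the expressed set and counts match an oracle", {
  b <- fixture_bundle()
  fp <- fpkm_from_counts(b$counts, b$lengths)
  part <- classify_specific(fp, b$meta)
  ids <- unlist(part$cells, use.names = FALSE)
  expect_identical(anyDuplicated(ids), 0L)         # disjoint

  # brute-force per-transcript membership oracle
  classes <- sort(unique(b$meta$phenotypic_class))
  oracle_cell <- function(g) {
    in_grp <- vapply(classes, function(cl) {
      genos <- unique(b$meta$genotype[b$meta$phenotypic_class == cl])
      all(vapply(genos, function(gt) {
        cols <- b$meta$sample_id[b$meta$genotype == gt]
        any(fp[g, cols] > 0)
      }, logical(1)))
    }, logical(1))
    if (!any(in_grp)) NA_character_ else paste(classes[in_grp], collapse = "+")
  }
  picked <- sample(rownames(fp), 60)
  expected <- vapply(picked, oracle_cell, character(1))
  for (i in seq_along(picked)) {
    got <- names(Filter(function(cell) picked[i] %in% cell, part$cells))
    if (is.na(expected[i])) expect_length(got, 0) else
      expect_identical(got, unname(expected[i]))
  }
  vc <- venn_counts(part)
  expect_identical(sum(vc$count), length(ids))     # exhaustive

  # planted specific transcripts recovered exactly (no dropout simulated)
  for (cl in names(b$truth$specific_sets))
    expect_setequal(part$specific[[cl]], b$truth$specific_sets[[cl]])
})

test_that("matrix and metadata TSV round-trips preserve content", {
  x <- small_matrix(10, 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, p)
  y <- read_expression_matrix(p, unit = "count")
  expect_equal(unclass(y), unclass(x), ignore_attr = TRUE)
  expect_identical(dimnames(y), dimnames(x))

  part <- structure(list(groups = c("A", "B"),
                         cells = list(A = "t1", `A+B` = c("t2", "t3"))),
                    class = "venn_partition")
  expect_identical(venn_counts(part)$count, c(1L, 2L))
})
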