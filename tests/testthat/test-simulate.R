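test_that("generation is seed-deterministic and respects the floor rule", {
  d <- study_design()
  p <- sim_params(n_transcripts = 400, seed = 11)
  a <- generate_counts(d, p)
  b <- generate_counts(d, p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$specific_sets, b$truth$specific_sets)

  # planted set sizes = floor(fraction * n)
  expect_length(a$truth$specific_sets[["4X_apo"]], floor(0.10 * 400))
  expect_length(a$truth$specific_sets[["2X_sex"]], floor(0.02 * 400))
  expect_length(unique(unlist(a$truth$de_sets[[1]])), floor(0.05 * 400))
  expect_length(a$truth$acr_set, floor(0.03 * 400))

  expect_error(sim_params(frac_specific = c("4X_apo" = 0.7), frac_de = 0.5),
               "jointly exceed")
  expect_error(sim_params(n_transcripts = 100, n_modules = 10,
                          module_size = 30), "exceeds n_transcripts")
})

test_that("class-specific transcripts are all-zero outside their class", {
  d <- study_design()
  p <- sim_params(n_transcripts = 1000,
                  frac_specific = c("4X_apo" = 0.1), seed = 3)
  sim <- generate_counts(d, p)
  apo_samples <- sim$meta$sample_id[sim$meta$phenotypic_class == "4X_apo"]
  other <- setdiff(colnames(sim$counts), apo_samples)
  zero_outside <- rownames(sim$counts)[
    rowSums(sim$counts[, other, drop = FALSE]) == 0 &
      rowSums(sim$counts[, apo_samples, drop = FALSE]) > 0]
  expect_length(sim$truth$specific_sets[["4X_apo"]], 100)
  expect_true(all(sim$truth$specific_sets[["4X_apo"]] %in% zero_outside))
})

test_that("planted fold changes are recovered empirically at many clones", {
  # Monte-Carlo: 30 clones per genotype tightens the class-mean ratio
  d <- study_design(clones_per_genotype = 30)
  p <- sim_params(n_transcripts = 300, de_log2fc = 2, genotype_sd = 0,
                  frac_specific = c(), seed = 1)
  sim <- generate_counts(d, p)
  apo <- sim$meta$sample_id[sim$meta$phenotypic_class == "4X_apo"]
  sex <- sim$meta$sample_id[sim$meta$phenotypic_class == "2X_sex"]
  up <- sim$truth$de_sets[["4X_apo_vs_2X_sex"]]$up
  dn <- sim$truth$de_sets[["4X_apo_vs_2X_sex"]]$down
  lfc <- log2(rowMeans(sim$counts[, apo]) / rowMeans(sim$counts[, sex]))
  expect_true(all(abs(lfc[up] - 2) <= 0.3))
  expect_true(all(abs(lfc[dn] + 2) <= 0.3))
})

test_that("background transcript means are class-independent", {
  d <- study_design()
  p <- sim_params(n_transcripts = 2000, seed = 5)
  sim <- generate_counts(d, p)
  planted <- unique(c(unlist(sim$truth$specific_sets),
                      unlist(lapply(sim$truth$de_sets, unlist))))
  bg <- setdiff(rownames(sim$counts), planted)
  apo <- sim$meta$sample_id[sim$meta$phenotypic_class == "4X_apo"]
  sex <- sim$meta$sample_id[sim$meta$phenotypic_class == "2X_sex"]
  # paired per-transcript comparison of log class means
  la <- log1p(rowMeans(sim$counts[bg, apo]))
  ls <- log1p(rowMeans(sim$counts[bg, sex]))
  expect_gt(t.test(la, ls, paired = TRUE)$p.value, 0.01)
})

test_that("planted modules reach the correlation design targets", {
  d <- study_design(classes = c(A = 1L), clones_per_genotype = 20L)  # 20 samples
  p0 <- sim_params(n_transcripts = 200, n_modules = 4, module_size = 15,
                   module_noise_sd = 0, frac_specific = c(), frac_de = 0,
                   seed = 2)
  sim <- generate_counts(d, p0)
  # continuous values: count rounding would perturb the exact-correlation check
  vals <- expression_matrix(unclass(sim$counts), unit = "fpkm")
  pm0 <- plant_modules(vals, p0, sim$truth)
  ids <- names(pm0$truth$module_assignment[pm0$truth$module_assignment == 1])
  cc <- cor(t(pm0$matrix[ids, ]))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)  # exact with zero noise

  p1 <- sim_params(n_transcripts = 200, n_modules = 4, module_size = 15,
                   frac_specific = c(), frac_de = 0, seed = 2)
  pm1 <- plant_modules(vals, p1, sim$truth)
  assign <- pm1$truth$module_assignment
  within <- unlist(lapply(1:4, function(m) {
    cc <- cor(t(pm1$matrix[names(assign[assign == m]), ]))
    cc[upper.tri(cc)]
  }))
  expect_gte(mean(within), 0.8)
  m1 <- names(assign[assign == 1]); m2 <- names(assign[assign == 2])
  between <- cor(t(pm1$matrix[m1, ]), t(pm1$matrix[m2, ]))
  expect_lt(mean(abs(between)), 0.3)
})

test_that("synthetic hits pass or fail interval filtering as planted", {
  b <- fixture_bundle()
  res <- filter_hits(b$hits, b$intervals, evalue_cutoff = 1e-05)
  # every planted ACR transcript survives; every decoy is removed
  expect_setequal(res$acr_transcripts, b$truth$acr_set)

  # a decoy at e-value 1e-04 inside an interval is dropped at cutoff 1e-05
  iv <- synthetic_intervals()
  decoy <- data.frame(query_id = "q1", subject_id = iv$chrom[1], pident = 99,
                      length = 100, mismatch = 0, gapopen = 0, qstart = 1,
                      qend = 100, sstart = iv$start[1], send = iv$start[1] + 99,
                      evalue = 1e-04, bitscore = 100, minus_strand = FALSE)
  expect_length(filter_hits(decoy, iv)$acr_transcripts, 0)

  # empty ACR set -> zero surviving hits
  truth0 <- b$truth
  truth0$acr_set <- character(0)
  ann0 <- generate_annotation_and_hits(truth0, seed = 9)
  expect_length(filter_hits(ann0$hits, iv)$acr_transcripts, 0)
})
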