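test_that("generator config validates its invariants", {
  expect_error(generator_config(n_per_class = c(-1, 10, 10)),
               "nonnegative")
  expect_error(generator_config(dropout_prob = 1.5), "dropout_prob")
  expect_error(generator_config(n_genes = 10, markers_per_class = 5),
               "markers_per_class")
  expect_error(generator_config(noise_sd = 0), "noise_sd")
})

test_that("generation is deterministic and respects its config", {
  cfg <- generator_config(n_per_class = c(20L, 30L, 25L), n_genes = 80L,
                          markers_per_class = 6L, seed = 42L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$matrix), c(75L, 80L))
  expect_true(all(a$matrix >= 0))
  expect_equal(as.vector(table(a$labels)[cfg$class_names]),
               c(20L, 30L, 25L))
  expect_equal(lengths(a$truth), c(CGE = 6L, dMGE = 6L, vMGE = 6L))
})

test_that("dropout_prob 1 zeroes everything", {
  ds <- generate_dataset(generator_config(
    n_per_class = c(5L, 5L, 5L), n_genes = 20L, markers_per_class = 2L,
    dropout_prob = 1))
  expect_true(all(ds$matrix == 0))
})

test_that("zero fraction tracks the dropout probability", {
  cfg <- generator_config(n_per_class = c(500L, 500L, 500L),
                          n_genes = 40L, markers_per_class = 5L,
                          dropout_prob = 0.3, seed = 99L)
  ds <- generate_dataset(cfg)
  N <- length(ds$matrix)
  se <- sqrt(0.3 * 0.7 / N)
  expect_lt(abs(mean(ds$matrix == 0) - 0.3), 3 * se)
})

test_that("planted markers carry a positive within-class mean shift", {
  cfg <- generator_config(n_per_class = c(500L, 500L, 500L),
                          n_genes = 40L, markers_per_class = 5L,
                          effect_size = 2, seed = 13L)
  ds <- generate_dataset(cfg)
  for (cl in names(ds$truth)) {
    inc <- ds$labels == cl
    for (g in ds$truth[[cl]]) {
      expect_gt(mean(ds$matrix[inc, g]) - mean(ds$matrix[!inc, g]), 1)
    }
  }
})

test_that("effect_size 0 leaves markers exchangeable with background", {
  cfg <- generator_config(n_per_class = c(500L, 500L, 500L),
                          n_genes = 40L, markers_per_class = 5L,
                          effect_size = 0, seed = 13L)
  ds <- generate_dataset(cfg)
  shifts <- unlist(lapply(names(ds$truth), function(cl) {
    inc <- ds$labels == cl
    vapply(ds$truth[[cl]], function(g)
      mean(ds$matrix[inc, g]) - mean(ds$matrix[!inc, g]), numeric(1))
  }))
  # mean shift of "markers" should be statistically indistinguishable
  # from zero at this n (SE of a mean difference ~ 0.1 here)
  expect_lt(max(abs(shifts)), 0.5)
})

test_that("reference ruleset fixture has the published structure", {
  rs <- cin_reference_ruleset()
  st <- ruleset_stats(rs)
  expect_identical(st$n_rules, 22L)
  expect_identical(st$rules_per_class[["CGE"]], 12L)
  expect_identical(st$rules_per_class[["vMGE"]], 10L)
  expect_identical(st$default_class, "dMGE")
  # normalized typography: every condition well-formed with one operator
  for (r in rs$rules) {
    expect_true(all(r$conditions$op %in% c("<=", ">=")))
    expect_true(all(is.finite(r$conditions$threshold)))
  }
  # spot-check thresholds reproduced to all printed decimals
  expect_identical(rs$rules[[1]]$conditions$threshold[4], 2019.223223)
  expect_identical(rs$rules[[4]]$conditions$threshold[3], 14.4383)
  expect_identical(rs$rules[[13]]$conditions$threshold, c(1.4487, 0.0111))
})

test_that("reference ruleset round-trips through the text format", {
  rs <- cin_reference_ruleset()
  expect_identical(parse_ruleset(format_ruleset(rs)), rs)
})

test_that("dataset manifest fixture matches the published arithmetic", {
  mf <- cin_dataset_manifest()
  expect_identical(mf$class_names, c("CGE", "dMGE", "vMGE"))
  expect_identical(mf$class_counts, c(856L, 957L, 856L))
  expect_identical(sum(mf$class_counts), 2669L)
  expect_identical(mf$total_transcripts - mf$all_zero_transcripts, 31273L)
  expect_identical(mf$class_counts[1], mf$class_counts[3])
})

test_that("write_dataset emits the standard file trio", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(generator_config(
    n_per_class = c(5L, 5L, 5L), n_genes = 12L, markers_per_class = 2L))
  paths <- write_dataset(ds, dir)
  m <- read_expression_matrix(paths$expression)
  expect_equal(m, ds$matrix)
  lab <- read_labels(paths$labels)
  expect_identical(lab$class, unname(ds$labels))
  truth <- read.delim(paths$truth, stringsAsFactors = FALSE)
  expect_setequal(truth$gene_id, unlist(ds$truth))
})
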