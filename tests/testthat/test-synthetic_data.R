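test_that("generator config validates its inputs", {
  expect_error(generator_config(deamination_rate = -0.1), ">= 0")
  expect_error(generator_config(island_fractions = c(Island = 0.5,
    N_Shore = 0.1, S_Shore = 0.1, N_Shelf = 0.1, S_Shelf = 0.1,
    OpenSea = 0.3)), "sum to 1")
  expect_error(generator_config(storage_range_years = c(4, 2)), "invalid")
  expect_error(generator_config(dirichlet_alpha = rep(-1, 6)), "positive")
})

test_that("baseline reference reflects island biology and reference_sep", {
  cfg <- generator_config(n_cpgs = 2000, seed = 10,
                          island_fractions = c(Island = 1, N_Shore = 0,
                                               S_Shore = 0, N_Shelf = 0,
                                               S_Shelf = 0, OpenSea = 0))
  ref <- generate_reference(cfg)
  expect_true(all(ref$annotation$relation_to_island == "Island"))
  expect_lt(mean(ref$baseline_beta), 0.3)   # islands mostly unmethylated

  # deterministic under a fixed seed
  ref2 <- generate_reference(cfg)
  expect_identical(ref$baseline_beta, ref2$baseline_beta)

  # zero separation means identical cell-type columns
  cfg0 <- generator_config(n_cpgs = 500, seed = 2, reference_sep = 0)
  r0 <- generate_reference(cfg0)
  expect_true(all(r0$baseline_beta == r0$baseline_beta[, 1]))
})

test_that("mix_and_degrade applies first-order decay to the methylated fraction", {
  B <- matrix(c(1, 0, 0.4), 3, 6,
              dimnames = list(c("g1", "g2", "g3"), CELL_TYPES))
  W <- matrix(1 / 6, 2, 6, dimnames = list(c("s1", "s2"), CELL_TYPES))
  t <- c(0, 4)

  # r = 0: expected beta equals the cell-type mixture exactly
  e0 <- mix_and_degrade(B, W, t, 0)
  expect_equal(e0[, 1], e0[, 2])
  expect_equal(unname(e0["g3", 1]), 0.4)

  # closed form: fully methylated CpG after 4 years at r = 0.05
  e <- mix_and_degrade(B, W, t, 0.05)
  expect_equal(unname(e["g1", 2]), exp(-0.2))
  # nothing methylated, nothing to decay
  expect_equal(unname(e["g2", ]), c(0, 0))
  expect_error(mix_and_degrade(B, W, t, -1), ">= 0")
})

test_that("expected beta decreases strictly with storage time when r > 0", {
  cfg <- generator_config(n_cpgs = 300, n_samples = 20, seed = 6,
                          deamination_rate = 0.01)
  ref <- generate_reference(cfg)
  W <- matrix(1 / 6, 5, 6, dimnames = list(paste0("s", 1:5), CELL_TYPES))
  tt <- c(0, 1, 2, 3, 4)
  e <- mix_and_degrade(ref$baseline_beta, W, tt, 0.01)
  pos <- rowSums(ref$baseline_beta) > 0
  expect_true(all(apply(e[pos, ], 1, function(z) all(diff(z) < 0))))
})

test_that("M-scale noise has the configured variance and is reproducible", {
  eb <- matrix(0.5, 1, 10000,
               dimnames = list("g1", paste0("s", 1:10000)))
  # zero noise is the identity up to the clip round trip
  b0 <- add_noise(eb, 0, seed = 1)
  expect_lt(max(abs(unclass(b0) - 0.5)), 1e-9)

  b1 <- add_noise(eb, 0.3, seed = 5)
  b2 <- add_noise(eb, 0.3, seed = 5)
  expect_identical(unclass(b1), unclass(b2))
  v <- stats::var(as.vector(beta_to_m(unclass(b1))))
  expect_lt(abs(v - 0.09) / 0.09, 0.10)   # Monte-Carlo, 1e4 draws
})

test_that("generate_dataset honors the configured cohort structure", {
  cfg <- generator_config(n_cpgs = 400, n_samples = 126, seed = 8,
                          storage_range_years = c(2.79, 4.17))
  d <- generate_dataset(cfg)
  expect_true(all(d$sheet$storage_dna_years >= 2.79 &
                  d$sheet$storage_dna_years <= 4.17))
  expect_equal(nrow(d$sheet), 126)
  expect_lt(max(abs(rowSums(d$proportions) - 1)), 1e-12)

  # identical seed, identical outputs
  d2 <- generate_dataset(cfg)
  expect_identical(unclass(d$beta), unclass(d2$beta))
  expect_identical(d$sheet, d2$sheet)

  # r = 0 (and identical cell profiles): expected beta is flat in storage time
  d0 <- generate_dataset(generator_config(n_cpgs = 50, n_samples = 20,
                                          seed = 9, deamination_rate = 0,
                                          reference_sep = 0))
  tt <- d0$sheet$storage_dna_years
  slopes <- apply(d0$truth$expected_beta, 1,
                  function(y) stats::cov(y, tt) / stats::var(tt))
  expect_lt(max(abs(slopes)), 1e-12)
})

test_that("shore CpGs lose more expected beta over 4 years than island CpGs", {
  cfg <- generator_config(n_cpgs = 4000, seed = 12)
  ref <- generate_reference(cfg)
  mixture <- rowMeans(ref$baseline_beta)
  drop4 <- mixture * (1 - exp(-4 * cfg$deamination_rate))
  rel <- ref$annotation$relation_to_island
  expect_gt(mean(drop4[rel %in% c("N_Shore", "S_Shore")]),
            mean(drop4[rel == "Island"]))
})

test_that("write_dataset emits readable tables", {
  d <- small_dataset(seed = 3, n_cpgs = 30, n_samples = 8)
  dir <- tempfile()
  write_dataset(d, dir)
  b <- read_methylation_matrix(file.path(dir, "beta.tsv"), "beta")
  expect_lt(max(abs(unclass(b) - unclass(d$beta))), 1e-12)
  sh <- read_sample_sheet(file.path(dir, "sheet.tsv"))
  expect_equal(sh$storage_dna_years, d$sheet$storage_dna_years)
  ann <- read_probe_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann$relation_to_island, d$annotation$relation_to_island)
})
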