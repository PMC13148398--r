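test_that("seed derivation is stable, distinct across cells, and below 2^31", {
  s1 <- derive_seed(1, 100, -0.005, 1e-7, 1e-10, 4, 1)
  expect_identical(s1, derive_seed(1, 100, -0.005, 1e-7, 1e-10, 4, 1))
  others <- c(derive_seed(1, 100, -0.005, 1e-7, 1e-10, 4, 2),
              derive_seed(1, 100, -0.005, 1e-7, 1e-10, 2, 1),
              derive_seed(1, 100, -0.005, 1e-7, 1e-9, 4, 1),
              derive_seed(2, 100, -0.005, 1e-7, 1e-10, 4, 1),
              derive_seed(1, 100, "empirical", 1e-7, 1e-10, 4, 1))
  expect_false(any(others == s1))
  expect_true(all(c(s1, others) >= 0 & c(s1, others) < 2^31))
})

test_that("a sweep writes one trajectory per run plus a reproducible master table", {
  cfg <- sweep_config(N = 20, s = "-0.01", rho = 1e-9, mu = 1e-7,
                      ploidy = 4L, replicates = 2L, base_seed = 5L,
                      generations = 120L, record_every = 10L, L = 1e6,
                      scale_factor = 100)
  dir <- file.path(tempdir(), "sweep_test")
  res <- run_sweep(cfg, pod = NULL, out_dir = dir)
  expect_equal(nrow(res$results), 2L)
  expect_length(res$trajectories, 2L)
  tsvs <- list.files(dir, pattern = "^N20.*\\.tsv$")
  expect_length(tsvs, 2L)
  expect_true(file.exists(file.path(dir, "master_results.tsv")))
  expect_true(all(res$results$status == "ok"))
  # grid values echoed verbatim at full scale
  expect_equal(unique(res$results$mu), 1e-7)
  expect_equal(unique(res$results$rho), 1e-9)
  # rerun with the same base seed: identical master table
  res2 <- run_sweep(cfg, pod = NULL, keep_trajectories = FALSE)
  expect_identical(res$results, res2$results)
  # replicates differ from each other
  expect_false(identical(res$trajectories[[1]]$rows, res$trajectories[[2]]$rows))
  unlink(dir, recursive = TRUE)
})

test_that("heatmap aggregation is the arithmetic mean with sentinel handling", {
  toy <- data.frame(
    N = 100, s = "-0.005", ploidy = 4,
    mu = rep(c(1e-8, 1e-8, 1e-7), each = 1), rho = 1e-10,
    replicate = 1:3, seed = 1:3, status = "ok",
    final_median_af = c(0.38, 0.42, NA), final_mean_fitness = 0.9,
    final_n_segregating = 10L, final_n_fixed = 0L,
    stringsAsFactors = FALSE)
  hm <- aggregate_heatmap(toy, N = 100, s = -0.005, ploidy = 4)
  expect_equal(hm$mean_final_median_af[hm$mu == 1e-8], 0.40)
  expect_true(is.na(hm$mean_final_median_af[hm$mu == 1e-7]))  # all-sentinel
  # three-replicate hand computation
  toy3 <- toy
  toy3$mu <- 1e-8
  toy3$final_median_af <- c(0.2, 0.3, 0.7)
  hm3 <- aggregate_heatmap(toy3, N = 100, s = -0.005, ploidy = 4)
  expect_equal(hm3$mean_final_median_af, mean(c(0.2, 0.3, 0.7)))
  expect_error(aggregate_heatmap(toy, N = 200, s = -0.005, ploidy = 4))
})

test_that("tetraploids occupy more of the (mu, rho) grid than diploids", {
  # scaled-down two-cell slice of the allele-frequency heatmap
  cfg <- sweep_config(N = 100, s = "-0.005", rho = 1e-10, mu = c(5e-9, 1e-7),
                      ploidy = c(2L, 4L), replicates = 2L, base_seed = 3L,
                      generations = 4000L, record_every = 10L,
                      scale_factor = 10)
  res <- run_sweep(cfg, pod = NULL, keep_trajectories = FALSE)
  hm4 <- aggregate_heatmap(res, N = 100, s = -0.005, ploidy = 4)
  hm2 <- aggregate_heatmap(res, N = 100, s = -0.005, ploidy = 2)
  expect_gt(sum(hm4$mean_final_median_af >= 0.25, na.rm = TRUE),
            sum(hm2$mean_final_median_af >= 0.25, na.rm = TRUE))
})

test_that("trajectory TSVs and config echoes round-trip", {
  p <- sim_params(N = 20, ploidy = 4, mu = 1e-6, rho = 1e-8, generations = 60,
                  L = 1e4, record_every = 10, seed = 9)
  m <- selection_model("empirical", beta_is_mean = TRUE)
  tr <- run_simulation(p, m, replicate = 3L)
  path <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  back <- read_trajectory_tsv(path)
  expect_equal(back$rows, tr$rows)
  expect_equal(back$params[names(back$params) != "seed"],
               tr$params[names(tr$params) != "seed"])
  expect_equal(back$model$mode, "empirical")
  expect_equal(back$model$scale, m$scale)
  expect_equal(back$replicate, 3L)
  unlink(path)

  cfgl <- config_lines(p, m, extra = list(replicate = 3L))
  parsed <- parse_config_lines(paste0("# ", cfgl))
  expect_equal(parsed$mu, 1e-6)
  expect_equal(parsed$model_beta, 0.0092)
  expect_true(parsed$model_beta_is_mean)
  expect_equal(parsed$replicate, 3)
})

test_that("VCF snapshots are valid and carry ploidy-arity genotypes", {
  skip_if_not_installed("vcfR")
  p <- sim_params(N = 15, ploidy = 4, mu = 5e-6, rho = 1e-7, generations = 80,
                  L = 1e4, record_every = 10)
  m <- selection_model("constant", s = -0.01)
  tr <- run_simulation(p, m, seed = 42)
  path <- tempfile(fileext = ".vcf")
  write_population_vcf(tr$population, path, model = m)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  af <- allele_frequencies(tr$population)
  expect_equal(nrow(vcf@gt), length(af))
  expect_equal(ncol(vcf@gt), 15L + 1L)  # FORMAT + N samples
  gt <- vcf@gt[, -1]
  expect_true(all(grepl("^[01](/[01]){3}$", gt)))  # unphased, arity 4
  pos <- as.integer(vcfR::getPOS(vcf))
  expect_true(all(pos >= 1 & pos <= 1e4))
  # dosage in the VCF matches carrier counts
  counts4 <- vapply(seq_len(nrow(gt)), function(i)
    sum(as.integer(strsplit(paste(gt[i, ], collapse = "/"), "/")[[1]])),
    integer(1))
  expect_equal(sort(counts4), sort(unname(af * 4 * 15)))
  info <- vcfR::extract.info(vcf, "S")
  expect_true(all(as.numeric(info) == -0.01))
  unlink(path)
})
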