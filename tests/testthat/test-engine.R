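test_that("wf_generation keeps census size and samples by fitness", {
  # degenerate weights: parent with fitness 0 is never drawn
  muts <- data.frame(id = 1L, position = 10, s = -1, h = 0,
                     origin_generation = 0L)
  p <- sim_params(N = 2, ploidy = 2, mu = 0, rho = 0, generations = 1, L = 1e4)
  pop <- make_test_pop(list(list(integer(0), integer(0)), list(1L, 1L)),
                       muts, ploidy = 2, params = p)
  expect_equal(pop$fitness, c(1, 0))
  set.seed(1)
  nxt <- wf_generation(pop, selection_model("constant", s = -1))
  expect_true(all(nxt$parents == 1L))
  expect_equal(nxt$parental_mean_fitness, 1)

  # all-zero fitness: extinction error
  pop0 <- make_test_pop(list(list(1L, 1L), list(1L, 1L)), muts, ploidy = 2,
                        params = p)
  expect_error(wf_generation(pop0, selection_model("constant", s = -1)),
               "extinct")

  # constant census size across many generations
  p2 <- sim_params(N = 25, ploidy = 4, mu = 1e-5, rho = 1e-7, generations = 1,
                   L = 1e4)
  pop <- new_population(p2)
  m <- selection_model("constant", s = -0.01)
  set.seed(2)
  for (g in 1:60) {
    pop <- sweep_fixations(wf_generation(pop, m))
    expect_length(pop$individuals, 25L)
    expect_true(all(lengths(pop$individuals) == 4L))
    expect_length(pop$parents, 50L)
  }
  expect_equal(pop$generation, 60L)
})

test_that("neutral reproductive success is multinomial-like", {
  # variance of offspring number approaches 2(1 - 1/N) under uniform weights
  N <- 50
  p <- sim_params(N = N, ploidy = 2, mu = 0, rho = 0, generations = 1, L = 1e4)
  m <- selection_model("constant", s = 0)
  pop <- new_population(p)
  set.seed(4)
  vars <- replicate(250, {
    pop <<- wf_generation(pop, m)
    var(tabulate(pop$parents, nbins = N))
  })
  expect_lt(abs(mean(vars) - 2 * (1 - 1 / N)), 0.15)
})

test_that("fixation sweep converts fixed mutations to substitutions", {
  muts <- mut_table(2, s = -0.005)
  # mutation 1 on all 2N chromosomes, mutation 2 segregating
  pop <- make_test_pop(list(list(c(1L, 2L), 1L), list(1L, 1L), list(1L, 1L)),
                       muts, ploidy = 2, generation = 7L)
  swept <- sweep_fixations(pop)
  expect_equal(swept$substitutions$id, 1L)
  expect_equal(swept$substitutions$fixation_generation, 7L)
  expect_false(any(unlist(swept$individuals) == 1L))
  af <- allele_frequencies(swept)
  expect_equal(unname(af), 1 / 6)
  # fitness recomputed without the fixed mutation
  expect_equal(swept$fitness, c(1, 1, 1))
  # no-op when nothing is fixed
  expect_identical(sweep_fixations(swept)$individuals, swept$individuals)
})

test_that("neutral substitutions accumulate at rate mu*L for both ploidies", {
  # measured at steady state: fixations cannot begin until the first
  # mutations have drifted to fixation (~2 * ploidy * N generations), so the
  # count over a window after that lag is compared with mu*L per generation
  t0 <- 1500
  t1 <- 4000
  for (pl in c(2L, 4L)) {
    p <- sim_params(N = 50, ploidy = pl, mu = 2e-5, rho = 0,
                    generations = t1, L = 1e4, record_every = 100)
    tr <- run_simulation(p, selection_model("constant", s = 0),
                         seed = 10 + pl, keep_population = FALSE)
    r <- tr$rows
    nfix <- r$n_fixed_cumulative[r$generation == t1] -
      r$n_fixed_cumulative[r$generation == t0]
    expected <- 2e-5 * 1e4 * (t1 - t0)  # 500
    expect_lt(abs(nfix - expected), 3 * sqrt(expected),
              label = sprintf("ploidy %d substitution count", pl))
  }
})

test_that("runs are bit-reproducible given (params, seed)", {
  p <- sim_params(N = 30, ploidy = 4, mu = 5e-6, rho = 1e-7, generations = 400,
                  L = 1e4, record_every = 10, seed = 77,
                  snapshot_generations = c(200L, 400L))
  m <- selection_model("empirical")
  a <- run_simulation(p, m)
  b <- run_simulation(p, m)
  expect_identical(a$rows, b$rows)
  expect_identical(a$offspring_fitness, b$offspring_fitness)
  expect_identical(a$population$individuals, b$population$individuals)
  fa <- tempfile(fileext = ".tsv")
  fb <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(a, fa)
  write_trajectory_tsv(b, fb)
  expect_identical(readLines(fa), readLines(fb))  # byte-identical output
  unlink(c(fa, fb))
})

test_that("a zero-generation run reports only the founder state", {
  p <- sim_params(N = 10, ploidy = 2, mu = 1e-6, rho = 0, generations = 0,
                  L = 1e4)
  tr <- run_simulation(p, selection_model("constant", s = -0.01), seed = 1)
  expect_equal(nrow(tr$rows), 1L)
  expect_true(is.na(tr$rows$median_allele_freq))
  expect_equal(tr$rows$mean_fitness, 1)
  expect_equal(tr$rows$n_segregating, 0L)
  expect_equal(tr$rows$n_fixed_cumulative, 0L)
})

test_that("stepwise wf_generation + sweep matches the compiled run loop", {
  p <- sim_params(N = 15, ploidy = 4, mu = 2e-5, rho = 1e-6, generations = 40,
                  L = 1e4, record_every = 40)
  m <- selection_model("constant", s = -0.02)
  full <- run_simulation(p, m, seed = 99)
  set.seed(99)
  pop <- new_population(p)
  for (g in 1:40) pop <- sweep_fixations(wf_generation(pop, m))
  expect_identical(pop$individuals, full$population$individuals)
  row <- summarize_generation(pop)
  last <- full$rows[nrow(full$rows), ]
  expect_equal(row$median_allele_freq, last$median_allele_freq)
  expect_equal(row$mean_fitness, last$mean_fitness)
  expect_equal(row$n_segregating, last$n_segregating)
  expect_equal(row$n_fixed_cumulative, last$n_fixed_cumulative)
})

test_that("trajectories are invariant to genome rescaling holding mu*L and rho*L", {
  # L x 1/10 with per-bp rates x 10: end-state distributions indistinguishable
  m <- selection_model("constant", s = -0.01)
  run_end <- function(L, mu, rho, seed) {
    p <- sim_params(N = 50, ploidy = 4, mu = mu, rho = rho, generations = 1500,
                    L = L, record_every = 50)
    r <- run_simulation(p, m, seed = seed, keep_population = FALSE)$rows
    c(af = r$median_allele_freq[nrow(r)], seg = r$n_segregating[nrow(r)],
      fit = r$mean_fitness[nrow(r)])
  }
  a <- t(sapply(1:12, function(i) run_end(2e4, 5e-6, 1e-7, 1000 + i)))
  b <- t(sapply(1:12, function(i) run_end(2e3, 5e-5, 1e-6, 2000 + i)))
  for (col in c("af", "seg", "fit")) {
    ks <- suppressWarnings(stats::ks.test(a[, col], b[, col]))
    expect_gt(ks$p.value, 0.01)
  }
})
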