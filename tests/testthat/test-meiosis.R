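test_that("bivalent pairing is uniform over the three matchings and seeded", {
  expect_error(pair_bivalents(list(integer(0), integer(0))))
  canon <- function(pr) {
    pairs <- lapply(pr, sort)
    paste(sapply(pairs[order(sapply(pairs, `[`, 1))], paste, collapse = ","),
          collapse = "|")
  }
  ind <- replicate(4, integer(0), simplify = FALSE)
  set.seed(123)
  n <- 30000
  draws <- replicate(n, canon(pair_bivalents(ind)))
  tab <- table(draws)
  expect_setequal(names(tab), c("1,2|3,4", "1,3|2,4", "1,4|2,3"))
  # each matching 1/3 within 3 binomial SEs
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(tab / n - 1 / 3) < 3 * se))
  # seeded determinism
  set.seed(5); a <- replicate(200, canon(pair_bivalents(ind)))
  set.seed(5); b <- replicate(200, canon(pair_bivalents(ind)))
  expect_identical(a, b)
})

test_that("recombination respects zero rate, breakpoints, and Poisson mean", {
  muts <- mut_table(3, L = 1000)  # positions 0, 499, 999
  r <- recombine_pair(c(1L, 2L, 3L), integer(0), muts, rho = 0, L = 1000)
  expect_identical(r$product1, c(1L, 2L, 3L))
  expect_identical(r$product2, integer(0))
  expect_identical(r$n_crossovers, 0L)

  # single forced breakpoint at boundary 500: positions < 500 stay, >= 500 swap
  r <- recombine_pair(c(1L, 2L, 3L), integer(0), muts, rho = 0, L = 1000,
                      breakpoints = 500)
  expect_identical(r$product1, c(1L, 2L))
  expect_identical(r$product2, 3L)
  # reciprocal: mutation at 10 on hapA, forced breakpoint leaves it in place
  m1 <- data.frame(id = 1L, position = 10, s = -0.01, h = 0,
                   origin_generation = 0L)
  r <- recombine_pair(1L, integer(0), m1, rho = 0, L = 1000, breakpoints = 500)
  expect_identical(r$product1, 1L)
  expect_identical(r$product2, integer(0))

  # crossover count mean rho*(L-1) ~ 0.1
  set.seed(11)
  n <- 1e5
  k <- replicate(n, recombine_pair(integer(0), integer(0), mut_table(0),
                                   rho = 1e-7, L = 1e6)$n_crossovers)
  lambda <- 1e-7 * (1e6 - 1)
  expect_lt(abs(mean(k) - lambda), 3 * sqrt(lambda / n))
})

test_that("gamete dosage distributions match the bivalent enumeration oracle", {
  # oracle agrees with the closed-form hypergeometric(4, d, 2)
  for (d in 0:4)
    expect_equal(unname(enum_gamete_dosage(d)), dhyper(0:2, d, 4 - d, 2))
  # engine gametes match the oracle for every parental dosage
  n <- 20000
  for (d in 0:4) {
    emp <- sim_gamete_dosage(d, n = n, seed = 100 + d)
    expected <- unname(enum_gamete_dosage(d))
    se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
    expect_true(all(abs(emp - expected) <= 3 * se + 1e-12),
                label = sprintf("dosage %d within 3 SE", d))
  }
  # triplex parent never transmits zero mutant copies; simplex never two
  expect_equal(sim_gamete_dosage(3, n = 2000, seed = 1)[1], 0)
  expect_equal(sim_gamete_dosage(1, n = 2000, seed = 2)[3], 0)
})

test_that("diploid heterozygote transmits the mutation half the time", {
  muts <- mut_table(1)
  p <- sim_params(N = 2, ploidy = 2, mu = 0, rho = 0, generations = 1, L = 1e4)
  set.seed(3)
  n <- 20000
  carry <- replicate(n, length(make_gamete(list(1L, integer(0)), p, muts)[[1]]))
  expect_lt(abs(mean(carry) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("tetraploid gametes never show double reduction", {
  # four distinguishable chromosomes: a gamete must carry two different tags
  muts <- mut_table(4)
  ind <- list(1L, 2L, 3L, 4L)
  p <- sim_params(N = 2, ploidy = 4, mu = 0, rho = 0, generations = 1, L = 1e4)
  set.seed(17)
  for (i in 1:2000) {
    g <- make_gamete(ind, p, muts)
    expect_length(g, 2L)
    expect_false(identical(g[[1]], g[[2]]))
  }
})

test_that("mutation adds Poisson(mu*L) distinct stacked alleles", {
  p0 <- sim_params(N = 2, ploidy = 2, mu = 0, rho = 0, generations = 1, L = 1e4)
  m <- selection_model("constant", s = -0.005)
  res <- mutate_gamete(list(c(1L)), p0, m, generation = 1,
                       mutations = mut_table(1))
  expect_identical(res$gamete[[1]], 1L)  # mu = 0: unchanged

  # mean new mutations per chromosome = mu*L
  p <- sim_params(N = 2, ploidy = 2, mu = 1e-7, rho = 0, generations = 1, L = 1e6)
  set.seed(21)
  n <- 2e4
  counts <- replicate(n, {
    length(mutate_gamete(list(integer(0)), p, m, 1, NULL)$gamete[[1]])
  })
  lambda <- 1e-7 * 1e6
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / n))

  # stacking: with L = 1 every mutation hits position 0 yet all ids distinct
  p1 <- sim_params(N = 2, ploidy = 2, mu = 5, rho = 0, generations = 1, L = 1)
  set.seed(8)
  res <- mutate_gamete(list(integer(0)), p1, m, 1, NULL)
  hap <- res$gamete[[1]]
  expect_gt(length(hap), 1)
  expect_equal(length(unique(hap)), length(hap))
  expect_true(all(res$mutations$position == 0))
})
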