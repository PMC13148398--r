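# Shared builders and oracles for the test suite.

# Hand-built population with explicit haplotypes and mutation registry.
# `individuals` is a list of N lists of `ploidy` integer id vectors; ids must
# be contiguous 1..K rows of `mutations`.
make_test_pop <- function(individuals, mutations, ploidy,
                          params = NULL, generation = 0L) {
  N <- length(individuals)
  if (is.null(params))
    params <- sim_params(N = N, ploidy = ploidy, mu = 0, rho = 0,
                         generations = 1, L = 1e4)
  fitness <- vapply(individuals, function(ind) individual_fitness(ind, mutations),
                    numeric(1))
  structure(
    list(individuals = individuals, fitness = fitness,
         generation = as.integer(generation), mutations = mutations,
         substitutions = data.frame(id = integer(0),
                                    fixation_generation = integer(0)),
         parents = NULL, parental_mean_fitness = NA_real_, params = params),
    class = "wf_population")
}

# Registry of n mutations at spread-out positions.
mut_table <- function(n, s = -0.01, h = 0, L = 1e4) {
  if (n == 0) return(data.frame(id = integer(0), position = numeric(0),
                                s = numeric(0), h = numeric(0),
                                origin_generation = integer(0)))
  data.frame(id = seq_len(n),
             position = floor(seq(0, L - 1, length.out = n)),
             s = rep_len(s, n), h = rep_len(h, n), origin_generation = 0L)
}

# A tetraploid individual carrying mutation id 1 on `d` of its 4 copies.
tetra_dosage_ind <- function(d) {
  c(rep(list(1L), d), rep(list(integer(0)), 4 - d))
}

# Independent oracle for the tetraploid gamete dosage distribution: exhaustive
# enumeration of the 3 bivalent pairings x 2x2 segregation choices (12 equally
# likely outcomes), without reference to the engine or to dhyper.
enum_gamete_dosage <- function(d) {
  chr <- c(rep(1, d), rep(0, 4 - d))
  pairings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  out <- numeric(3)
  for (p in pairings) for (i in 1:2) for (j in 1:2) {
    dos <- chr[p[1, i]] + chr[p[2, j]]
    out[dos + 1] <- out[dos + 1] + 1 / 12
  }
  names(out) <- as.character(0:2)
  out
}

# Monte-Carlo gamete dosage distribution from the engine for a parent with
# mutant dosage d (target mutation id 1), rho = 0.
sim_gamete_dosage <- function(d, n = 20000, seed = 99) {
  muts <- mut_table(1)
  ind <- tetra_dosage_ind(d)
  p <- sim_params(N = 2, ploidy = 4, mu = 0, rho = 0, generations = 1, L = 1e4)
  set.seed(seed)
  draws <- replicate(n, {
    g <- make_gamete(ind, p, muts)
    sum(unlist(g) == 1L)
  })
  tabulate(draws + 1L, nbins = 3) / n
}

# Exemplar run: N = 100, mu = 1e-7, s = -0.005, rho = 1e-10 at full scale,
# desk-scaled by 10 (L = 1e5 with per-bp rates x10, holding mu*L and rho*L).
fig1_model <- function() selection_model("constant", s = -0.005)

fig1_params <- function(ploidy, generations = 8000) {
  sim_params(N = 100, ploidy = ploidy, mu = 1e-6, rho = 1e-9,
             generations = generations, L = 1e5, record_every = 10,
             snapshot_generations = generations)
}

# Runs at the exemplar parameters are shared across test files.
.podsim_run_cache <- new.env(parent = emptyenv())

cached_fig1_run <- function(ploidy, seed, generations = 8000) {
  key <- sprintf("p%d_s%d_g%d", ploidy, seed, generations)
  if (is.null(.podsim_run_cache[[key]])) {
    .podsim_run_cache[[key]] <- run_simulation(
      fig1_params(ploidy, generations), fig1_model(), seed = seed,
      keep_population = FALSE)
  }
  .podsim_run_cache[[key]]
}

equilibrium_median_af <- function(traj, last = 1000) {
  r <- traj$rows
  gmax <- max(r$generation)
  mean(r$median_allele_freq[r$generation > gmax - last], na.rm = TRUE)
}
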