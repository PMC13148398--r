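#' Create a mutation-free founder population
#'
#' Populations start from N individuals carrying no mutations: there is no
#' burn-in period, since the object of study is the approach to (and nature
#' of) the equilibrium itself, mirroring a fresh polyploid bottleneck.
#'
#' Inside a `wf_population` the mutation registry rows are the ids: the id of
#' the mutation in row k is k, and ids stay valid after fixation or loss (the
#' registry never shrinks).
#'
#' @param params A [sim_params()] object.
#' @return An object of class `wf_population` with fields `individuals` (list
#'   of N lists of `ploidy` integer haplotypes), `fitness`, `generation`,
#'   `mutations` (registry data frame), `substitutions`, `parents` (1-based
#'   indices of the 2N parent draws that produced the current generation, or
#'   NULL for founders) and `params`.
#' @examples
#' pop <- new_population(sim_params(10, 2, mu = 0, rho = 0, generations = 1))
#' @export
new_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  inds <- replicate(params$N,
                    replicate(params$ploidy, integer(0), simplify = FALSE),
                    simplify = FALSE)
  structure(
    list(individuals = inds, fitness = rep(1, params$N), generation = 0L,
         mutations = .empty_mutation_table(),
         substitutions = data.frame(id = integer(0),
                                    fixation_generation = integer(0)),
         parents = NULL, parental_mean_fitness = NA_real_, params = params),
    class = "wf_population"
  )
}

.empty_mutation_table <- function() {
  data.frame(id = integer(0), position = numeric(0), s = numeric(0),
             h = numeric(0), origin_generation = integer(0))
}

#' @export
print.wf_population <- function(x, ...) {
  af <- allele_frequencies(x)
  cat(sprintf(
    "wf_population: N = %d, ploidy = %d, generation %d\n  %d segregating, %d fixed, mean fitness %.4f\n",
    x$params$N, x$params$ploidy, x$generation, length(af),
    nrow(x$substitutions), mean(x$fitness)))
  invisible(x)
}

#' Random bivalent pairing of a tetraploid's four homologues
#'
#' Draws one of the three perfect matchings of chromosomes 1-4 into two
#' bivalents, each with probability 1/3. Diploids have no pairing choice and
#' calling this on one is an error.
#'
#' @param individual List of 4 haplotypes (integer vectors of mutation ids).
#' @return List of two integer pairs of chromosome indices.
#' @examples
#' set.seed(1)
#' pair_bivalents(list(integer(0), integer(0), integer(0), integer(0)))
#' @export
pair_bivalents <- function(individual) {
  if (length(individual) != 4L)
    stop("bivalent pairing is defined for tetraploids (4 chromosome copies)")
  m <- cpp_pair_bivalents()
  list(m[1:2], m[3:4])
}

#' Recombine two haplotypes
#'
#' Draws a crossover count from Poisson(rho * (L - 1)) and that many
#' breakpoints uniformly on the L - 1 inter-site boundaries (no interference,
#' no gene conversion), and returns the two reciprocal products. A breakpoint
#' at boundary b exchanges material from position b onwards. `breakpoints`
#' overrides the random draw for deterministic construction of recombinants.
#'
#' @param hapA,hapB Integer vectors of mutation ids, position-sorted.
#' @param mutations Mutation registry data frame (columns `id`, `position`).
#' @param rho Per-base-pair crossover rate.
#' @param L Chromosome length.
#' @param breakpoints Optional numeric vector of boundaries in 1..L-1.
#' @return List with `product1`, `product2` (id vectors) and `n_crossovers`.
#' @examples
#' muts <- data.frame(id = 1L, position = 10, s = -0.01, h = 0)
#' recombine_pair(1L, integer(0), muts, rho = 0, L = 1000,
#'                breakpoints = 500)
#' @export
recombine_pair <- function(hapA, hapB, mutations, rho, L, breakpoints = NULL) {
  stopifnot(rho >= 0)
  haps <- .remap_haps(list(hapA, hapB), mutations)
  res <- cpp_recombine(haps[[1]], haps[[2]], as.numeric(mutations$position),
                       rho, L, breakpoints)
  list(product1 = mutations$id[res$product1],
       product2 = mutations$id[res$product2],
       n_crossovers = res$n_crossovers)
}

#' Form one gamete by meiosis
#'
#' Diploids recombine their homologue pair and transmit one product chosen
#' uniformly. Tetraploids draw a random bivalent pairing, recombine within
#' each bivalent independently, and transmit one product per bivalent, chosen
#' uniformly -- the two gamete chromosomes always descend from different
#' bivalents, so double reduction is impossible. New mutations are added
#' separately by [mutate_gamete()].
#'
#' @param individual List of `ploidy` haplotypes.
#' @param params A [sim_params()] (supplies rho and L).
#' @param mutations Mutation registry data frame.
#' @return A gamete: list of `ploidy/2` haplotypes.
#' @examples
#' p <- sim_params(10, 4, mu = 0, rho = 0, generations = 1, L = 1000)
#' muts <- data.frame(id = 1L, position = 10, s = -0.01, h = 0)
#' set.seed(1)
#' make_gamete(list(1L, 1L, 1L, integer(0)), p, muts)  # from a triplex parent
#' @export
make_gamete <- function(individual, params, mutations) {
  stopifnot(length(individual) == params$ploidy)
  haps <- .remap_haps(individual, mutations)
  gam <- cpp_make_gamete(haps, as.numeric(mutations$position), params$rho,
                         params$L)
  lapply(gam, function(g) mutations$id[g])
}

#' Add new mutations to a gamete
#'
#' Each chromosome of the gamete receives Poisson(mu * L) new mutations at
#' uniform positions in \[0, L). Every event creates a distinct allele with
#' its own id, even at an already-mutated position (stacking), with (s, h)
#' drawn from the selection model.
#'
#' @param gamete List of haplotypes as returned by [make_gamete()].
#' @param params A [sim_params()].
#' @param model A [selection_model()].
#' @param generation Origin generation recorded on new mutations.
#' @param mutations Current mutation registry; new rows are appended with ids
#'   continuing after `max(mutations$id)`.
#' @return List with the mutated `gamete` and the augmented `mutations`
#'   registry.
#' @examples
#' p <- sim_params(10, 2, mu = 1e-3, rho = 0, generations = 1, L = 1000)
#' set.seed(1)
#' mutate_gamete(list(integer(0)), p, selection_model("constant", s = -0.01),
#'               generation = 1, mutations = NULL)
#' @export
mutate_gamete <- function(gamete, params, model, generation, mutations = NULL) {
  if (is.null(mutations) || nrow(mutations) == 0L) mutations <- .empty_mutation_table()
  haps <- .remap_haps(gamete, mutations)
  res <- cpp_mutate_haps(haps, as.numeric(mutations$position),
                         as.numeric(mutations$s), as.numeric(mutations$h),
                         params$mu, params$L, as.integer(generation), model)
  n0 <- nrow(mutations)
  nn <- length(res$new_position)
  base_id <- if (n0 > 0L) max(mutations$id) else 0L
  ids <- c(mutations$id, base_id + seq_len(nn))
  if (nn > 0L) {
    mutations <- rbind(mutations, data.frame(
      id = base_id + seq_len(nn), position = res$new_position, s = res$new_s,
      h = res$new_h, origin_generation = res$new_origin))
  }
  list(gamete = lapply(res$haplotypes, function(g) ids[g]),
       mutations = mutations)
}

#' Advance a population by one Wright-Fisher generation
#'
#' Produces exactly N offspring. For each offspring two parents are drawn
#' independently with replacement, with probability proportional to fitness
#' (selfing happens at the incidental rate of about 1/N); each parent
#' contributes one recombinant, mutated gamete. Offspring fitness is computed
#' over all mutations carried, including any that reach fixation this
#' generation -- apply [sweep_fixations()] afterwards to convert those to
#' substitutions. The 2N parent draws are recorded in `$parents` and their
#' mean fitness in `$parental_mean_fitness`.
#'
#' @param pop A `wf_population`.
#' @param model A [selection_model()].
#' @return The next-generation `wf_population`.
#' @examples
#' p <- sim_params(10, 2, mu = 1e-6, rho = 0, generations = 1, L = 1e4)
#' set.seed(1)
#' pop <- wf_generation(new_population(p), selection_model("constant", s = -0.01))
#' @export
wf_generation <- function(pop, model) {
  stopifnot(inherits(pop, "wf_population"), inherits(model, "selection_model"))
  pars <- pop$params
  flat <- unlist(pop$individuals, recursive = FALSE)
  res <- cpp_wf_generation(flat, pop$fitness,
                           as.numeric(pop$mutations$position),
                           as.numeric(pop$mutations$s),
                           as.numeric(pop$mutations$h),
                           pars$N, pars$ploidy, pars$L, pars$mu, pars$rho,
                           model, pop$generation + 1L)
  nn <- length(res$new_position)
  if (nn > 0L) {
    n0 <- nrow(pop$mutations)
    pop$mutations <- rbind(pop$mutations, data.frame(
      id = n0 + seq_len(nn), position = res$new_position, s = res$new_s,
      h = res$new_h, origin_generation = res$new_origin))
  }
  pop$individuals <- .split_flat(res$haplotypes, pars$N, pars$ploidy)
  pop$fitness <- res$fitness
  pop$generation <- pop$generation + 1L
  pop$parents <- res$parents
  pop$parental_mean_fitness <- res$parental_mean_fitness
  pop
}

.split_flat <- function(flat, N, ploidy) {
  lapply(seq_len(N), function(i) flat[((i - 1L) * ploidy + 1L):(i * ploidy)])
}

#' Convert fixed mutations to substitutions
#'
#' Any mutation present on all `ploidy * N` chromosomes is removed from every
#' haplotype and appended to the substitution ledger with the current
#' generation; mutations at count zero have already disappeared implicitly.
#' Cached fitnesses are recomputed afterwards, so reported fitness reflects
#' segregating mutations only. Note the implied discontinuity: fixing a
#' recessive deleterious allele multiplies every individual's reported
#' fitness by 1/(1+s).
#'
#' @param pop A `wf_population`.
#' @return The population with fixed mutations swept.
#' @export
sweep_fixations <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  full <- pop$params$ploidy * pop$params$N
  cnt <- .allele_counts(pop)
  fixed <- which(cnt == full)
  if (length(fixed) == 0L) return(pop)
  pop$individuals <- lapply(pop$individuals, function(ind)
    lapply(ind, function(hp) hp[!(hp %in% fixed)]))
  pop$substitutions <- rbind(pop$substitutions, data.frame(
    id = as.integer(fixed), fixation_generation = pop$generation))
  pop$fitness <- vapply(pop$individuals, function(ind)
    cpp_individual_fitness(ind, pop$mutations$position, pop$mutations$s,
                           pop$mutations$h), numeric(1))
  pop
}

.allele_counts <- function(pop) {
  ids <- unlist(pop$individuals, use.names = FALSE)
  tabulate(ids, nbins = nrow(pop$mutations))
}

#' Run a full forward simulation
#'
#' Initialises N mutation-free founders and iterates the Wright-Fisher
#' generation step plus the fixation sweep for `params$generations` steps,
#' recording a trajectory row at generation 0, every `record_every`
#' generations, and at the final generation, plus full offspring-fitness
#' samples at `snapshot_generations`. Statistics describe the offspring
#' population after the fixation sweep; parental fitness is the mean over the
#' 2N parents actually drawn that generation. Bit-exactly reproducible given
#' (params, seed).
#'
#' @param params A [sim_params()].
#' @param model A [selection_model()].
#' @param replicate Replicate label stored in the trajectory.
#' @param seed RNG seed; defaults to `params$seed`. If both are NULL the
#'   current RNG state is used.
#' @param keep_population Retain the final population (for snapshots, VCF
#'   export, or further stepping)?
#' @return An object of class `sim_trajectory`: `rows` (data frame of
#'   trajectory statistics), `params`, `model`, `replicate`, `seed`,
#'   `offspring_fitness` (named list of snapshot fitness vectors),
#'   `substitutions`, and `population` (a `wf_population`, or NULL).
#' @examples
#' p <- sim_params(20, 4, mu = 1e-6, rho = 1e-9, generations = 50, L = 1e4,
#'                 record_every = 10)
#' run_simulation(p, selection_model("constant", s = -0.005), seed = 1)
#' @export
run_simulation <- function(params, model, replicate = 1L, seed = params$seed,
                           keep_population = TRUE) {
  stopifnot(inherits(params, "sim_params"), inherits(model, "selection_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- cpp_run_simulation(params$N, params$ploidy, params$L, params$mu,
                            params$rho, params$generations,
                            params$record_every, params$snapshot_generations,
                            model)
  rows <- data.frame(
    generation = res$generation, median_allele_freq = res$median_allele_freq,
    mean_fitness = res$mean_fitness,
    parental_mean_fitness = res$parental_mean_fitness,
    n_segregating = res$n_segregating,
    n_fixed_cumulative = res$n_fixed_cumulative)
  muts <- data.frame(id = seq_along(res$mut_position),
                     position = res$mut_position, s = res$mut_s,
                     h = res$mut_h, origin_generation = res$mut_origin)
  subs <- data.frame(id = res$sub_id, fixation_generation = res$sub_generation)
  pop <- NULL
  if (keep_population) {
    pop <- structure(
      list(individuals = .split_flat(res$haplotypes, params$N, params$ploidy),
           fitness = res$fitness, generation = params$generations,
           mutations = muts, substitutions = subs, parents = NULL,
           parental_mean_fitness = NA_real_, params = params),
      class = "wf_population")
  }
  snaps <- res$snapshots
  names(snaps) <- as.character(res$snapshot_generations)
  structure(
    list(rows = rows, params = params, model = model,
         replicate = as.integer(replicate),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         offspring_fitness = snaps, substitutions = subs, population = pop),
    class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  last <- x$rows[nrow(x$rows), ]
  cat(sprintf(
    "sim_trajectory: %d recorded generations (0..%d), replicate %d\n  final: median AF %s, mean fitness %.4f, %d segregating, %d fixed\n",
    nrow(x$rows), max(x$rows$generation), x$replicate,
    ifelse(is.na(last$median_allele_freq), "NA",
           sprintf("%.3f", last$median_allele_freq)),
    last$mean_fitness, last$n_segregating, last$n_fixed_cumulative))
  invisible(x)
}
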