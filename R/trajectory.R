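#' Allele frequencies of segregating mutations
#'
#' Frequency of each segregating mutation as carrier chromosome count divided
#' by `ploidy * N`. Fixed mutations never appear: they are swept into the
#' substitution ledger before statistics are taken.
#'
#' @param pop A `wf_population`.
#' @return Named numeric vector of frequencies in (0, 1); names are mutation
#'   ids.
#' @examples
#' p <- sim_params(10, 2, mu = 1e-5, rho = 0, generations = 5, L = 1e4)
#' run <- run_simulation(p, selection_model("constant", s = -0.01), seed = 1)
#' allele_frequencies(run$population)
#' @export
allele_frequencies <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  full <- pop$params$ploidy * pop$params$N
  cnt <- .allele_counts(pop)
  seg <- which(cnt > 0L & cnt < full)
  stats::setNames(cnt[seg] / full, as.character(seg))
}

#' Summarise one generation as a trajectory row
#'
#' Computes the per-generation statistics tracked across a run: the median
#' allele frequency over segregating mutations (the median of an even count
#' averages the two central values; with no segregating mutations the value
#' is NA rather than 0, so mutation-free early generations do not fake a
#' low-frequency signal), mean fitness over all N individuals (segregating
#' mutations only -- fixed ones are excluded by the sweep), the mean fitness
#' of the 2N parents drawn to produce this generation, and the segregating
#' and cumulative fixed mutation counts.
#'
#' @param pop A `wf_population` with current cached fitnesses.
#' @return A one-row data frame with columns `generation`,
#'   `median_allele_freq`, `mean_fitness`, `parental_mean_fitness`,
#'   `n_segregating`, `n_fixed_cumulative`.
#' @export
summarize_generation <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  af <- allele_frequencies(pop)
  data.frame(
    generation = pop$generation,
    median_allele_freq = if (length(af)) stats::median(af) else NA_real_,
    mean_fitness = mean(pop$fitness),
    parental_mean_fitness = pop$parental_mean_fitness,
    n_segregating = length(af),
    n_fixed_cumulative = nrow(pop$substitutions))
}

#' Offspring fitness sample
#'
#' The fitness of every individual in the newly created offspring generation,
#' before any further selection. The contrast between the diploid and
#' tetraploid versions of this distribution (a large vs small mass of
#' low-fitness homozygotes) is the fitness signature distinguishing the two
#' ploidies under pseudo-overdominance.
#'
#' @param pop A `wf_population`.
#' @return Numeric vector of N fitness values.
#' @export
offspring_fitness_sample <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  pop$fitness
}
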