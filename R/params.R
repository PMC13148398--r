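#' Simulation parameters
#'
#' Bundles the demographic and genomic parameters of one forward run:
#' a constant census size `N`, ploidy 2 (diploid) or 4 (tetrasomic
#' autotetraploid), a single chromosome of `L` base pairs, a per-base-pair
#' per-generation mutation rate `mu` and crossover rate `rho`, and the number
#' of generations to simulate. Populations start from mutation-free founders;
#' there is no burn-in.
#'
#' @param N Census population size (constant); at least 2.
#' @param ploidy 2 or 4.
#' @param mu Per-base-pair per-generation deleterious mutation rate.
#' @param rho Per-base-pair per-generation crossover rate.
#' @param generations Number of generations to simulate (>= 0).
#' @param L Chromosome length in base pairs (default 1 Mb).
#' @param seed Optional RNG seed; runs with the same parameters and seed are
#'   bit-exactly reproducible.
#' @param record_every Sampling stride (in generations) for trajectory rows.
#' @param snapshot_generations Generations at which the full vector of
#'   offspring fitness values is retained.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(N = 100, ploidy = 4, mu = 1e-7, rho = 1e-10, generations = 100)
#' @export
sim_params <- function(N, ploidy, mu, rho, generations, L = 1e6, seed = NULL,
                       record_every = 10L, snapshot_generations = integer(0)) {
  N <- as.integer(N)
  ploidy <- as.integer(ploidy)
  generations <- as.integer(generations)
  record_every <- as.integer(record_every)
  stopifnot(
    length(N) == 1L, N >= 2L,
    ploidy %in% c(2L, 4L),
    length(L) == 1L, L >= 1,
    length(mu) == 1L, mu >= 0,
    length(rho) == 1L, rho >= 0,
    generations >= 0L,
    record_every >= 1L
  )
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(N = N, ploidy = ploidy, L = as.numeric(L), mu = as.numeric(mu),
         rho = as.numeric(rho), generations = generations, seed = seed,
         record_every = record_every,
         snapshot_generations = as.integer(snapshot_generations)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher parameters: N = %d, ploidy = %d, L = %g bp\n  mu = %g /bp/gen, rho = %g /bp/gen, %d generations (record every %d)\n",
    x$N, x$ploidy, x$L, x$mu, x$rho, x$generations, x$record_every))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Selection model for new mutations
#'
#' Two modes. `"constant"`: every mutation has the same selection coefficient
#' `s` (<= 0) and is fully recessive (h = 0). `"empirical"`: the magnitude of
#' s is gamma-distributed and made negative, and the dominance coefficient is
#' a deterministic function of s, `h = 1 / (1/theta_intercept - theta_rate *
#' s)`, so that h equals `theta_intercept` for neutral mutations and decays
#' towards 0 as mutations become more deleterious. Defaults follow the DFE
#' estimated from *Arabidopsis lyrata* (gamma alpha = 0.16, beta = 0.0092;
#' theta_intercept = 0.978, theta_rate = 50328).
#'
#' The printed gamma parameters "alpha, beta" are read as shape and scale
#' (mean |s| = alpha * beta). Set `beta_is_mean = TRUE` for the alternative
#' (mean, shape) reading used by some simulators, under which mean |s| = beta.
#'
#' @param mode `"constant"` or `"empirical"`.
#' @param s Selection coefficient for constant mode (<= 0).
#' @param alpha Gamma shape of |s| (empirical mode).
#' @param beta Gamma scale of |s|, or its mean when `beta_is_mean = TRUE`.
#' @param beta_is_mean Interpret `beta` as the mean of |s| rather than the
#'   gamma scale.
#' @param theta_intercept Dominance coefficient at s = 0, in (0, 1].
#' @param theta_rate Rate at which h approaches 0 with declining s (> 0).
#' @return An object of class `selection_model`.
#' @examples
#' selection_model("constant", s = -0.005)
#' selection_model("empirical")
#' @export
selection_model <- function(mode = c("constant", "empirical"), s = -0.005,
                            alpha = 0.16, beta = 0.0092, beta_is_mean = FALSE,
                            theta_intercept = 0.978, theta_rate = 50328) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    stopifnot(length(s) == 1L, s <= 0)
  } else {
    stopifnot(alpha > 0, beta > 0, theta_intercept > 0, theta_intercept <= 1,
              theta_rate > 0)
  }
  scale <- if (beta_is_mean) beta / alpha else beta
  structure(
    list(mode = mode, mode_code = if (mode == "constant") 0L else 1L,
         s = as.numeric(s), alpha = as.numeric(alpha), beta = as.numeric(beta),
         beta_is_mean = isTRUE(beta_is_mean), shape = as.numeric(alpha),
         scale = as.numeric(scale),
         theta_intercept = as.numeric(theta_intercept),
         theta_rate = as.numeric(theta_rate)),
    class = "selection_model"
  )
}

#' @export
print.selection_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Selection model: constant s = %g, fully recessive (h = 0)\n", x$s))
  } else {
    cat(sprintf(
      "Selection model: empirical h-s DFE\n  |s| ~ Gamma(shape = %g, scale = %g) (mean |s| = %g)\n  h(s) = 1 / (1/%g - %g * s)\n",
      x$shape, x$scale, x$shape * x$scale, x$theta_intercept, x$theta_rate))
  }
  invisible(x)
}

#' Dominance coefficient as a function of the selection coefficient
#'
#' The dominance-selection relationship of the empirical DFE:
#' `h = 1 / (1/theta_intercept - theta_rate * s)`. For s <= 0 the denominator
#' is at least `1/theta_intercept`, so h lies in (0, theta_intercept] and
#' decreases monotonically as mutations become more deleterious.
#'
#' @param s Selection coefficient(s), all <= 0.
#' @param theta_intercept Dominance at s = 0.
#' @param theta_rate Decay rate of h with declining s.
#' @return Dominance coefficient(s) in (0, theta_intercept].
#' @examples
#' h_of_s(0)        # 0.978
#' h_of_s(-0.001)
#' @export
h_of_s <- function(s, theta_intercept = 0.978, theta_rate = 50328) {
  if (any(s > 0)) stop("h_of_s is defined for deleterious mutations only (s <= 0)")
  1 / (1 / theta_intercept - theta_rate * s)
}

#' Draw selection and dominance coefficients for new mutations
#'
#' @param n Number of mutations to draw.
#' @param model A [selection_model()].
#' @return A data frame with columns `s` (<= 0) and `h` (in \[0, 1\]).
#' @examples
#' set.seed(1)
#' sample_mutation_effects(5, selection_model("empirical"))
#' @export
sample_mutation_effects <- function(n, model) {
  stopifnot(inherits(model, "selection_model"), n >= 0)
  m <- cpp_sample_effects(as.integer(n), model)
  data.frame(s = m[, "s"], h = m[, "h"])
}
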