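#' Multiplicative fitness of one individual
#'
#' Fitness is the product over distinct mutations carried: a factor `1 + s`
#' for a mutation present on all ploidy copies (homozygous), `1 + h * s` for
#' any partial dosage (1 to ploidy-1 copies), and 1 for absent mutations,
#' clamped at 0 from below. With fully recessive mutations (h = 0) partial
#' dosages contribute nothing, which is the masking effect that
#' pseudo-overdominance exploits. Homozygosity is judged per allele id
#' (infinite-alleles bookkeeping): two mutations at the same site are
#' distinct alleles and never make a homozygote together.
#'
#' @param haplotypes List of `ploidy` integer vectors of mutation ids, one per
#'   chromosome copy.
#' @param mutations Data frame with columns `id`, `s`, `h` describing every
#'   mutation id used.
#' @return Fitness w in \[0, 1\] when all s <= 0.
#' @examples
#' muts <- data.frame(id = 1L, position = 10, s = -0.005, h = 0)
#' individual_fitness(list(1L, 1L), muts)          # homozygous: 0.995
#' individual_fitness(list(1L, integer(0)), muts)  # masked: 1
#' @export
individual_fitness <- function(haplotypes, mutations) {
  stopifnot(is.list(haplotypes), length(haplotypes) %in% c(2L, 4L))
  haps <- .remap_haps(haplotypes, mutations)
  cpp_individual_fitness(haps, as.numeric(mutations$position),
                         as.numeric(mutations$s), as.numeric(mutations$h))
}

# map arbitrary mutation ids onto registry row indices
.remap_haps <- function(haplotypes, mutations) {
  lapply(haplotypes, function(hp) {
    if (length(hp) == 0L) return(integer(0))
    idx <- match(hp, mutations$id)
    if (anyNA(idx)) stop("haplotype carries mutation ids absent from `mutations`")
    as.integer(idx)
  })
}

#' Random-union homozygosity at a biallelic haplotype system
#'
#' Probability that an offspring is homozygous for either of two complementary
#' haplotypes when each of its `ploidy` copies is an independent draw with
#' haplotype frequency `p`: `p^k + (1 - p)^k` for ploidy k. At p = 0.4 this
#' gives 0.52 for diploids but only 0.1552 for tetraploids -- the reduced
#' homozygote formation that keeps fitness high in tetraploid
#' pseudo-overdominance.
#'
#' @param p Haplotype frequency in \[0, 1\] (vectorised).
#' @param ploidy Number of chromosome copies (k >= 1).
#' @return Probability of complete homozygosity.
#' @examples
#' hwe_homozygosity(0.4, 2)  # 0.52
#' hwe_homozygosity(0.4, 4)  # 0.1552
#' @export
hwe_homozygosity <- function(p, ploidy) {
  stopifnot(all(p >= 0 & p <= 1), ploidy >= 1)
  p^ploidy + (1 - p)^ploidy
}

#' Gamete dosage distribution of a tetraploid parent
#'
#' Probability that a bivalent-forming tetraploid parent carrying `d` mutant
#' copies transmits 0, 1, or 2 of them in a gamete, with no recombination.
#' Random bivalent pairing followed by one-chromosome-per-bivalent segregation
#' is equivalent to drawing 2 of the 4 copies without replacement, i.e.
#' hypergeometric(4, d, 2).
#'
#' @param d Parental mutant dosage, 0 to 4.
#' @return Named numeric vector of probabilities for gamete dosages 0, 1, 2.
#' @examples
#' gamete_dosage_probs(2)  # 1/6, 4/6, 1/6
#' @export
gamete_dosage_probs <- function(d) {
  stopifnot(length(d) == 1L, d %in% 0:4)
  pr <- stats::dhyper(0:2, m = d, n = 4L - d, k = 2L)
  names(pr) <- as.character(0:2)
  pr
}

#' Fully homozygous offspring fraction of a tetraploid cross
#'
#' Exact probability that the offspring of two bivalent-forming tetraploid
#' parents carries four identical copies at a two-haplotype (A/a) system with
#' no recombination, from the hypergeometric gamete distributions of each
#' parent. Among crosses where both parents are heterozygous (dosage 1-3) the
#' maximum is 25%, attained by the triplex x triplex (AAAa x AAAa) cross and
#' its mirror image; a diploid heterozygote cross produces 50%.
#'
#' @param parent1_dosage,parent2_dosage Mutant copy number (0-4) of each
#'   parent.
#' @return Probability the offspring is quadruplex or nulliplex (AAAA or
#'   aaaa).
#' @examples
#' cross_homozygote_fraction(3, 3)  # 0.25
#' cross_homozygote_fraction(4, 0)  # 0: all offspring duplex
#' cross_homozygote_fraction(2, 2)  # 1/18
#' @export
cross_homozygote_fraction <- function(parent1_dosage, parent2_dosage) {
  g1 <- gamete_dosage_probs(parent1_dosage)
  g2 <- gamete_dosage_probs(parent2_dosage)
  # quadruplex needs two 2-dose gametes, nulliplex two 0-dose gametes
  unname(g1["2"] * g2["2"] + g1["0"] * g2["0"])
}

#' Maximum homozygous offspring fraction over heterozygous tetraploid crosses
#'
#' Scans all dosage pairs where both parents segregate the two haplotypes
#' (dosage 1-3) and returns the largest fully homozygous offspring fraction.
#'
#' @return A list with the maximising dosage pair and the maximum fraction.
#' @examples
#' max_cross_homozygote_fraction()$fraction  # 0.25
#' @export
max_cross_homozygote_fraction <- function() {
  grid <- expand.grid(d1 = 1:3, d2 = 1:3)
  frac <- mapply(cross_homozygote_fraction, grid$d1, grid$d2)
  i <- which.max(frac)
  list(parent1_dosage = grid$d1[i], parent2_dosage = grid$d2[i],
       fraction = frac[i])
}
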