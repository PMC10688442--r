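#' Population state
#'
#' An individual-based population: two `N x m` matrices of allele signs
#' (`+1`/`-1`, one matrix per allele copy), a logical sex vector and the
#' phenotypes drawn once at each individual's birth. Allele contributions are
#' scaled by `1/(2*sqrt(m))` only when genotypic values are computed, so the
#' stored state is exact integers.
#'
#' @param t Generation index (0 = founding census, environment already
#'   shifted).
#' @param a1,a2 Integer matrices (`N x m`) with entries in `{+1, -1}`: the
#'   two allele copies at each of the `m` loci.
#' @param female Logical vector of length `N`; `TRUE` for females.
#' @param z Numeric phenotypes of length `N` (genotype plus an environmental
#'   deviation drawn at birth).
#' @return An object of class `population_state`.
#' @export
population_state <- function(t, a1, a2, female, z) {
  stopifnot(is.matrix(a1), is.matrix(a2),
            identical(dim(a1), dim(a2)),
            nrow(a1) == length(female), nrow(a1) == length(z))
  structure(list(t = t, a1 = a1, a2 = a2, female = female, z = z),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: generation %d, N = %d (%d female), m = %d loci\n",
              x$t, nrow(x$a1), sum(x$female), ncol(x$a1)))
  invisible(x)
}

#' Census size of a population state
#' @param pop A [population_state()].
#' @return Integer number of individuals.
#' @export
census_size <- function(pop) nrow(pop$a1)

#' Found a population
#'
#' Create the generation-0 population. Under high diversity every allele copy
#' is independently positive with probability 1/2, giving expected
#' allele frequencies of 1/2 at all loci (expected additive genetic variance
#' 0.5 at `m = 25`). Under low diversity the first six loci are fixed for the
#' positive (adaptive) allele and the next six for the negative (maladaptive)
#' allele in every individual, leaving `m - 12` freely segregating loci
#' (expected additive variance 0.26 at `m = 25`) while keeping the expected
#' mean genotype at 0. Loci are exchangeable, so which indices are fixed is
#' immaterial. Sex is assigned independently with probability 1/2 and each
#' founder's phenotype is drawn at birth.
#'
#' @param params A [sim_params()] object.
#' @return A [population_state()] at generation 0.
#' @examples
#' pop <- init_population(sim_params(N0 = 20, seed = 1))
#' census_size(pop)
#' @export
init_population <- function(params) {
  params <- validate_sim_params(params)
  N <- params$N0
  m <- params$m
  a1 <- matrix(sample(c(1L, -1L), N * m, replace = TRUE), N, m)
  a2 <- matrix(sample(c(1L, -1L), N * m, replace = TRUE), N, m)
  if (params$diversity == "low") {
    a1[, 1:6] <- 1L;  a2[, 1:6] <- 1L
    a1[, 7:12] <- -1L; a2[, 7:12] <- -1L
  }
  female <- stats::runif(N) < 0.5
  pop <- population_state(0L, a1, a2, female, z = numeric(N))
  pop$z <- draw_phenotypes(pop, params$sigma_e2)
  pop
}

#' Genotypic values
#'
#' The genotype of individual `i` is the sum of its `2m` signed allele
#' contributions, each `+1/(2*sqrt(m))` or `-1/(2*sqrt(m))`; equivalently
#' `(n_pos - n_neg) / (2*sqrt(m))`. Genotypes are bounded in
#' `[-sqrt(m), sqrt(m)]`.
#'
#' @param pop A non-empty [population_state()].
#' @return Numeric vector of genotypic values `g_i`.
#' @export
genotype_values <- function(pop) {
  if (census_size(pop) == 0) stop("empty population has no genotypes")
  m <- ncol(pop$a1)
  (rowSums(pop$a1) + rowSums(pop$a2)) / (2 * sqrt(m))
}

#' Positive-allele frequencies
#'
#' @param pop A non-empty [population_state()].
#' @return Numeric vector of length `m`: the frequency of the positive allele
#'   at each locus, `count(+1) / (2N)`.
#' @export
allele_frequencies <- function(pop) {
  N <- census_size(pop)
  if (N == 0) stop("no survivors: allele frequencies undefined")
  (colSums(pop$a1 == 1L) + colSums(pop$a2 == 1L)) / (2 * N)
}

#' Additive genetic variance from allele frequencies
#'
#' The allele-frequency (Hardy-Weinberg) form: with allelic substitution
#' effect `1/sqrt(m)` per locus, `sigma_a2 = sum_l 2 p_l (1 - p_l) / m`. It
#' is zero iff every locus is monomorphic and is maximized at 0.5 when all
#' loci segregate at frequency 1/2. The realized-genotype alternative (the
#' sample variance of `g_i`) is available through [genic_variance_genotypic()]
#' and the `sa2_method` switch of [sim_params()].
#'
#' @param p Vector of positive-allele frequencies in `[0, 1]`.
#' @param m Locus count; defaults to `length(p)`.
#' @return The additive genetic variance.
#' @examples
#' additive_genetic_variance(rep(0.5, 25)) # 0.5
#' @export
additive_genetic_variance <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  sum(2 * p * (1 - p)) / m
}

#' Additive genetic variance as realized genotypic variance
#'
#' Sample variance of the genotypic values; provided as a sensitivity check
#' against the allele-frequency estimator.
#'
#' @param g Vector of genotypic values.
#' @return Sample variance of `g` (0 for a single individual).
#' @export
genic_variance_genotypic <- function(g) {
  if (length(g) < 2) return(0)
  stats::var(g)
}

#' Narrow-sense heritability
#'
#' @param sigma_a2 Additive genetic variance.
#' @param sigma_e2 Environmental phenotypic variance.
#' @return `sigma_a2 / (sigma_a2 + sigma_e2)`.
#' @examples
#' heritability(0.5, 0.5)  # 0.5
#' heritability(0.26, 0.5) # about 0.34
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0)
  if (sigma_a2 + sigma_e2 == 0)
    stop("heritability undefined when both variance components are zero")
  sigma_a2 / (sigma_a2 + sigma_e2)
}

#' Counts of fixed loci
#'
#' @param p Vector of positive-allele frequencies.
#' @return Named integer vector: `pos` (loci with `p == 1`) and `neg`
#'   (loci with `p == 0`).
#' @export
fixation_counts <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  c(pos = sum(p == 1), neg = sum(p == 0))
}
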