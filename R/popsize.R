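#' Probability of the full multi-locus target genotype
#'
#' With Q unlinked loci each carrying the desired genotype with probability
#' P, an individual carries the complete target genotype with probability
#' P^Q.
#'
#' @param p per-locus probability of the desired genotype (the segregation
#'   ratio P), in (0, 1].
#' @param n_loci number of unlinked target loci Q (>= 1).
#' @return P^Q.
#' @examples
#' multi_locus_probability(0.46875, 2)  # 0.2197 to 4 d.p.
#' @export
multi_locus_probability <- function(p, n_loci = 1L) {
  check_prob(p, "p", zero_ok = TRUE)
  if (!is_count(n_loci) || n_loci < 1) stop("n_loci must be an integer >= 1")
  p^n_loci
}

#' Probability that a population fails to yield enough positives
#'
#' The number of individuals carrying the complete target genotype in a
#' population of size n is Binomial(n, P^Q). Failure is observing fewer
#' than R of them: BinomialCDF(R - 1; n, P^Q), evaluated exactly (no normal
#' or Poisson approximation).
#'
#' @param n population size (>= 0).
#' @param p per-locus probability of the desired genotype.
#' @param n_loci number of unlinked target loci Q.
#' @param n_required required number R of positive individuals (>= 0).
#' @return the failure probability.
#' @examples
#' failure_probability(33, 0.5, 1, 10)  # ~ 0.00677
#' @export
failure_probability <- function(n, p, n_loci = 1L, n_required = 1L) {
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (!is_count(n_required) || n_required < 0)
    stop("n_required must be a non-negative integer")
  p_eff <- multi_locus_probability(p, n_loci)
  if (n_required == 0L) return(0)
  stats::pbinom(n_required - 1L, n, p_eff)
}

#' Population size for at least one positive individual
#'
#' The smallest n such that the chance of finding no individual with the
#' full target genotype is at most the acceptable failure risk F:
#' (1 - P^Q)^n <= F, i.e. n(1) = ceiling(log F / log(1 - P^Q)), verified by
#' direct evaluation at n and n - 1 to guard against floating-point edge
#' cases. Optional map distances D (Morgans) fold recombinant selection
#' into the per-locus probability, which becomes P * D.
#'
#' @param p per-locus probability of the desired genotype.
#' @param n_loci number of unlinked target loci Q.
#' @param risk acceptable failure risk F, in (0, 1).
#' @param morgans optional map distance(s) D in Morgans for recombinant
#'   selection, one per locus (recycled if scalar), each in (0, 1].
#' @return a [sizing_result].
#' @examples
#' n_at_least_one(0.5, risk = 0.05, morgans = 0.01)$n  # 598
#' @export
n_at_least_one <- function(p, n_loci = 1L, risk = 0.05, morgans = NULL) {
  check_prob(risk, "risk", one_ok = FALSE, zero_ok = FALSE)
  p_eff <- effective_probability(p, n_loci, morgans)
  if (p_eff == 0)
    stop("the target genotype has probability 0; no finite population suffices")
  if (p_eff == 1) return(make_sizing(1L, p_eff, 1L, risk))
  n <- ceiling(log(risk) / log(1 - p_eff))
  # verify the analytic ceiling against direct evaluation
  while (n > 1 && (1 - p_eff)^(n - 1) <= risk) n <- n - 1
  while ((1 - p_eff)^n > risk) n <- n + 1
  make_sizing(as.integer(n), p_eff, 1L, risk)
}

#' Minimal population size for R positive individuals
#'
#' The smallest n whose failure probability BinomialCDF(R - 1; n, P^Q) does
#' not exceed the acceptable risk F. Because the failure probability is
#' strictly decreasing in n, the search brackets the answer exponentially
#' starting from the mean-based lower bound R / P^Q and then bisects.
#'
#' A population size passes when its failure probability is less than or
#' equal to F (inclusive boundary).
#'
#' @inheritParams n_at_least_one
#' @param n_required required number R of positive individuals (>= 1).
#' @return a [sizing_result].
#' @examples
#' population_size(0.5, n_required = 10, risk = 0.01)$n               # 33
#' population_size(0.5, n_required = 2, risk = 0.05, morgans = 0.01)$n # 947
#' @export
population_size <- function(p, n_loci = 1L, n_required = 1L, risk = 0.05,
                            morgans = NULL) {
  check_prob(risk, "risk", one_ok = FALSE, zero_ok = FALSE)
  if (!is_count(n_required) || n_required < 1)
    stop("n_required must be an integer >= 1")
  p_eff <- effective_probability(p, n_loci, morgans)
  if (p_eff == 0)
    stop("the target genotype has probability 0; no finite population suffices")
  if (p_eff == 1) return(make_sizing(n_required, p_eff, n_required, risk))
  fails <- function(n) stats::pbinom(n_required - 1L, n, p_eff) > risk
  lo <- max(n_required, floor(n_required / p_eff))
  while (lo > n_required && !fails(lo)) lo <- max(n_required, floor(lo / 2))
  hi <- max(lo, n_required)
  while (fails(hi)) { lo <- hi; hi <- hi * 2L }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (fails(mid)) lo <- mid else hi <- mid
  }
  n <- if (fails(lo)) hi else lo
  while (n > n_required && !fails(n - 1L)) n <- n - 1L
  make_sizing(as.integer(n), p_eff, n_required, risk)
}

#' Population size for recombinant selection
#'
#' Sizing for selection of individuals that carry the desired genotype at
#' each target locus *and* a recombination between the target and a
#' flanking marker, breaking linkage drag. The per-locus probability
#' becomes P * D with D the map distance in Morgans (a recombinant at 1 cM
#' is D = 0.01); the effective per-individual probability is the product
#' over loci, and sizing then proceeds as in [population_size()].
#'
#' @inheritParams population_size
#' @param morgans map distance(s) D in Morgans, required, one per locus.
#' @return a [sizing_result].
#' @examples
#' recombinant_population_size(0.5, morgans = 0.01, n_required = 2,
#'                             risk = 0.05)$n  # 947
#' @export
recombinant_population_size <- function(p, n_loci = 1L, n_required = 1L,
                                        risk = 0.05, morgans) {
  if (missing(morgans) || is.null(morgans))
    stop("recombinant selection requires map distances (morgans)")
  population_size(p, n_loci, n_required, risk, morgans = morgans)
}

#' Naive Mendelian population size
#'
#' The mean-based estimate n = R / P^Q, rounded half away from zero to the
#' nearest integer. In roughly half of real populations the observed number
#' of positives falls below its mean, so this is a consistent underestimate
#' of the size actually needed; it is provided for comparison and reporting
#' only.
#'
#' @inheritParams population_size
#' @return an integer population size.
#' @examples
#' naive_mendelian_n(0.46875, 2, 100)  # 455
#' @export
naive_mendelian_n <- function(p, n_loci = 1L, n_required = 1L) {
  p_eff <- multi_locus_probability(p, n_loci)
  if (p_eff <= 0) stop("per-individual probability must be positive")
  x <- n_required / p_eff
  as.integer(floor(x + 0.5))
}

#' Expected number of positive individuals
#'
#' @inheritParams population_size
#' @param n population size.
#' @return n * P^Q, the mean count of individuals with the full target
#'   genotype.
#' @examples
#' expected_positives(145, 0.5, 4)  # 9.0625
#' @export
expected_positives <- function(n, p, n_loci = 1L) {
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  n * multi_locus_probability(p, n_loci)
}

#' @rdname population_size
#' @section Sizing results:
#' `sizing_result` objects carry the chosen population size `n`, the
#' per-individual probability `effective_p` actually used (P^Q, or the
#' product of P * D_i under recombinant selection), the failure probability
#' achieved at `n` and at `n - 1`, and the expected number of positives.
#' @name sizing_result
NULL

make_sizing <- function(n, p_eff, n_required, risk) {
  n <- as.integer(n)
  structure(list(
    n = n,
    effective_p = p_eff,
    n_required = as.integer(n_required),
    risk = risk,
    achieved_failure = stats::pbinom(n_required - 1L, n, p_eff),
    failure_at_n_minus_1 = if (n > 0)
      stats::pbinom(n_required - 1L, n - 1L, p_eff) else 1,
    expected_positives = n * p_eff
  ), class = "sizing_result")
}

#' @export
print.sizing_result <- function(x, ...) {
  cat("<sizing_result>\n")
  cat(sprintf("  required population size n : %d\n", x$n))
  cat(sprintf("  effective per-plant prob   : %.6g\n", x$effective_p))
  cat(sprintf("  required positives R       : %d\n", x$n_required))
  cat(sprintf("  failure risk tolerated F   : %.4g\n", x$risk))
  cat(sprintf("  achieved failure prob      : %.4g\n", x$achieved_failure))
  cat(sprintf("  expected positives         : %.4g\n", x$expected_positives))
  invisible(x)
}

effective_probability <- function(p, n_loci, morgans = NULL) {
  check_prob(p, "p", zero_ok = TRUE)
  if (!is_count(n_loci) || n_loci < 1) stop("n_loci must be an integer >= 1")
  if (is.null(morgans)) return(p^n_loci)
  if (any(!is.finite(morgans)) || any(morgans <= 0) || any(morgans > 1))
    stop("map distances must lie in (0, 1] Morgans")
  if (length(morgans) == 1L) morgans <- rep(morgans, n_loci)
  if (length(morgans) != n_loci)
    stop("supply one map distance per locus (got ", length(morgans),
         " for ", n_loci, " loci)")
  prod(p * morgans)
}

check_prob <- function(x, name, zero_ok = FALSE, one_ok = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  lo_bad <- if (zero_ok) x < 0 else x <= 0
  hi_bad <- if (one_ok) x > 1 else x >= 1
  if (lo_bad || hi_bad)
    stop(name, " must be a probability in ",
         if (zero_ok) "[0," else "(0,", if (one_ok) "1]" else "1)")
  invisible(x)
}
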