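#' Simulate a breeding population
#'
#' Draws `n` individuals with `n_loci` unlinked target loci. By default
#' each locus genotype is sampled directly from the closed-form
#' [locus_distribution()]; for selfing generations, `chain = TRUE` instead
#' runs the explicit single-seed-descent Markov chain from a heterozygous
#' F1 (heterozygotes resolve 1:2:1 each generation, homozygotes are
#' absorbing), providing a mechanistic cross-check of the closed form.
#'
#' @param gen a [generation_spec()] or label.
#' @param n population size (>= 0).
#' @param n_loci number of unlinked loci.
#' @param chain logical; simulate the explicit selfing chain instead of the
#'   closed-form distribution (selfing generations only).
#' @param seed optional integer seed; when supplied the caller's RNG state
#'   is left untouched and results are reproducible.
#' @return a list with `locus_counts` (3 x n_loci matrix of genotype
#'   counts), `class_counts` (table of multi-locus genotype classes, coded
#'   per locus as F/H/U), and `n`.
#' @examples
#' sim <- simulate_population("F5", n = 1000, seed = 1)
#' sim$locus_counts[, 1] / 1000
#' @export
simulate_population <- function(gen, n, n_loci = 1L, chain = FALSE,
                                seed = NULL) {
  gen <- as_generation(gen)
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (!is_count(n_loci) || n_loci < 1) stop("n_loci must be an integer >= 1")
  n <- as.integer(n)
  n_loci <- as.integer(n_loci)
  if (chain && gen$pathway != "selfing")
    stop("chain-mode simulation is defined for selfing generations only")
  codes <- c("F", "H", "U")
  draw <- function() {
    if (n == 0L) return(matrix(character(0), nrow = 0, ncol = n_loci))
    g <- if (chain) {
      m <- matrix("H", nrow = n, ncol = n_loci)
      for (step in seq_len(gen$index - 1L)) {
        het <- m == "H"
        k <- sum(het)
        if (k == 0L) break
        m[het] <- sample(codes, k, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      }
      m
    } else {
      probs <- unname(locus_distribution(gen))
      matrix(sample(codes, n * n_loci, replace = TRUE, prob = probs),
             nrow = n, ncol = n_loci)
    }
    g
  }
  g <- if (is.null(seed)) draw() else with_seed(seed, draw())
  locus_counts <- vapply(seq_len(n_loci), function(j)
    tabulate(match(g[, j], codes), nbins = 3L), integer(3))
  dimnames(locus_counts) <- list(c("hom_fav", "het", "hom_unfav"),
                                 paste0("locus", seq_len(n_loci)))
  class_counts <- if (n == 0L) table(character(0)) else
    table(apply(g, 1L, paste0, collapse = ""))
  list(locus_counts = locus_counts, class_counts = class_counts, n = n)
}

#' Empirical failure probability by Monte Carlo
#'
#' Estimates, over `reps` replicate populations of size `n`, the fraction
#' in which fewer than `n_required` individuals carry the complete target
#' genotype. Each individual succeeds with the effective probability
#' p = P^Q (or the product of P * D_i when map distances are supplied);
#' because the loci are independent, collapsing them to the product
#' probability per individual is exact, and the per-individual Bernoulli
#' draws remain at the plant level. Replicates are processed in chunks to
#' bound memory.
#'
#' @param n population size per replicate.
#' @param p per-locus probability of the desired genotype (or supply `gen`
#'   and `mode` to resolve it via [segregation_ratio()]).
#' @param n_loci number of unlinked loci.
#' @param n_required required number of positives R.
#' @param reps number of replicate populations (>= 1).
#' @param gen,mode optional generation and selection mode resolving `p`.
#' @param morgans optional map distances (Morgans) for recombinant
#'   selection.
#' @param seed optional integer seed.
#' @return a list: `estimate`, binomial `se`, `reps`, `effective_p`, and
#'   the analytic `exact` failure probability for reference.
#' @examples
#' empirical_failure(33, p = 0.5, n_required = 10, reps = 2000, seed = 1)
#' @export
empirical_failure <- function(n, p = NULL, n_loci = 1L, n_required = 1L,
                              reps = 10000L, gen = NULL, mode = "fixed_only",
                              morgans = NULL, seed = NULL) {
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (!is_count(reps) || reps < 1) stop("reps must be an integer >= 1")
  if (!is_count(n_required) || n_required < 0)
    stop("n_required must be a non-negative integer")
  if (is.null(p)) {
    if (is.null(gen)) stop("supply either p or gen")
    p <- segregation_ratio(gen, mode)
  }
  p_eff <- effective_probability(p, n_loci, morgans)
  if (n_required == 0L)
    return(list(estimate = 0, se = 0, reps = reps, effective_p = p_eff,
                exact = 0))
  run <- function() {
    if (n == 0L) return(reps)
    failures <- 0L
    chunk <- max(1L, min(reps, floor(5e6 / max(n, 1L))))
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      hits <- matrix(stats::runif(m * n) < p_eff, nrow = m)
      failures <- failures + sum(rowSums(hits) < n_required)
      done <- done + m
    }
    failures
  }
  failures <- if (is.null(seed)) run() else with_seed(seed, run())
  est <- failures / reps
  list(estimate = est,
       se = sqrt(est * (1 - est) / reps),
       reps = reps, effective_p = p_eff,
       exact = stats::pbinom(n_required - 1L, n, p_eff))
}

#' Simulate recombinant selection in BC-F1 progeny
#'
#' Mechanistic gamete-level simulation of selection for linkage-drag
#' breaking. The F1 parent is heterozygous with the donor target allele and
#' donor flank allele in coupling phase; each BC-F1 individual receives one
#' F1 gamete, recombinant between target and flank with probability `r`
#' (two-point model, double recombinants ignored). A success is a gamete
#' carrying the donor allele at the target and the recipient allele at the
#' flank, which has frequency r/2 — the P * D model with P = 0.5, D = r.
#'
#' @param n number of BC-F1 individuals per replicate.
#' @param r recombination fraction between target and flanking marker,
#'   in \[0, 0.5\].
#' @param reps number of replicates (successes are pooled across all
#'   `n * reps` individuals for the frequency estimate).
#' @param seed optional integer seed.
#' @return a list: `frequency`, `successes`, `total`, `expected` (= r/2).
#' @examples
#' simulate_recombinant_selection(1000, r = 0.01, reps = 50, seed = 1)
#' @export
simulate_recombinant_selection <- function(n, r, reps = 1L, seed = NULL) {
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5)
    stop("r must lie in [0, 0.5]")
  if (!is_count(reps) || reps < 1) stop("reps must be an integer >= 1")
  total <- n * reps
  run <- function() {
    successes <- 0L
    chunk <- 5e6
    done <- 0
    while (done < total) {
      m <- min(chunk, total - done)
      recombinant <- stats::runif(m) < r
      donor_at_target <- stats::runif(m) < 0.5
      successes <- successes + sum(recombinant & donor_at_target)
      done <- done + m
    }
    successes
  }
  successes <- if (is.null(seed)) run() else with_seed(seed, run())
  list(frequency = if (total > 0) successes / total else NaN,
       successes = successes, total = total, expected = r / 2)
}

#' Simulate F2 enrichment followed by fixation
#'
#' Draws F2 individuals (1:2:1), eliminates homozygous-unfavourable plants,
#' and advances each survivor through `t - 1` further rounds of single-seed
#' descent with the generation count restarted at the selected F2 — the
#' same convention as [enriched_ratio()]. Returns the fraction of surviving
#' lineages homozygous favourable at the end, whose expectation is
#' `enriched_ratio(t)` (31/48 at t = 5).
#'
#' @param t generation index reached after enrichment (>= 3), selected F2
#'   as founder.
#' @param n number of F2 individuals drawn before elimination.
#' @param seed optional integer seed.
#' @return a list: `fraction_hom_fav`, `n_kept`, `counts`, `expected`.
#' @examples
#' simulate_enriched_fixation(5, 20000, seed = 1)
#' @export
simulate_enriched_fixation <- function(t, n, seed = NULL) {
  if (!is_count(t) || t < 3) stop("t must be an integer >= 3")
  if (!is_count(n) || n < 1) stop("n must be an integer >= 1")
  codes <- c("F", "H", "U")
  run <- function() {
    f2 <- sample(codes, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    kept <- f2[f2 != "U"]
    for (step in seq_len(t - 1L)) {
      het <- kept == "H"
      k <- sum(het)
      if (k == 0L) break
      kept[het] <- sample(codes, k, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    }
    kept
  }
  kept <- if (is.null(seed)) run() else with_seed(seed, run())
  counts <- tabulate(match(kept, codes), nbins = 3L)
  names(counts) <- c("hom_fav", "het", "hom_unfav")
  list(fraction_hom_fav = if (length(kept)) counts[["hom_fav"]] / length(kept)
       else NaN,
       n_kept = length(kept), counts = counts, expected = enriched_ratio(t))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulations never perturb user code.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop("seed must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
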