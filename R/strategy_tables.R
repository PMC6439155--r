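#' Two-stage F2-enrichment selection plan
#'
#' Sizes a two-stage marker-assisted selection scheme under rapid
#' generation advance: stage 1 genotypes the F2 and discards every plant
#' negative (homozygous unfavourable) for any target locus, keeping
#' heterozygotes (per-locus retention probability 0.75); stage 2 genotypes
#' the fixed generation, where enrichment has skewed the per-locus
#' favourable-homozygote ratio to [enriched_ratio()] (31/48 at t = 5,
#' versus 0.46875 unenriched).
#'
#' The overall failure risk F is split evenly across the two stages (F/2
#' each); the split is reported so it can be revisited. Stage 2 is sized
#' first for R positives at risk F/2; stage 1 is then sized so that at
#' least `n` stage-2 candidates survive enrichment, again at risk F/2.
#'
#' Two cost metrics are reported, because "cheaper" can mean either fewer
#' genotyping datapoints or fewer plants standing in the RGA nursery:
#' total genotyped samples (`n_f2 + n_ft`) and plant-generations
#' (`n_f2 + (t_fix - 2) * n_ft`, the enriched cohort being carried from F3
#' to the fixed generation). The single-stage comparator genotypes
#' `n_single` plants once but carries them for `t_fix - 1` generations.
#'
#' @param n_loci number of unlinked target loci Q.
#' @param n_required required number R of fixed-positive lines.
#' @param risk overall acceptable failure risk F.
#' @param t_fix fixed generation at which stage-2 selection is applied
#'   (counted with the selected F2 as founder; default 5).
#' @return a list of class `two_stage_plan` with stage sizes, cost metrics
#'   and the single-stage comparator.
#' @examples
#' two_stage_plan(3, 50, 0.01)
#' @export
two_stage_plan <- function(n_loci, n_required, risk, t_fix = 5L) {
  if (!is_count(n_loci) || n_loci < 1) stop("n_loci must be an integer >= 1")
  if (!is_count(n_required) || n_required < 1)
    stop("n_required must be an integer >= 1")
  check_prob(risk, "risk", one_ok = FALSE, zero_ok = FALSE)
  if (!is_count(t_fix) || t_fix < 3) stop("t_fix must be an integer >= 3")
  stage_risk <- risk / 2
  p_enriched <- enriched_ratio(t_fix)
  s2 <- population_size(p_enriched, n_loci, n_required, stage_risk)
  p_keep <- segregation_ratio("F2", "include_het")  # 0.75 per locus
  s1 <- population_size(p_keep, n_loci, s2$n, stage_risk)
  p_single <- locus_distribution(generation_spec("selfing", t_fix))[["hom_fav"]]
  single <- population_size(p_single, n_loci, n_required, risk)
  structure(list(
    n_loci = as.integer(n_loci), n_required = as.integer(n_required),
    risk = risk, stage_risk = stage_risk, t_fix = as.integer(t_fix),
    n_f2 = s1$n, n_ft = s2$n,
    stage1 = s1, stage2 = s2,
    total_genotyped = s1$n + s2$n,
    plant_generations = s1$n + (t_fix - 2L) * s2$n,
    single_stage_n = single$n,
    single_stage_genotyped = single$n,
    single_stage_plant_generations = (t_fix - 1L) * single$n,
    single_stage = single
  ), class = "two_stage_plan")
}

#' @export
print.two_stage_plan <- function(x, ...) {
  cat("<two_stage_plan>  Q =", x$n_loci, " R =", x$n_required,
      " F =", format(x$risk), " (F/2 per stage)\n")
  cat(sprintf("  stage 1 (F2 enrichment, p = 0.75/locus) : n = %d\n", x$n_f2))
  cat(sprintf("  stage 2 (F%d fixation,  p = %.5g/locus) : n = %d\n",
              x$t_fix, enriched_ratio(x$t_fix), x$n_ft))
  cat(sprintf("  total genotyped samples    : %d (single-stage: %d)\n",
              x$total_genotyped, x$single_stage_genotyped))
  cat(sprintf("  plant-generations in RGA   : %d (single-stage: %d)\n",
              x$plant_generations, x$single_stage_plant_generations))
  invisible(x)
}

#' Compare single-stage, two-stage and F2-only selection strategies
#'
#' @inheritParams two_stage_plan
#' @return a data.frame with one row per strategy: single-stage fixed
#'   generation, two-stage (F2 enrichment + fixed generation), and F2-only
#'   selection retaining heterozygotes.
#' @examples
#' compare_strategies(2, 100, 0.01)
#' @export
compare_strategies <- function(n_loci, n_required, risk, t_fix = 5L) {
  plan <- two_stage_plan(n_loci, n_required, risk, t_fix)
  f2_only <- population_size(segregation_ratio("F2", "include_het"),
                             n_loci, n_required, risk)
  data.frame(
    strategy = c(sprintf("single_stage_F%d", t_fix), "two_stage",
                 "F2_only_include_het"),
    n_genotyped = c(plan$single_stage_genotyped, plan$total_genotyped,
                    f2_only$n),
    plant_generations = c(plan$single_stage_plant_generations,
                          plan$plant_generations, f2_only$n),
    effective_p = c(plan$single_stage$effective_p, NA, f2_only$effective_p),
    stringsAsFactors = FALSE
  )
}

#' Reference population-size tables
#'
#' Regenerates the two standard sizing tables for rapid generation advance
#' at failure risk F = 0.01: table 1, marker-assisted forward breeding with
#' selection in the F5 (per-locus P = 0.46875) for R in {50, 100, 200}
#' fixed-positive lines; table 2, line augmentation foreground selection in
#' BC-F1 progeny (per-locus P = 0.5) for R in {5, 10, 20} heterozygous-
#' positive lines. Rows cover 1 to 5 target loci. All entries are
#' exact-minimal sizes under the inclusive boundary convention.
#'
#' @param table 1 (forward breeding) or 2 (line augmentation).
#' @param risk failure risk (default 0.01, the tables' convention).
#' @return a data.frame: `n_loci` plus one column per R value.
#' @examples
#' size_table(2)
#' @export
size_table <- function(table = 1L, risk = 0.01) {
  if (!table %in% c(1L, 2L)) stop("table must be 1 or 2")
  if (table == 1L) {
    p <- segregation_ratio("F5", "fixed_only")
    r_values <- c(50L, 100L, 200L)
  } else {
    p <- segregation_ratio("BC1", "include_het")
    r_values <- c(5L, 10L, 20L)
  }
  out <- data.frame(n_loci = 1:5)
  for (r in r_values)
    out[[paste0("R", r)]] <- vapply(
      1:5, function(q) population_size(p, q, r, risk)$n, integer(1))
  out
}
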