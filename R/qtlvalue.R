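#' Absolute QTL effect from PVE
#'
#' The percentage of variance explained (PVE, the mapping r^2) is relative
#' to the phenotypic range of one mapping population, so a high PVE in a
#' narrow population can hide a biologically small effect. A
#' population-free proxy for the absolute effect is the product of PVE and
#' the population's trait variance, in squared trait units.
#'
#' @param pve proportion of variance explained, in \[0, 1\].
#' @param population_variance trait variance of the mapping population.
#' @return `pve * population_variance`.
#' @export
absolute_effect_from_pve <- function(pve, population_variance) {
  check_prob(pve, "pve", zero_ok = TRUE)
  if (!is.numeric(population_variance) || length(population_variance) != 1L ||
      !is.finite(population_variance) || population_variance < 0)
    stop("population_variance must be a single non-negative number")
  pve * population_variance
}

#' QTL effect from genotypic class means
#'
#' Difference between the mean trait value of favourable homozygotes and
#' that of unfavourable homozygotes, in trait units. For near-isogenic
#' materials this reduces to the mean difference from the recipient
#' parent. Plain arithmetic means, no outlier handling.
#'
#' @param favourable numeric trait values of the favourable-homozygote
#'   class (non-empty).
#' @param unfavourable numeric trait values of the unfavourable-homozygote
#'   class (non-empty).
#' @return mean(favourable) - mean(unfavourable).
#' @examples
#' class_mean_effect(c(5, 7), c(1, 3))  # 4
#' @export
class_mean_effect <- function(favourable, unfavourable) {
  if (length(favourable) == 0L || !is.numeric(favourable))
    stop("favourable class values must be a non-empty numeric vector")
  if (length(unfavourable) == 0L || !is.numeric(unfavourable))
    stop("unfavourable class values must be a non-empty numeric vector")
  mean(favourable) - mean(unfavourable)
}

#' Attenuation of indirect selection through a proxy trait
#'
#' Selecting on a QTL mapped for a correlated proxy trait (for example
#' leaf sodium content standing in for visual salinity injury) delivers
#' only part of the proxy's gain to the target trait: the expected
#' proportional improvement is the product of the QTL's PVE on the proxy
#' and the proxy-target correlation. A QTL explaining 20% of proxy
#' variation with a 0.65 correlation improves the target by only
#' 0.2 x 0.65 = 13%.
#'
#' @param pve_on_proxy PVE of the QTL on the proxy trait, in \[0, 1\].
#' @param proxy_trait_correlation correlation between proxy and target
#'   trait, in \[-1, 1\].
#' @return a list: `proportion` (the product) and `percent`.
#' @examples
#' indirect_selection_attenuation(0.20, 0.65)$percent  # 13
#' @export
indirect_selection_attenuation <- function(pve_on_proxy,
                                           proxy_trait_correlation) {
  check_prob(pve_on_proxy, "pve_on_proxy", zero_ok = TRUE)
  r <- proxy_trait_correlation
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) > 1)
    stop("proxy_trait_correlation must lie in [-1, 1]")
  prop <- pve_on_proxy * r
  list(proportion = prop, percent = 100 * prop)
}

.strategy_cells <- list(
  high_major = "MAS in forward breeding",
  high_minor = "Genomic selection",
  moderate_major = c("Haplotype embedding", "MAS in forward breeding"),
  moderate_minor = c("Pyramiding", "Trait introgression",
                     "Genomic selection"),
  low_major = c("QTL deployment", "Haplotype embedding", "Pyramiding",
                "Trait introgression", "Genomic selection"),
  low_minor = c("QTL deployment", "Pyramiding", "Trait introgression",
                "Genomic selection"))

#' Recommend a deployment strategy for a MAS target
#'
#' The optimal route for capturing the value of a gene or QTL depends on
#' its current frequency among elite lines of the breeding program and on
#' its effect size. Frequency is bucketed high (> 0.80), moderate, or low
#' (< 0.05); effect is minor or major at the 30%-improvement threshold.
#' Genes already common in the program need only forward-breeding
#' selection (major) or genomic selection (minor); rare major genes
#' justify the full QTL-deployment pipeline; rare minor genes face a
#' cost-benefit decision among deployment, pyramiding, trait introgression
#' and genomic selection.
#'
#' Boundary values fall to the lower bucket: a frequency of exactly 0.80
#' is moderate, exactly 0.05 is moderate, and an improvement of exactly
#' 30% is minor.
#'
#' @param frequency favourable-allele frequency among elite breeding
#'   lines, in \[0, 1\].
#' @param effect either `"minor"`/`"major"`, or a numeric percentage
#'   improvement (major when > 30).
#' @return a list: `frequency_class`, `effect_class`, `strategies`
#'   (ordered character vector).
#' @examples
#' deployment_strategy(0.90, "major")  # MAS in forward breeding
#' deployment_strategy(0.01, 45)$strategies[1]  # "QTL deployment"
#' @export
deployment_strategy <- function(frequency, effect) {
  check_prob(frequency, "frequency", zero_ok = TRUE)
  effect_class <- if (is.character(effect)) {
    match.arg(effect, c("minor", "major"))
  } else if (is.numeric(effect) && length(effect) == 1L && is.finite(effect)) {
    if (effect > 30) "major" else "minor"
  } else stop("effect must be \"minor\"/\"major\" or a percentage")
  frequency_class <- if (frequency > 0.80) "high"
    else if (frequency < 0.05) "low" else "moderate"
  list(frequency_class = frequency_class,
       effect_class = effect_class,
       strategies = .strategy_cells[[paste(frequency_class, effect_class,
                                           sep = "_")]])
}
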