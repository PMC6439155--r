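#' Specify a breeding generation
#'
#' A `generation_spec` identifies the population in which single-locus
#' genotypes are to be assessed: a selfing series (F2, F3, ... derived from
#' an F1 by successive single-seed descent), a backcross (genotype assessed
#' in the BC-F1), or doubled haploids.
#'
#' The F1 is taken to be heterozygous at every target locus, and target loci
#' are unlinked and independent.
#'
#' @param pathway one of `"selfing"`, `"backcross"`, `"doubled_haploid"`.
#' @param index generation number. For selfing, `index = t >= 2` denotes the
#'   F_t, reached from the F1 by `t - 1` rounds of selfing. For backcross,
#'   the BC generation (`>= 1`); genotype ratios refer to the BC-F1 progeny
#'   and do not depend on the backcross number. Ignored for doubled haploids.
#' @return an object of class `generation_spec`.
#' @examples
#' generation_spec("selfing", 5)
#' parse_generation("F5")
#' @export
generation_spec <- function(pathway = c("selfing", "backcross", "doubled_haploid"),
                            index = NULL) {
  pathway <- match.arg(pathway)
  if (pathway == "selfing") {
    if (is.null(index) || !is_count(index) || index < 2)
      stop("selfing generations require an integer index t >= 2 (F2, F3, ...)")
  } else if (pathway == "backcross") {
    if (is.null(index)) index <- 1
    if (!is_count(index) || index < 1)
      stop("backcross generations require an integer index >= 1")
  } else {
    index <- NA_integer_
  }
  structure(list(pathway = pathway, index = as.integer(index)),
            class = "generation_spec")
}

#' Parse a generation label
#'
#' Accepts the shorthand used throughout breeding practice: `"F2"`..`"F9"`
#' for selfing generations, `"BC1"`, `"BC2"`, ... (or `"BC1F1"`) for
#' backcrosses, and `"DH"` for doubled haploids.
#'
#' @param label a character scalar.
#' @return a [generation_spec()].
#' @export
parse_generation <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- toupper(gsub("[-_ ]", "", label))
  if (lab == "DH") return(generation_spec("doubled_haploid"))
  if (grepl("^BC[0-9]*(F1)?$", lab)) {
    idx <- sub("^BC([0-9]*)(F1)?$", "\\1", lab)
    return(generation_spec("backcross", if (nzchar(idx)) as.integer(idx) else 1L))
  }
  if (grepl("^F[0-9]+$", lab))
    return(generation_spec("selfing", as.integer(sub("^F", "", lab))))
  stop("cannot parse generation label: ", label)
}

#' @export
print.generation_spec <- function(x, ...) {
  lab <- switch(x$pathway,
    selfing = paste0("F", x$index),
    backcross = paste0("BC", x$index, "-F1"),
    doubled_haploid = "doubled haploid")
  cat("<generation_spec>", lab, "\n")
  invisible(x)
}

#' Single-locus genotype distribution
#'
#' Probabilities of the three genotype classes at one unlinked target locus
#' for a given breeding generation. For a selfing series the heterozygote
#' frequency halves each generation: `p_het(F_t) = (1/2)^(t-1)`, the
#' remainder splitting equally between the two homozygote classes. In BC-F1
#' progeny a donor-derived locus segregates 1:1 heterozygous :
#' homozygous-recipient, so no favourable homozygotes exist. Doubled
#' haploids are fixed one way or the other with equal probability.
#'
#' All of these probabilities are dyadic rationals and are represented
#' exactly in double precision; the three classes always sum to 1 exactly.
#'
#' @param gen a [generation_spec()] (or a label accepted by
#'   [parse_generation()]).
#' @return a named numeric vector `c(hom_fav, het, hom_unfav)`.
#' @examples
#' locus_distribution("F2")   # 0.25, 0.50, 0.25
#' locus_distribution("F5")["hom_fav"]  # 0.46875
#' @export
locus_distribution <- function(gen) {
  gen <- as_generation(gen)
  d <- switch(gen$pathway,
    selfing = {
      p_het <- 0.5^(gen$index - 1L)
      c(hom_fav = (1 - p_het) / 2, het = p_het, hom_unfav = (1 - p_het) / 2)
    },
    backcross = c(hom_fav = 0, het = 0.5, hom_unfav = 0.5),
    doubled_haploid = c(hom_fav = 0.5, het = 0, hom_unfav = 0.5))
  d
}

#' Selection-relevant segregation ratio
#'
#' The per-locus probability P of the desired genotype class: favourable
#' homozygotes only (`"fixed_only"`, the usual target in fixed-generation
#' forward breeding) or favourable homozygote-or-heterozygote
#' (`"include_het"`, used for F2 enrichment and for BC-F1 foreground
#' selection, where the desired class is the heterozygote itself).
#'
#' For a backcross with `mode = "fixed_only"` the ratio is 0 — no favourable
#' homozygotes exist in BC-F1 progeny — returned with a warning so that
#' sizing calls remain total.
#'
#' @inheritParams locus_distribution
#' @param mode `"fixed_only"` or `"include_het"`.
#' @return a probability.
#' @examples
#' segregation_ratio("F5", "fixed_only")   # 0.46875
#' segregation_ratio("F2", "include_het")  # 0.75
#' segregation_ratio("BC1", "include_het") # 0.5
#' @export
segregation_ratio <- function(gen, mode = c("fixed_only", "include_het")) {
  gen <- as_generation(gen)
  mode <- match.arg(mode)
  d <- locus_distribution(gen)
  if (gen$pathway == "backcross") {
    if (mode == "fixed_only") {
      warning("BC-F1 progeny contain no favourable homozygotes; ratio is 0")
      return(0)
    }
    return(unname(d[["het"]]))
  }
  if (mode == "fixed_only") unname(d[["hom_fav"]])
  else unname(d[["hom_fav"]] + d[["het"]])
}

#' Post-enrichment fixation ratio
#'
#' Probability that a line is homozygous favourable at a target locus after
#' two-stage selection: homozygous-unfavourable individuals are eliminated
#' at the F2 (i.e. heterozygotes are retained), and the surviving material
#' is advanced by single-seed descent with the generation count restarted at
#' the selected F2. A surviving F2 is homozygous favourable with probability
#' 1/3 and heterozygous with probability 2/3; the heterozygous branch then
#' follows the ordinary selfing recursion for `t - 1` further rounds, giving
#'
#'   enriched(t) = 1/3 + (2/3) * (1 - (1/2)^(t-1)) / 2 = (2 - 2^(1-t)) / 3.
#'
#' At `t = 5` this is 31/48 (about 0.646, commonly quoted as "approximately
#' 2/3"); as `t` grows all residual heterozygotes resolve and the ratio
#' tends to 2/3. At the moment of selection itself the conditional
#' favourable-homozygote share is 1/3.
#'
#' @param t integer generation index (>= 3) reached after the F2
#'   enrichment, counted with the selected F2 as founder.
#' @return a probability.
#' @examples
#' enriched_ratio(5)  # 31/48
#' @export
enriched_ratio <- function(t) {
  if (!is_count(t) || t < 3)
    stop("enrichment ratio is defined for integer generations t >= 3")
  (2 - 2^(1 - t)) / 3
}

as_generation <- function(gen) {
  if (inherits(gen, "generation_spec")) return(gen)
  if (is.character(gen)) return(parse_generation(gen))
  stop("expected a generation_spec or a label such as \"F5\", \"BC1\", \"DH\"")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
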