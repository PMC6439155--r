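---
title: "Planning marker-assisted selection: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning marker-assisted selection: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masplan)
```

## The segregation model

All sizing in `masplan` rests on a single-locus genotype model. The F1 of
a biparental cross is heterozygous at every target locus; loci are
unlinked and segregate independently. Under single-seed descent the
heterozygote frequency halves each generation,

$$p_\mathrm{het}(F_t) = \left(\tfrac12\right)^{t-1}, \qquad
  p_\mathrm{hom^+}(F_t) = p_\mathrm{hom^-}(F_t) = \tfrac{1 - p_\mathrm{het}(F_t)}{2},$$

giving the familiar ratios 0.25/0.50/0.25 in the F2 and a
favourable-homozygote share of 0.46875 in the F5. BC-F1 progeny of a
backcross segregate 1:1 heterozygous : homozygous-recipient at a
donor-derived locus (there are *no* favourable homozygotes, which is why
requesting fixed-only selection on a backcross returns probability 0 with
a warning rather than an error — sizing stays a total function). Doubled
haploids are fixed either way with probability one half.

These quantities are all dyadic rationals, and dyadic rationals are
represented *exactly* in binary floating point, so the package needs no
rational-number machinery: the three class probabilities sum to exactly 1
for every generation, and `locus_distribution()` agrees bit-for-bit with
an exhaustive enumeration of the one-locus selfing Markov chain (the test
suite checks `t` up to 8 against a matrix-power oracle).

### Selection modes

`segregation_ratio(gen, mode)` resolves the per-locus probability *P* of
the *desired* class: `"fixed_only"` counts favourable homozygotes (the
target when selecting fixed lines); `"include_het"` also counts
heterozygotes, which is the relevant ratio for F2 enrichment (0.75) and
for BC-F1 foreground selection (0.5, the heterozygote itself being the
target).

### Two-stage enrichment and the restarted generation index

A two-stage scheme genotypes the F2, discards plants negative for any
target locus (keeping heterozygotes), and re-selects in the fixed
generation. Conditional on surviving the cull, an F2 is homozygous
favourable with probability 1/3 and heterozygous with probability 2/3.
`masplan` counts post-enrichment generations *with the selected F2 as the
founder of a fresh selfing series*: the heterozygous branch then follows
the ordinary recursion for $t-1$ further rounds, so

$$\mathrm{enriched}(t) = \tfrac13 + \tfrac23 \cdot
  \tfrac{1 - (1/2)^{t-1}}{2} = \frac{2 - 2^{1-t}}{3},$$

which is $31/48 \approx 0.646$ at $t = 5$ — the value usually quoted
loosely as "approximately 2/3" — and tends to exactly $2/3$ as residual
heterozygotes resolve. The alternative convention (counting the F2 cull
as part of the same F1-founded series, i.e. only $t-2$ further rounds)
would give $5/8$ at $t=5$; we prefer the restarted index because it keeps
`enriched_ratio()` and the unenriched `locus_distribution()` formally
parallel — in both, generation $t$ means $t-1$ meioses after the founder —
and the Monte-Carlo enrichment simulator (`simulate_enriched_fixation()`)
implements the identical convention, so the analytic value and the
simulation are never comparing different schemes.

## Population sizing

The number of positives among $n$ independent plants is
$\mathrm{Binomial}(n, P^Q)$. `population_size()` returns the smallest $n$
whose failure probability $\mathrm{CDF}(R-1;\, n,\, P^Q)$ does not exceed
the risk $F$.

Numerical choices:

* **Exact tail evaluation.** The binomial CDF is evaluated by
  `stats::pbinom()`, which computes the tail to near machine precision
  without normal or Poisson approximation; the tests pin it against exact
  integer arithmetic (e.g. $\mathrm{CDF}(9; 33, 1/2) = 58115146/2^{33}$).
* **Inclusive boundary.** A size *passes* when its failure probability is
  $\le F$. Published reference tables for these designs are not uniformly
  exact-minimal under any single convention (some printed entries sit one
  to a few plants above the exact minimum, a few below); `masplan`
  standardizes on the exact minimum and reports the achieved failure
  probability at $n$ and $n-1$ so the boundary is auditable.
* **Search.** Failure probability is strictly decreasing in $n$ (for
  $n \ge R$), so the search brackets exponentially from the mean-based
  lower bound $R/P^Q$ and bisects; for $R=1$ the closed form
  $\lceil \log F / \log(1-P^Q) \rceil$ is used with a direct verification
  step at $n$ and $n-1$. The two routes coincide on a randomized grid in
  the tests.
* **Degenerate inputs.** $P^Q = 1$ gives $n = R$; $P^Q = 0$ is an
  explicit infeasibility error, as is any map distance outside
  $(0, 1]$ Morgans.

### Recombinant selection

Breaking linkage drag requires plants recombinant between the target and
a flanking marker $D$ Morgans away. Following the two-point model, $D$ is
used *directly* as the recombinant-gamete probability for the interval
(1 cM $\Rightarrow$ 0.01) and the per-locus probability becomes $P\cdot D$
— no Haldane or Kosambi mapping-function conversion is applied, and double
recombinants are ignored. At map distances of a few centiMorgans the
difference is far below the granularity of any nursery decision.

### Cost metrics for the two-stage plan

`two_stage_plan()` splits the overall risk evenly, $F/2$ per stage, and
reports the split; an uneven allocation is a legitimate economic choice
the user can emulate by calling the stage sizings directly. Because
"cheaper" is ambiguous, both cost metrics are reported: *total genotyped
samples* ($n_{F2} + n_{F_t}$) and *plant-generations in the RGA nursery*
($n_{F2} + (t-2)\,n_{F_t}$, the enriched cohort being carried from F3 to
fixation, versus $(t-1)\,n$ for the single-stage scheme which grows the
full cohort every generation). For a single locus the two-stage scheme
loses on both counts (sampling twice); by three loci it wins decisively
on plant-generations while still genotyping more samples — which metric
governs depends on local genotyping and nursery costs.

## Monte-Carlo validation

`mcvalidate`-style simulators exist so that no analytic ratio in the
package is trusted on faith:

* `simulate_population()` draws per-locus genotypes either from the
  closed-form distribution or (for selfing series) by running the
  explicit single-seed-descent chain; the two agree within Monte-Carlo
  error.
* `empirical_failure()` estimates the failure probability by replicate
  populations. Since loci are independent, the $Q$ per-locus Bernoulli
  draws are collapsed into one per-plant draw at the product probability —
  an exact reduction, not an approximation — which keeps $10^5$ replicates
  of a 947-plant population inside a few seconds; replicates are chunked
  to bound memory.
* `simulate_recombinant_selection()` is mechanistic at the gamete level:
  a recombination indicator at rate $r$ and an independent
  transmitted-strand choice, so a success (donor allele at target,
  recipient at flank) has frequency $r/2$, recovering the $P\cdot D$
  model with $P = 1/2$, $D = r$.
* `simulate_enriched_fixation()` culls simulated F2s and advances the
  survivors, validating the $31/48$ ratio above.

All simulators take a `seed` and restore the caller's RNG state, so runs
are reproducible and composable. Simulation sizes in the test suite
($10^4$–$10^5$ plants or replicates) are chosen so that three binomial
standard errors separate the tested value from its nearest competing
hypothesis.

What passing these tests shows — and what it does not: the simulators
share the package's model assumptions (unlinked loci, no segregation
distortion, no selection on background genotype, perfect genotyping at
the sizing stage). They validate the *mathematics*, not the biology; real
populations with distorted ratios, linked targets, or marker error need
larger safety margins, which is exactly why the failure-risk parameter
and the marker-grading module exist.

## Marker grading

`evaluate_marker()` computes, against lines of known QTL status, the
false-positive rate (known-negative lines called positive), the
false-negative rate (known-positive lines called negative) and the call
rate. Conventions, each configurable or deliberate:

* heterozygous calls default to *positive* (codominant assays detect the
  favourable allele, and enrichment schemes deliberately keep
  heterozygotes);
* missing calls and unknown-status lines are excluded from the FPR/FNR
  denominators — the call rate is reported separately rather than folded
  into accuracy;
* ranking is ascending by (FPR, FNR, 1 − call rate) with lexicographic
  tie-break, FPR first because a false positive wastes field resources or,
  worse, promotes a QTL-negative line as a donor, while a false negative
  mostly costs the marker's reach across programs.

`mas_success_matrix()` makes the cross-level consequence concrete: a
marker helps in cross (donor, recipient) only if it calls the donor
positive *and* the recipient negative. `generate_panel()` manufactures
panels whose measured rates equal requested values exactly (missingness
is placed first, then miscalls are drawn from the scored lines), which
gives the test suite a round-trip oracle.

## QTL value and deployment

A mapping $r^2$ (PVE) is population-relative; `absolute_effect_from_pve()`
(PVE × population variance) and `class_mean_effect()` (difference of
genotypic class means) are the two population-free proxies offered, and
`indirect_selection_attenuation()` quantifies how selecting on a proxy
trait dilutes gains on the target: a QTL with PVE 0.20 on a proxy
correlated 0.65 with the target delivers only a 13% expected improvement.

`deployment_strategy()` buckets favourable-allele frequency (high > 0.80,
low < 0.05, moderate between) and effect size (major above a 30%
improvement) and returns the recommended route(s), from plain forward
breeding (common major gene) through the full QTL-deployment pipeline
(rare major gene) to genomic selection (minor effects). Both published
bucket boundaries are strict inequalities on both sides, so boundary
values fall to the *lower* bucket (0.80 is moderate, 0.05 is moderate,
exactly 30% is minor); the moderate band is the complement of the other
two. The moderate-frequency recommendations are the one place where the
source tabulation is typographically ambiguous about column membership;
the package assigns {Pyramiding, Trait introgression, Genomic selection}
to minor and {Haplotype embedding, MAS in forward breeding} to major
effects, the reading consistent with the unambiguous high- and
low-frequency rows.

## Interfaces and limitations

The canonical panel format is the documented CSV schema
(`line_id,role,qtl_status,<marker>...`, calls A/B/H/NA); VCF input is a
minimal read-only convenience (GT fields only, favourable allele
designated per site in a sidecar, 1-based positions preserved) and
requires `vcfR`. The `masplan` CLI is a thin wrapper over the R API with
a flat key=value config file; flags override config, and every sizing
call can log its resolved effective probability so unit mistakes
(centiMorgans vs Morgans, per-locus vs per-genotype probabilities) are
auditable.

Out of scope by design: multi-generation recurrent-selection optimization
(sizing is per-generation, matching the RGA workflow), recurrent-parent
genome recovery tracking, linked multi-locus selfing dynamics beyond the
single flanking interval, economic optimization of the risk split, and
QTL mapping itself.
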