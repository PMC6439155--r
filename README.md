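# masplan

Quantitative planning for marker-assisted selection (MAS) in breeding
programs that fix lines by rapid generation advance (RGA, single-seed
descent). `masplan` answers the questions a breeder or pre-breeder faces
when rolling a gene or QTL out through a program:

* **How many plants do I need?** Exact binomial population sizing for
  forward breeding, recombinant selection against linkage drag, and
  line-augmentation backcrossing.
* **Can I trust this marker?** False-positive/false-negative grading of
  candidate diagnostic markers against germplasm panels of known QTL
  status, with per-cross MAS success prediction and QTL profiling.
* **Is this QTL worth deploying, and how?** Effect-size assessment from
  PVE and genotypic class means, indirect-selection attenuation, and a
  frequency-by-effect deployment-strategy recommendation.

Every analytic result is backed by a Monte-Carlo simulator of the
underlying breeding populations.

## The model

An individual carries the desired genotype at one unlinked target locus
with probability *P*, the Mendelian segregation ratio of the relevant
generation: *P* = 0.25 (F2 homozygote), 0.46875 (F5 homozygote), 0.5
(doubled haploid, or heterozygote in BC-F1 progeny), 0.75 (F2 keeping
heterozygotes). With *Q* unlinked loci the per-plant probability is
*P^Q*, and the count of positive plants in a population of *n* is
Binomial(*n*, *P^Q*). The naive estimate *n = R / P^Q* only delivers the
required *R* positives *on average* — about half of real populations fall
short. `masplan` instead fixes an acceptable failure risk *F* and finds
the smallest *n* with

    BinomialCDF(R − 1; n, P^Q) ≤ F

by exact evaluation (for *R* = 1 this reduces to
*n*(1) = log F / log(1 − P^Q)). For recombinant selection — demanding the
donor allele at the target and the recipient allele at a flanking marker
*D* Morgans away — the per-locus probability becomes *P·D*, so a
recombinant at 1 cM contributes a factor 0.005 in a backcross.

## Worked example

Deploying a gene by marker-assisted backcrossing, we want at least two
BC-F1 plants that are heterozygous at the target (*P* = 0.5) and
recombinant at a flanking marker 1 cM away (*D* = 0.01), tolerating a 5%
chance of coming up short:

```r
library(masplan)
population_size(p = segregation_ratio("BC1", "include_het"),
                n_required = 2, risk = 0.05, morgans = 0.01)
#> <sizing_result>
#>   required population size n : 947
#>   effective per-plant prob   : 0.005
#>   required positives R       : 2
#>   failure risk tolerated F   : 0.05
#>   achieved failure prob      : 0.04998
#>   expected positives         : 4.735
```

947 plants give a 95.0% chance of at least two usable recombinants (the
mean yield is ~4.7); 946 plants would fail the 5% risk target. Forward
breeding for ten fixed-positive lines at one locus in the F5 is far
cheaper:

```r
population_size(0.46875, n_required = 10, risk = 0.01)$n
#> [1] 35
naive_mendelian_n(0.46875, n_required = 10)
#> [1] 21   # the mean-based underestimate
```

and the marker side:

```r
panel <- generate_panel(2, 5, markers = data.frame(marker = "m1",
                        fpr = 0, fnr = 0.5), seed = 1)
evaluate_marker(panel, "m1")
#>   marker fpr fnr call_rate n_pos_scored n_neg_scored
#> 1     m1   0 0.5         1            2            5
mas_success_matrix(panel, "m1")$success_fraction
#> [1] 0.5   # the marker silently fails in every cross from the missed donor
```

A command line mirroring the R API is installed as `exec/masplan`:

```sh
masplan size --p 0.5 -Q 1 -R 10 -F 0.01
masplan size-table --table 1
masplan marker-eval --panel panel.csv
masplan qtl-strategy --frequency 0.9 --effect 35
```

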