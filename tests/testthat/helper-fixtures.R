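# Independent oracles and fixtures shared across test files.

# One-locus selfing Markov chain, enumerated by matrix power.
# States: hom_fav, het, hom_unfav; F1 = het; F_t reached after t-1 steps.
selfing_chain_oracle <- function(t) {
  T <- rbind(c(1, 0, 0),
             c(0.25, 0.5, 0.25),
             c(0, 0, 1))
  v <- c(0, 1, 0)
  for (i in seq_len(t - 1L)) v <- as.vector(v %*% T)
  names(v) <- c("hom_fav", "het", "hom_unfav")
  v
}

# Exact binomial lower tail for p = a/2^b expressed in integer arithmetic
# (exact for the modest n used in tests; doubles hold the integers exactly).
exact_cdf_dyadic <- function(kmax, n, num, den) {
  sum(vapply(0:kmax, function(k)
    choose(n, k) * num^k * (den - num)^(n - k), numeric(1))) / den^n
}

# Brute-force minimal n by linear scan from R upward.
scan_min_n <- function(p_eff, n_required, risk) {
  n <- n_required
  while (pbinom(n_required - 1, n, p_eff) > risk) n <- n + 1
  n
}

# The marker-accuracy illustration: two QTL[+] donors crossed with five
# QTL[-] recipients. marker1 misses donor 2 (FNR 1/2, FPR 0); marker2
# calls recipients 2, 4, 5 positive (FPR 3/5, FNR 0); marker3 is perfect.
make_fig5_panel <- function() {
  lines <- data.frame(
    line_id = c("donor1", "donor2", paste0("recip", 1:5)),
    role = c("donor", "donor", rep("recipient", 5)),
    qtl_status = c("positive", "positive", rep("negative", 5)),
    stringsAsFactors = FALSE)
  calls <- cbind(
    marker1 = c("A", "B", rep("B", 5)),
    marker2 = c("A", "A", "B", "A", "B", "A", "A"),
    marker3 = c("A", "A", rep("B", 5)))
  rownames(calls) <- lines$line_id
  genotype_panel(lines, calls)
}

table1_printed <- matrix(
  c(135, 252, 480,
    298, 555, 1050,
    651, 1200, 2258,
    1396, 2580, 4840,
    3001, 5500, 10350),
  ncol = 3, byrow = TRUE,
  dimnames = list(paste0("Q", 1:5), c("R50", "R100", "R200")))

table2_printed <- matrix(
  c(20, 33, 57,
    44, 71, 121,
    89, 147, 250,
    182, 297, 508,
    373, 601, 1016),
  ncol = 3, byrow = TRUE,
  dimnames = list(paste0("Q", 1:5), c("R5", "R10", "R20")))
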