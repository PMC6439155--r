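#' Construct a genotype panel
#'
#' A genotype panel is the substrate for marker grading: a set of breeding
#' lines of known (or unknown) QTL status, together with per-line,
#' per-marker allele calls. Calls are coded `"A"` (the allele designated
#' favourable), `"B"` (the alternative), `"H"` (heterozygous) or `NA`
#' (missing / no call).
#'
#' @param lines a data.frame with columns `line_id` (unique), `role` (one
#'   of `"donor"`, `"recipient"`, `"other"`) and `qtl_status` (one of
#'   `"positive"`, `"negative"`, `"unknown"`).
#' @param calls a character matrix, rows matching `lines$line_id` (by
#'   rowname or order), columns named by unique marker ids, entries in
#'   A/B/H/NA.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(lines, calls) {
  stopifnot(is.data.frame(lines))
  need <- c("line_id", "role", "qtl_status")
  if (!all(need %in% names(lines)))
    stop("lines must have columns: ", paste(need, collapse = ", "))
  lines <- as.data.frame(lapply(lines[need], as.character),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(lines$line_id))
    stop("line ids must be unique")
  bad_role <- setdiff(unique(lines$role), c("donor", "recipient", "other"))
  if (length(bad_role))
    stop("invalid role(s): ", paste(bad_role, collapse = ", "))
  bad_st <- setdiff(unique(lines$qtl_status),
                    c("positive", "negative", "unknown"))
  if (length(bad_st))
    stop("invalid qtl_status value(s): ", paste(bad_st, collapse = ", "))
  calls <- as.matrix(calls)
  mode(calls) <- "character"
  if (nrow(calls) != nrow(lines))
    stop("calls has ", nrow(calls), " rows but there are ",
         nrow(lines), " lines")
  if (is.null(colnames(calls)) || anyDuplicated(colnames(calls)) ||
      any(!nzchar(colnames(calls))))
    stop("calls must have unique, non-empty marker ids as column names")
  if (!is.null(rownames(calls)) && !identical(rownames(calls), lines$line_id)) {
    if (!setequal(rownames(calls), lines$line_id))
      stop("call matrix rownames do not match line ids")
    calls <- calls[lines$line_id, , drop = FALSE]
  }
  rownames(calls) <- lines$line_id
  bad <- !(is.na(calls) | calls %in% c("A", "B", "H"))
  if (any(bad))
    stop("invalid call value(s): ",
         paste(unique(calls[bad]), collapse = ", "),
         " (allowed: A, B, H, NA)")
  structure(list(lines = lines, calls = calls), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$lines), " lines x ",
      ncol(x$calls), " markers\n", sep = "")
  cat("  roles : ", paste(names(table(x$lines$role)),
      table(x$lines$role), sep = "=", collapse = ", "), "\n", sep = "")
  cat("  status: ", paste(names(table(x$lines$qtl_status)),
      table(x$lines$qtl_status), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic genotype panel with prescribed marker accuracies
#'
#' Builds a panel of `n_donors` QTL-positive donor lines and
#' `n_recipients` QTL-negative recipient lines (plus optional
#' unknown-status lines), and for each requested marker plants exactly the
#' requested false-positive rate, false-negative rate and call rate.
#' Missing calls are assigned first (seeded shuffle over all lines), then
#' the requested rates are applied to the *scored* lines, so measured
#' rates — whose denominators exclude missing calls — reproduce the request
#' exactly. Rates that do not correspond to a whole number of lines are
#' rejected with the achievable values listed.
#'
#' @param n_donors,n_recipients,n_other line counts (donors and recipients
#'   >= 1).
#' @param markers a data.frame with columns `marker` (unique id), `fpr`,
#'   `fnr` and optionally `call_rate` (default 1).
#' @param seed integer seed; the same seed yields an identical panel.
#' @return a [genotype_panel()].
#' @examples
#' generate_panel(2, 5, markers = data.frame(marker = "m1",
#'                fpr = 0, fnr = 0.5), seed = 1)
#' @export
generate_panel <- function(n_donors, n_recipients, n_other = 0L,
                           markers, seed = 1L) {
  if (!is_count(n_donors) || n_donors < 1 ||
      !is_count(n_recipients) || n_recipients < 1)
    stop("at least one donor and one recipient line are required")
  if (!is_count(n_other) || n_other < 0)
    stop("n_other must be a non-negative integer")
  stopifnot(is.data.frame(markers), all(c("marker", "fpr", "fnr")
                                        %in% names(markers)))
  if (anyDuplicated(markers$marker)) stop("marker ids must be unique")
  if (is.null(markers$call_rate)) markers$call_rate <- 1
  lines <- data.frame(
    line_id = c(sprintf("D%d", seq_len(n_donors)),
                sprintf("R%d", seq_len(n_recipients)),
                if (n_other > 0) sprintf("O%d", seq_len(n_other))),
    role = c(rep("donor", n_donors), rep("recipient", n_recipients),
             rep("other", n_other)),
    qtl_status = c(rep("positive", n_donors), rep("negative", n_recipients),
                   rep("unknown", n_other)),
    stringsAsFactors = FALSE)
  n_lines <- nrow(lines)
  calls <- with_seed(seed, {
    m <- matrix(NA_character_, n_lines, nrow(markers),
                dimnames = list(lines$line_id, markers$marker))
    for (j in seq_len(nrow(markers))) {
      cr <- markers$call_rate[j]
      check_prob(cr, "call_rate", zero_ok = TRUE)
      n_miss <- exact_count((1 - cr) * n_lines, "call_rate", cr,
                            achievable((0:n_lines) / n_lines))
      miss <- if (n_miss > 0) sample.int(n_lines, n_miss) else integer(0)
      scored <- setdiff(seq_len(n_lines), miss)
      sd_idx <- scored[lines$role[scored] == "donor" &
                       lines$qtl_status[scored] == "positive"]
      sr_idx <- scored[lines$qtl_status[scored] == "negative"]
      if (length(sd_idx) == 0L || length(sr_idx) == 0L)
        stop("call rate leaves no scored donor or recipient lines")
      k_fn <- exact_count(markers$fnr[j] * length(sd_idx), "fnr",
                          markers$fnr[j],
                          achievable((0:length(sd_idx)) / length(sd_idx)))
      k_fp <- exact_count(markers$fpr[j] * length(sr_idx), "fpr",
                          markers$fpr[j],
                          achievable((0:length(sr_idx)) / length(sr_idx)))
      truth <- ifelse(lines$qtl_status == "positive", "A",
               ifelse(lines$qtl_status == "negative", "B", NA))
      call_j <- truth
      unknown <- which(is.na(truth))
      if (length(unknown))
        call_j[unknown] <- sample(c("A", "B"), length(unknown),
                                  replace = TRUE)
      if (k_fn > 0) call_j[sample(sd_idx, k_fn)] <- "B"
      if (k_fp > 0) call_j[sample(sr_idx, k_fp)] <- "A"
      call_j[miss] <- NA_character_
      m[, j] <- call_j
    }
    m
  })
  genotype_panel(lines, calls)
}

achievable <- function(values) paste(format(unique(round(values, 6))),
                                     collapse = ", ")

exact_count <- function(x, what, requested, options) {
  k <- round(x)
  if (abs(x - k) > 1e-9)
    stop(sprintf(
      "%s = %g does not correspond to a whole number of lines; achievable values: %s",
      what, requested, options))
  as.integer(k)
}
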