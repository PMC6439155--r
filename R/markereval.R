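#' Grade one marker against a panel of known-status lines
#'
#' A candidate diagnostic marker is graded by how it classifies lines of
#' known QTL status. The false-positive rate (FPR) is the proportion of
#' known QTL-negative lines the marker calls positive; the false-negative
#' rate (FNR) is the proportion of known QTL-positive lines it calls
#' negative. Missing calls and unknown-status lines are excluded from both
#' denominators; the call rate (non-missing fraction over all lines) is
#' reported separately. FPRs are the more damaging error in a breeding
#' context: a false positive wastes resources on lines that lack the QTL,
#' or worse, promotes a QTL-negative line as a donor.
#'
#' @param panel a [genotype_panel()].
#' @param marker a marker id present in the panel.
#' @param het_policy how to classify heterozygous calls: as carrying the
#'   favourable allele (`"het_as_positive"`, the default — codominant
#'   markers detect the allele, and enrichment deliberately retains
#'   heterozygotes) or as negative (`"het_as_negative"`).
#' @return a one-row data.frame of class `marker_accuracy`: `marker`,
#'   `fpr`, `fnr`, `call_rate`, `n_pos_scored`, `n_neg_scored`.
#' @examples
#' p <- generate_panel(2, 5, markers = data.frame(marker = "m1",
#'        fpr = 0, fnr = 0.5), seed = 1)
#' evaluate_marker(p, "m1")  # fnr = 0.5
#' @export
evaluate_marker <- function(panel, marker,
                            het_policy = c("het_as_positive",
                                           "het_as_negative")) {
  stopifnot(inherits(panel, "genotype_panel"))
  het_policy <- match.arg(het_policy)
  if (!marker %in% colnames(panel$calls))
    stop("marker not in panel: ", marker)
  calls <- panel$calls[, marker]
  called_pos <- call_is_positive(calls, het_policy)
  status <- panel$lines$qtl_status
  pos_scored <- which(status == "positive" & !is.na(calls))
  neg_scored <- which(status == "negative" & !is.na(calls))
  if (length(pos_scored) == 0L)
    stop("no scored QTL-positive lines for marker ", marker,
         "; FNR is undefined")
  if (length(neg_scored) == 0L)
    stop("no scored QTL-negative lines for marker ", marker,
         "; FPR is undefined")
  out <- data.frame(
    marker = marker,
    fpr = mean(called_pos[neg_scored]),
    fnr = mean(!called_pos[pos_scored]),
    call_rate = mean(!is.na(calls)),
    n_pos_scored = length(pos_scored),
    n_neg_scored = length(neg_scored),
    stringsAsFactors = FALSE)
  class(out) <- c("marker_accuracy", class(out))
  out
}

call_is_positive <- function(calls, het_policy) {
  ifelse(is.na(calls), NA,
         calls == "A" | (calls == "H" & het_policy == "het_as_positive"))
}

#' Rank all markers of a panel by accuracy
#'
#' Markers are sorted ascending by (FPR, FNR, 1 - call rate), ties broken
#' by marker id, so the ordering is deterministic and the most reliable
#' diagnostic marker comes first. Markers whose accuracy is undefined on
#' this panel (all relevant calls missing) sort last with NA rates.
#'
#' @inheritParams evaluate_marker
#' @return a data.frame, one row per marker, best first.
#' @export
rank_markers <- function(panel, het_policy = c("het_as_positive",
                                               "het_as_negative")) {
  stopifnot(inherits(panel, "genotype_panel"))
  het_policy <- match.arg(het_policy)
  rows <- lapply(colnames(panel$calls), function(m)
    tryCatch(evaluate_marker(panel, m, het_policy),
             error = function(e) data.frame(
               marker = m, fpr = NA_real_, fnr = NA_real_,
               call_rate = mean(!is.na(panel$calls[, m])),
               n_pos_scored = NA_integer_, n_neg_scored = NA_integer_,
               stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  ord <- order(out$fpr, out$fnr, 1 - out$call_rate, out$marker,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict per-cross MAS success for one marker
#'
#' A marker is useful in a cross only if it distinguishes the parents: the
#' cross (donor d, recipient r) supports marker-assisted selection iff the
#' marker calls d QTL-positive and r QTL-negative. A marker with a
#' nonzero FNR silently fails in every population derived from the donors
#' it misses; a nonzero FPR fails in populations from the recipients it
#' miscalls.
#'
#' @inheritParams evaluate_marker
#' @return a list: `success` (logical donors x recipients matrix; missing
#'   parental calls count as failure) and `success_fraction`.
#' @export
mas_success_matrix <- function(panel, marker,
                               het_policy = c("het_as_positive",
                                              "het_as_negative")) {
  stopifnot(inherits(panel, "genotype_panel"))
  het_policy <- match.arg(het_policy)
  if (!marker %in% colnames(panel$calls))
    stop("marker not in panel: ", marker)
  donors <- panel$lines$line_id[panel$lines$role == "donor"]
  recips <- panel$lines$line_id[panel$lines$role == "recipient"]
  if (length(donors) == 0L || length(recips) == 0L)
    stop("panel must contain at least one donor and one recipient line")
  calls <- panel$calls[, marker]
  pos <- call_is_positive(calls, het_policy)
  donor_ok <- !is.na(pos[donors]) & pos[donors]
  recip_ok <- !is.na(pos[recips]) & !pos[recips]
  success <- outer(donor_ok, recip_ok, `&`)
  dimnames(success) <- list(donor = donors, recipient = recips)
  list(success = success, success_fraction = mean(success))
}

#' QTL profile of panel lines
#'
#' Translates marker calls into a per-line fingerprint of QTL
#' presence/absence: each mapped marker stands for one QTL, and a line is
#' reported `"positive"`, `"heterozygous"`, `"negative"` or `"missing"` at
#' that QTL from its call at the designated favourable allele. Under the
#' default heterozygote policy a heterozygous profile entry counts as
#' carrying the favourable allele. Lines of unknown QTL status are
#' profiled like any other (they are only excluded from accuracy
#' denominators, not from fingerprints).
#'
#' @inheritParams evaluate_marker
#' @param marker_map named character vector mapping marker id -> QTL name
#'   (or a data.frame with columns `marker`, `qtl`). Mapped markers absent
#'   from the panel are skipped with a warning.
#' @return a character matrix, lines x QTLs.
#' @export
qtl_profile <- function(panel, marker_map) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.data.frame(marker_map)) {
    stopifnot(all(c("marker", "qtl") %in% names(marker_map)))
    marker_map <- stats::setNames(as.character(marker_map$qtl),
                                  as.character(marker_map$marker))
  }
  if (is.null(names(marker_map)) || any(!nzchar(names(marker_map))))
    stop("marker_map must map marker ids to QTL names")
  missing_mk <- setdiff(names(marker_map), colnames(panel$calls))
  if (length(missing_mk)) {
    warning("marker(s) not in panel, skipped: ",
            paste(missing_mk, collapse = ", "))
    marker_map <- marker_map[setdiff(names(marker_map), missing_mk)]
  }
  if (length(marker_map) == 0L) stop("no mapped markers present in panel")
  if (anyDuplicated(unname(marker_map)))
    stop("each QTL must be represented by a single marker")
  prof <- vapply(names(marker_map), function(m) {
    calls <- panel$calls[, m]
    ifelse(is.na(calls), "missing",
           ifelse(calls == "A", "positive",
                  ifelse(calls == "H", "heterozygous", "negative")))
  }, character(nrow(panel$lines)))
  prof <- matrix(prof, nrow = nrow(panel$lines),
                 dimnames = list(panel$lines$line_id, unname(marker_map)))
  prof
}
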