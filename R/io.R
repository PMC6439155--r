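#' Write a genotype panel to CSV
#'
#' Canonical panel schema: header `line_id,role,qtl_status,<marker_id>...`,
#' one row per line, calls coded A/B/H/NA. The file round-trips losslessly
#' through [read_panel_csv()].
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- cbind(panel$lines, as.data.frame(panel$calls,
                                         stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genotype panel from CSV
#'
#' Expects the schema written by [write_panel_csv()]. Windows (CRLF) line
#' endings are accepted. Rows whose field count does not match the header
#' are reported with their line number.
#'
#' @param path input file path.
#' @return a [genotype_panel()].
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"",
                            blank.lines.skip = TRUE)
  if (length(nf) < 2L)
    stop("panel file must have a header and at least one line row")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("malformed panel CSV: line ", bad[1] , " has ", nf[bad[1]],
         " fields, expected ", nf[1])
  df <- utils::read.csv(path, colClasses = "character", na.strings = "NA",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("line_id", "role", "qtl_status")
  if (!identical(names(df)[1:3], need))
    stop("malformed panel CSV header: first columns must be ",
         paste(need, collapse = ","))
  if (ncol(df) < 4L) stop("panel CSV contains no marker columns")
  calls <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(calls) <- df$line_id
  genotype_panel(df[1:3], calls)
}

#' Read marker calls from a minimal VCF
#'
#' A read-only convenience for panels genotyped as VCF: only GT fields are
#' consumed (`./.` and `.` are missing), sites are matched to markers via
#' a favourable-allele sidecar, and 1-based VCF positions are preserved in
#' the marker metadata. Multi-allelic handling is minimal: any allele
#' other than the favourable one counts as the alternative.
#'
#' The sidecar is a tab-separated file (or data.frame) with columns
#' `marker_id` (the VCF ID, or `CHROM_POS` where ID is `.`) and
#' `favourable` (`"REF"` or `"ALT"`). Sites without a sidecar entry are
#' skipped with a warning.
#'
#' @param path VCF file path (plain text).
#' @param favourable sidecar file path or data.frame.
#' @param lines optional data.frame (`line_id`, `role`, `qtl_status`)
#'   giving role/status metadata for the VCF samples; samples not listed
#'   default to role `"other"`, status `"unknown"`.
#' @return a [genotype_panel()] with a `markers` attribute holding site
#'   metadata (chrom, 1-based pos, ref, alt, favourable allele).
#' @export
read_minimal_vcf <- function(path, favourable, lines = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the vcfR package")
  if (is.character(favourable))
    favourable <- utils::read.delim(favourable, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(favourable),
            all(c("marker_id", "favourable") %in% names(favourable)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, sep = "_"), fix$ID)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- ids
  keep <- ids %in% favourable$marker_id
  if (any(!keep))
    warning("site(s) without favourable-allele designation skipped: ",
            paste(ids[!keep], collapse = ", "))
  if (!any(keep)) stop("no VCF site has a favourable-allele designation")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ids[keep]
  fav <- favourable$favourable[match(ids, favourable$marker_id)]
  if (!all(fav %in% c("REF", "ALT")))
    stop("favourable designation must be REF or ALT")
  fav_code <- ifelse(fav == "REF", "0", "1")
  calls <- matrix(NA_character_, ncol(gt), nrow(gt),
                  dimnames = list(colnames(gt), ids))
  for (i in seq_along(ids)) {
    g <- gt[i, ]
    alleles <- strsplit(ifelse(is.na(g), "./.", g), "[/|]")
    calls[, i] <- vapply(alleles, function(a) {
      a <- a[a != "."]
      if (length(a) == 0L) return(NA_character_)
      is_fav <- a == fav_code[i]
      if (all(is_fav)) "A" else if (any(is_fav)) "H" else "B"
    }, character(1))
  }
  sample_ids <- colnames(gt)
  meta <- data.frame(line_id = sample_ids, role = "other",
                     qtl_status = "unknown", stringsAsFactors = FALSE)
  if (!is.null(lines)) {
    idx <- match(sample_ids, lines$line_id)
    hit <- !is.na(idx)
    meta$role[hit] <- lines$role[idx[hit]]
    meta$qtl_status[hit] <- lines$qtl_status[idx[hit]]
  }
  panel <- genotype_panel(meta, calls)
  attr(panel, "markers") <- data.frame(
    marker = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, favourable = fav,
    stringsAsFactors = FALSE)
  panel
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with
#' `#` are ignored. Values are returned as character and coerced where
#' they are used. Command-line flags override configuration values.
#'
#' @param path file path.
#' @return a named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L) return(stats::setNames(character(0), character(0)))
  m <- regmatches(raw, regexec("^([^=]+)=(.*)$", raw))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", raw[which(bad)[1]])
  stats::setNames(trimws(vapply(m, `[`, character(1), 3L)),
                  trimws(vapply(m, `[`, character(1), 2L)))
}
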