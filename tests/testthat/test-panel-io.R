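test_that("panel construction validates structure and call codes", {
  lines <- data.frame(line_id = c("a", "b"), role = c("donor", "recipient"),
                      qtl_status = c("positive", "negative"))
  calls <- cbind(m1 = c("A", "B")); rownames(calls) <- lines$line_id
  expect_s3_class(genotype_panel(lines, calls), "genotype_panel")
  expect_error(genotype_panel(lines, cbind(m1 = c("A", "X"))), "invalid call")
  expect_error(genotype_panel(rbind(lines, lines), rbind(calls, calls)),
               "unique")
  bad <- lines; bad$role[1] <- "parent"
  expect_error(genotype_panel(bad, calls), "invalid role")
  expect_error(genotype_panel(lines, calls[1, , drop = FALSE]), "rows")
})

test_that("panel generation is seed-deterministic and enforces achievable rates", {
  mk <- data.frame(marker = "m1", fpr = 0.2, fnr = 0.5, call_rate = 1)
  a <- generate_panel(2, 5, markers = mk, seed = 3)
  b <- generate_panel(2, 5, markers = mk, seed = 3)
  expect_identical(a, b)
  c <- generate_panel(2, 5, markers = mk, seed = 4)
  expect_false(identical(a$calls, c$calls))
  expect_error(generate_panel(2, 5, markers = data.frame(
    marker = "m1", fpr = 0.5, fnr = 0)), "achievable values")
  expect_error(generate_panel(2, 5, markers = data.frame(
    marker = "m1", fpr = 0, fnr = 0.3)), "achievable values")
})

test_that("call-rate requests are honoured exactly on the scored denominator", {
  mk <- data.frame(marker = "m1", fpr = 0, fnr = 0, call_rate = 0.8)
  panel <- generate_panel(4, 6, markers = mk, seed = 8)
  acc <- evaluate_marker(panel, "m1")
  expect_identical(acc$call_rate, 0.8)
  expect_identical(acc$fpr, 0)
  expect_identical(acc$fnr, 0)
})

test_that("panel CSV writes and reads losslessly, including CRLF input", {
  panel <- generate_panel(2, 5, n_other = 1,
                          markers = data.frame(marker = c("m1", "m2"),
                                               fpr = c(0, 0.2),
                                               fnr = c(0.5, 0),
                                               call_rate = c(1, 0.875)),
                          seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_identical(back$lines, panel$lines)
  expect_identical(back$calls, panel$calls)
  # same seed, same bytes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(generate_panel(2, 5, n_other = 1,
                                 markers = data.frame(marker = c("m1", "m2"),
                                                      fpr = c(0, 0.2),
                                                      fnr = c(0.5, 0),
                                                      call_rate = c(1, 0.875)),
                                 seed = 5), path2)
  expect_identical(readLines(path), readLines(path2))
  # CRLF round trip
  crlf <- withr::local_tempfile(fileext = ".csv")
  writeLines(readLines(path), crlf, sep = "\r\n")
  expect_identical(read_panel_csv(crlf)$calls, panel$calls)
})

test_that("malformed panel CSVs are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,role,qtl_status,m1",
               "a,donor,positive,A",
               "b,recipient,negative"), path)
  expect_error(read_panel_csv(path), "line 3")
  writeLines(c("id,role,qtl_status,m1", "a,donor,positive,A"), path)
  expect_error(read_panel_csv(path), "header")
})

test_that("minimal VCF input maps GT calls through the favourable-allele sidecar", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "d1", "d2", "r1", sep = "\t"),
    paste("chr1", "1000", "mk1", "G", "A", ".", "PASS", ".", "GT",
          "1/1", "0/1", "0/0", sep = "\t"),
    paste("chr1", "2000", ".", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "./.", "1|1", sep = "\t"),
    paste("chr1", "3000", "mk9", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", sep = "\t")), vcf)
  sidecar <- data.frame(marker_id = c("mk1", "chr1_2000"),
                        favourable = c("ALT", "REF"))
  lines <- data.frame(line_id = c("d1", "d2", "r1"),
                      role = c("donor", "donor", "recipient"),
                      qtl_status = c("positive", "positive", "negative"))
  expect_warning(panel <- read_minimal_vcf(vcf, sidecar, lines), "mk9")
  expect_identical(unname(panel$calls[, "mk1"]), c("A", "H", "B"))
  expect_identical(unname(panel$calls[, "chr1_2000"]), c("A", NA, "B"))
  meta <- attr(panel, "markers")
  expect_identical(meta$pos, c(1000L, 2000L))
  expect_identical(meta$favourable, c("ALT", "REF"))
  acc <- evaluate_marker(panel, "mk1")
  expect_equal(c(acc$fpr, acc$fnr), c(0, 0))
})

test_that("flat key-value configuration files parse with comments", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# sizing defaults", "p = 0.5", "risk=0.01", "", "loci = 2"),
             path)
  cfg <- read_config(path)
  expect_identical(cfg[["p"]], "0.5")
  expect_identical(cfg[["risk"]], "0.01")
  expect_identical(cfg[["loci"]], "2")
  writeLines("just a line", path)
  expect_error(read_config(path), "malformed")
})
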