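test_that("clonotype tables parse in both dialects", {
  airr <- write_simple_tsv(c(
    "v_call\tj_call\tjunction\tjunction_aa\tduplicate_count",
    "TRAV1\tTRAJ4\tTGTGCTAGC\tCAS\t3",
    "TRAV2\tTRAJ4\tTGTGCTAGT\tCAS\t2",
    "TRAV1\tTRAJ5\tTGTTTTAGC\tCFS\t7"
  ))
  recs <- read_clonotype_table(airr, dialect = "airr")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$count, c(3L, 2L, 7L))
  expect_equal(recs$v_label, c("TRAV1", "TRAV2", "TRAV1"))
  expect_false(any(recs$missing_cdr3))

  simple <- write_simple_tsv(c(
    "v\tj\tcdr3_nt\tcdr3_aa\tcount",
    "TRBV3\tTRBJ1\tTGTGCTAGC\tCAS\t11"
  ))
  recs2 <- read_clonotype_table(simple, dialect = "simple_tsv")
  expect_equal(recs2$count, 11L)
  expect_error(read_clonotype_table(simple, dialect = "csv"))
})

test_that("rows with an empty junction are flagged, not dropped", {
  airr <- write_simple_tsv(c(
    "v_call\tj_call\tjunction\tjunction_aa\tduplicate_count",
    "TRAV1\tTRAJ4\tTGTGCTAGC\tCAS\t3",
    "TRAV2\tTRAJ4\t\t\t2"
  ))
  recs <- read_clonotype_table(airr)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$missing_cdr3, c(FALSE, TRUE))
  expect_true(is.na(recs$cdr3_nt[2]))
})

test_that("malformed rows error with their line number", {
  bad_count <- write_simple_tsv(c(
    "v_call\tj_call\tjunction\tjunction_aa\tduplicate_count",
    "TRAV1\tTRAJ4\tTGTGCTAGC\tCAS\t3",
    "TRAV2\tTRAJ4\tTGTGCTAGT\tCAS\t2.5"
  ))
  expect_error(read_clonotype_table(bad_count), "line 3")
  bad_nt <- write_simple_tsv(c(
    "v_call\tj_call\tjunction\tjunction_aa\tduplicate_count",
    "TRAV1\tTRAJ4\tTGTGNTAGC\tCAS\t3"
  ))
  expect_error(read_clonotype_table(bad_nt), "line 2")
})

test_that("CDR3 translation follows the standard genetic code", {
  expect_equal(translate_cdr3("TGTGCTAGC"), "CAS")
  expect_true(is.na(translate_cdr3("TGTGA")))   # not a multiple of 3
  expect_true(is.na(translate_cdr3("TGTTGA")))  # in-frame stop
  expect_error(translate_cdr3("TGTGNT"), "non-ACGT")
})

test_that("translation matches Biostrings on all 64 codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  ours <- translate_cdr3(codons)
  oracle <- vapply(codons, function(cd) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                             no.init.codon = TRUE))
    if (aa == "*") NA_character_ else aa
  }, character(1), USE.NAMES = FALSE)
  expect_identical(ours, oracle)
})

test_that("record filtering partitions the input and reports reasons", {
  recs <- toy_records()[rep(1:3, c(4, 4, 2)), ]
  recs$missing_cdr3[c(1, 5)] <- TRUE
  recs$cdr3_nt[c(1, 5)] <- NA
  out <- apply_record_filters(recs)
  expect_equal(nrow(out$kept), 8)
  expect_equal(out$report, c(missing_cdr3 = 2L))
  expect_equal(nrow(out$kept) + sum(out$report), nrow(recs))

  clean <- apply_record_filters(toy_records())
  expect_equal(nrow(clean$kept), 3)
  expect_length(clean$report, 0)
  expect_equal(clean$kept$cdr3_aa, c("CAS", "CAS", "CFS"))

  # in-frame stop and frame violation, checked against the translation
  # oracle record by record
  recs2 <- toy_records()
  recs2$cdr3_nt[2] <- "TGTTGAAGC"  # TGA stop
  recs2$cdr3_nt[3] <- "TGTGCTAG"   # length 8
  out2 <- apply_record_filters(recs2)
  expect_equal(sort(names(out2$report)), c("out_of_frame", "stop_codon"))
  expect_equal(unname(out2$report["stop_codon"]), 1L)
  per_record <- is.na(suppressWarnings(
    vapply(recs2$cdr3_nt, function(s) {
      if (nchar(s) %% 3 != 0) NA_character_ else translate_cdr3(s)
    }, character(1))))
  expect_equal(nrow(out2$kept), sum(!per_record))
})

test_that("collapse to amino-acid clonotypes sums synonymous counts", {
  recs <- tibble::tibble(
    v_label = c("TRAV1", "TRAV1"), j_label = c("TRAJ4", "TRAJ4"),
    cdr3_nt = c("TGTGCTAGC", "TGTGCTAGT"),  # both encode CAS
    cdr3_aa = NA_character_, count = c(3L, 2L), missing_cdr3 = FALSE
  )
  rep1 <- collapse_to_aa(apply_record_filters(recs)$kept, "m1", "CD4", "alpha")
  expect_equal(unique_count(rep1), 1)
  expect_equal(rep1$clones$count, 5L)

  # identical CDR3 aa under different V genes stays distinct
  recs$v_label <- c("TRAV1", "TRAV9")
  rep2 <- collapse_to_aa(apply_record_filters(recs)$kept, "m1", "CD4", "alpha")
  expect_equal(unique_count(rep2), 2)
})

test_that("collapse conserves total molecule count on random input", {
  set.seed(11)
  n <- 100
  recs <- tibble::tibble(
    v_label = sample(c("TRAV1", "TRAV2", "TRAV3"), n, replace = TRUE),
    j_label = sample(c("TRAJ1", "TRAJ2"), n, replace = TRUE),
    cdr3_nt = replicate(n, paste(sample(c("GCT", "TGT", "TTT", "AGC"), 4,
                                        replace = TRUE), collapse = "")),
    cdr3_aa = NA_character_, count = sample(1:50, n, replace = TRUE),
    missing_cdr3 = FALSE
  )
  kept <- apply_record_filters(recs)$kept
  rep <- collapse_to_aa(kept, "m1", "CD8", "beta")
  expect_equal(repertoire_size(rep), sum(kept$count))
})

test_that("write/read round-trips repertoires in both dialects", {
  set.seed(7)
  for (dialect in c("airr", "simple_tsv")) {
    rep <- toy_repertoire(sample(1:40, 50, replace = TRUE))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_clonotype_table(rep, path, dialect = dialect)
    back <- collapse_to_aa(read_clonotype_table(path, dialect = dialect),
                           "m1", "CD4", "alpha")
    expect_setequal(clone_keys(back), clone_keys(rep))
    m <- match(clone_keys(rep), clone_keys(back))
    expect_equal(back$clones$count[m], rep$clones$count)
  }
})

test_that("AIRR output has the expected schema, even when empty", {
  rep <- toy_repertoire(c(2, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(rep, path, dialect = "airr")
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("v_call", "j_call", "junction", "junction_aa",
                         "duplicate_count"))
  empty <- rep
  empty$clones <- rep$clones[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(empty, path2, dialect = "airr")
  expect_length(readLines(path2), 1)  # header only
})

test_that("metadata tables validate and round-trip", {
  md <- tibble::tibble(mouse_id = c("m1", "m2"), sex = c("F", "M"),
                       age_weeks = c(10, 40), site = "Nottingham",
                       cohort = "wild")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, path)
  back <- read_metadata(path)
  expect_equal(back$age_weeks, md$age_weeks)
  expect_equal(back$sex, md$sex)

  bad <- md
  bad$sex <- c("F", "X")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(bad, path2)
  expect_error(read_metadata(path2), "sex")
})
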