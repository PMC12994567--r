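#' Translate a CDR3 nucleotide sequence
#'
#' Standard-genetic-code translation in frame 0. A sequence whose length
#' is not a multiple of three, or whose translation contains a stop
#' codon, is unproductive and yields `NA`; callers treat `NA` as the
#' failure marker.
#'
#' @param cdr3_nt Character vector of nucleotide sequences over
#'   \{A, C, G, T\}.
#' @return Character vector of amino-acid sequences, `NA` where
#'   translation fails.
#' @examples
#' translate_cdr3("TGTGCTAGC") # "CAS"
#' @export
translate_cdr3 <- function(cdr3_nt) {
  cdr3_nt <- toupper(as.character(cdr3_nt))
  bad <- grepl("[^ACGT]", cdr3_nt)
  if (any(bad, na.rm = TRUE)) {
    stop("non-ACGT character in CDR3 nucleotide sequence: ",
         paste(utils::head(cdr3_nt[which(bad)], 3), collapse = ", "))
  }
  code <- Biostrings::GENETIC_CODE
  vapply(cdr3_nt, function(s) {
    if (is.na(s)) return(NA_character_)
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return(NA_character_)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(code[codons])
    if (any(aa == "*")) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

airr_cols <- c(v_call = "v_label", j_call = "j_label", junction = "cdr3_nt",
               junction_aa = "cdr3_aa", duplicate_count = "count")
simple_cols <- c(v = "v_label", j = "j_label", cdr3_nt = "cdr3_nt",
                 cdr3_aa = "cdr3_aa", count = "count")

dialect_map <- function(dialect) {
  switch(dialect,
    airr = airr_cols,
    simple_tsv = simple_cols,
    stop("unknown clonotype-table dialect: ", dialect)
  )
}

#' Read a clonotype table
#'
#' Reads one per-(mouse, subset, chain) clonotype table into a tibble of
#' clone records. Two tab-separated dialects are supported: the AIRR
#' Rearrangement subset (`v_call`, `j_call`, `junction`, `junction_aa`,
#' `duplicate_count`) and a minimal 5-column table (`v`, `j`, `cdr3_nt`,
#' `cdr3_aa`, `count`). Rows with an empty CDR3 nucleotide field are
#' returned with `missing_cdr3 = TRUE` rather than dropped, so the
#' exclusion step can report them.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param dialect `"airr"` (default) or `"simple_tsv"`.
#' @return A tibble with columns `v_label`, `j_label`, `cdr3_nt`,
#'   `cdr3_aa`, `count`, `missing_cdr3`.
#' @export
read_clonotype_table <- function(path, dialect = c("airr", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- dialect_map(dialect)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           check.names = FALSE, quote = "", na.strings = NULL)
  missing_cols <- setdiff(names(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("dialect '", dialect, "' requires column(s) missing from ", path,
         ": ", paste(missing_cols, collapse = ", "))
  }
  df <- as_tibble(raw[names(cols)])
  names(df) <- unname(cols)
  n <- nrow(df)
  if (n == 0) {
    df$count <- integer(0)
    df$missing_cdr3 <- logical(0)
    return(df)
  }
  # data row i sits on file line i + 1 (header is line 1)
  line_of <- function(i) i + 1L
  bad_count <- !grepl("^[0-9]+$", df$count) | df$count == "0"
  if (any(bad_count)) {
    i <- which(bad_count)[1]
    stop("line ", line_of(i), ": count '", df$count[i],
         "' is not a positive integer")
  }
  df$count <- as.integer(df$count)
  df$missing_cdr3 <- !nzchar(df$cdr3_nt)
  bad_nt <- !df$missing_cdr3 & grepl("[^ACGTacgt]", df$cdr3_nt)
  if (any(bad_nt)) {
    i <- which(bad_nt)[1]
    stop("line ", line_of(i), ": CDR3 nucleotide sequence contains ",
         "characters outside {A,C,G,T}")
  }
  df$cdr3_nt[df$missing_cdr3] <- NA_character_
  df$cdr3_aa[!nzchar(df$cdr3_aa)] <- NA_character_
  df$cdr3_nt <- toupper(df$cdr3_nt)
  df
}

#' Exclude records without a productive CDR3
#'
#' Implements the record-level exclusion rule: a clone record is kept
#' only if it carries a CDR3 nucleotide sequence that translates in
#' frame 0 without a stop codon. Exclusions are tallied by reason so
#' the filtering step is auditable; kept records have `cdr3_aa` filled
#' from the translation.
#'
#' @param records Tibble of clone records as returned by
#'   [read_clonotype_table()].
#' @return A list with `kept` (tibble of surviving records, `cdr3_aa`
#'   populated) and `report` (named integer vector of exclusion counts
#'   by reason: `missing_cdr3`, `out_of_frame`, `stop_codon`).
#' @export
apply_record_filters <- function(records) {
  records <- as_tibble(records)
  n <- nrow(records)
  if (!"missing_cdr3" %in% names(records)) {
    records$missing_cdr3 <- is.na(records$cdr3_nt) | !nzchar(records$cdr3_nt)
  }
  reason <- rep(NA_character_, n)
  reason[records$missing_cdr3] <- "missing_cdr3"
  todo <- which(is.na(reason))
  if (length(todo) > 0) {
    nt <- records$cdr3_nt[todo]
    frame_bad <- nchar(nt) %% 3L != 0L
    reason[todo[frame_bad]] <- "out_of_frame"
    ok <- todo[!frame_bad]
    if (length(ok) > 0) {
      aa <- translate_cdr3(records$cdr3_nt[ok])
      reason[ok[is.na(aa)]] <- "stop_codon"
      records$cdr3_aa[ok] <- aa
    }
  }
  keep <- is.na(reason)
  report <- table(factor(reason[!keep],
                         levels = c("missing_cdr3", "out_of_frame", "stop_codon")))
  report <- setNames(as.integer(report), names(report))
  report <- report[report > 0]
  kept <- records[keep, setdiff(names(records), "missing_cdr3")]
  list(kept = kept, report = report)
}

#' Collapse nucleotide-defined clones to amino-acid clonotypes
#'
#' Different CDR3 nucleotide sequences can encode the same amino-acid
#' sequence; after translation, records are merged by the clonotype
#' triple (V label, CDR3 amino-acid sequence, J label), summing molecule
#' counts. Total repertoire size is conserved.
#'
#' @param records Filtered clone records (all with `cdr3_aa` present),
#'   e.g. the `kept` element of [apply_record_filters()].
#' @inheritParams repertoire
#' @return A `tcr_repertoire` at amino-acid level.
#' @export
collapse_to_aa <- function(records, mouse_id, subset, chain) {
  records <- as_tibble(records)
  if (nrow(records) > 0 && anyNA(records$cdr3_aa)) {
    stop("records must carry cdr3_aa; run apply_record_filters() first")
  }
  clones <- records %>%
    group_by(across(all_of(c("v_label", "cdr3_aa", "j_label")))) %>%
    summarise(count = sum(count), .groups = "drop") %>%
    arrange(across(all_of(c("v_label", "cdr3_aa", "j_label"))))
  clones$cdr3_nt <- NA_character_
  repertoire(clones, mouse_id = mouse_id, subset = subset, chain = chain,
             level = "amino_acid")
}

#' Write a repertoire as a clonotype table
#'
#' Inverse of [read_clonotype_table()]: writes one row per clone in the
#' chosen dialect. Reading the file back and collapsing reproduces the
#' repertoire's key-to-count map exactly.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @param dialect `"airr"` or `"simple_tsv"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path, dialect = c("airr", "simple_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rep, "tcr_repertoire"))
  cols <- dialect_map(dialect)
  out <- rep$clones[unname(cols)]
  names(out) <- names(cols)
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write clonotype table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read and write mouse metadata tables
#'
#' Metadata is a tab-separated table with columns `mouse_id`, `sex`
#' (M/F), `age_weeks`, `site`, `cohort` (wild/lab). Ages are in weeks
#' (as estimated from dried eye-lens mass in wild animals).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the five metadata columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                    colClasses = "character", quote = ""))
  needed <- c("mouse_id", "sex", "age_weeks", "site", "cohort")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[needed]
  df$age_weeks <- as.numeric(df$age_weeks)
  if (anyNA(df$age_weeks) || any(df$age_weeks < 0)) {
    stop("age_weeks must be non-negative numbers")
  }
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  dup <- df$mouse_id[duplicated(df[c("mouse_id", "cohort")])]
  if (length(dup) > 0) {
    stop("duplicate mouse_id within cohort: ", paste(unique(dup), collapse = ", "))
  }
  df
}

#' @rdname read_metadata
#' @param metadata Metadata tibble to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
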