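#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr %>% group_by summarise ungroup arrange across all_of
#' @importFrom stats setNames
NULL

SUBSETS <- c("CD4", "CD8")
CHAINS <- c("alpha", "beta")
RECEPTOR_TYPES <- c("CD4_alpha", "CD4_beta", "CD8_alpha", "CD8_beta")

#' TCR repertoire container
#'
#' A repertoire is the multiset of T-cell clones observed for one
#' (mouse, T-cell subset, chain) combination. Each clone is identified
#' either by its exact CDR3 nucleotide sequence (`level = "nucleotide"`)
#' or by the amino-acid clonotype triple V gene / CDR3 amino-acid
#' sequence / J gene (`level = "amino_acid"`), and carries a positive
#' integer molecule count.
#'
#' @param clones A data frame with columns `v_label`, `j_label`,
#'   `cdr3_nt` (may be `NA` at amino-acid level), `cdr3_aa` (may be `NA`
#'   at nucleotide level) and integer `count`.
#' @param mouse_id Mouse identifier.
#' @param subset `"CD4"` or `"CD8"`.
#' @param chain `"alpha"` or `"beta"`.
#' @param level `"nucleotide"` or `"amino_acid"`; the clone key in use.
#' @return An object of class `tcr_repertoire`.
#' @export
repertoire <- function(clones, mouse_id, subset, chain,
                       level = c("amino_acid", "nucleotide")) {
  level <- match.arg(level)
  subset <- match.arg(subset, SUBSETS)
  chain <- match.arg(chain, CHAINS)
  clones <- as_tibble(clones)
  needed <- c("v_label", "j_label", "count")
  missing_cols <- setdiff(needed, names(clones))
  if (length(missing_cols) > 0) {
    stop("clone table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"cdr3_nt" %in% names(clones)) clones$cdr3_nt <- NA_character_
  if (!"cdr3_aa" %in% names(clones)) clones$cdr3_aa <- NA_character_
  key_col <- if (level == "amino_acid") "cdr3_aa" else "cdr3_nt"
  if (nrow(clones) > 0) {
    if (anyNA(clones[[key_col]]) || any(!nzchar(clones[[key_col]]))) {
      stop("all clones must have a non-empty ", key_col, " at level ", level)
    }
    if (any(clones$count < 1) || any(clones$count != round(clones$count))) {
      stop("clone counts must be positive integers")
    }
  }
  clones$count <- as.integer(round(clones$count))
  clones <- clones[, c("v_label", "j_label", "cdr3_nt", "cdr3_aa", "count")]
  structure(
    list(mouse_id = as.character(mouse_id), subset = subset, chain = chain,
         level = level, clones = clones),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> mouse %s, %s %s chain (%s level)\n  %d unique clones, %d molecules\n",
    x$mouse_id, x$subset, x$chain, x$level,
    unique_count(x), repertoire_size(x)
  ))
  invisible(x)
}

#' Receptor type label of a repertoire
#'
#' The four receptor types are the subset-by-chain combinations
#' `CD4_alpha`, `CD4_beta`, `CD8_alpha`, `CD8_beta`.
#'
#' @param rep A `tcr_repertoire`.
#' @return A string such as `"CD4_alpha"`.
#' @export
receptor_type <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  paste(rep$subset, rep$chain, sep = "_")
}

#' Clone keys of a repertoire
#'
#' Returns one string key per unique clone. At amino-acid level the key
#' is the clonotype triple `V|CDR3aa|J`; at nucleotide level it is
#' `V|CDR3nt|J`.
#'
#' @param rep A `tcr_repertoire`.
#' @return Character vector, one element per clone row.
#' @export
clone_keys <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cd <- if (rep$level == "amino_acid") rep$clones$cdr3_aa else rep$clones$cdr3_nt
  paste(rep$clones$v_label, cd, rep$clones$j_label, sep = "|")
}

#' Repertoire size, unique clonotype count, and richness
#'
#' Repertoire size is the total number of TCR molecules observed (the
#' sum of clone counts). The unique count is the number of distinct
#' clonotypes. Richness is the unique count as a proportion of the
#' repertoire size, a depth-normalised measure of repertoire breadth in
#' (0, 1].
#'
#' @param rep A `tcr_repertoire` (non-empty).
#' @return `repertoire_size()` and `unique_count()` return an integer
#'   (numeric for very large repertoires); `richness()` a number in (0, 1].
#' @export
repertoire_size <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep$clones) == 0) stop("repertoire is empty")
  sum(as.numeric(rep$clones$count))
}

#' @rdname repertoire_size
#' @export
unique_count <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep$clones) == 0) stop("repertoire is empty")
  nrow(rep$clones)
}

#' @rdname repertoire_size
#' @export
richness <- function(rep) {
  unique_count(rep) / repertoire_size(rep)
}

# Deterministic sub-seed in [1, 2^31 - 2] from a master seed plus string
# context (mouse id, receptor type, stage). Polynomial string hash mod the
# Mersenne prime 2^31 - 1; exact in double arithmetic.
derive_seed <- function(master_seed, ...) {
  p <- 2147483647
  txt <- paste(c(as.character(master_seed), as.character(unlist(list(...)))),
               collapse = "\x1f")
  h <- 7
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% p
  as.integer(h %% (p - 1) + 1)
}
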