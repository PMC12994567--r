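# Shared fixtures: all built in code at test time.

# A repertoire with the given counts and synthetic clonotype keys.
toy_repertoire <- function(counts, mouse = "m1", subset = "CD4",
                           chain = "alpha", prefix = "K") {
  n <- length(counts)
  clones <- tibble::tibble(
    v_label = sprintf("V%02d", (seq_len(n) - 1) %% 5 + 1),
    j_label = sprintf("J%02d", (seq_len(n) - 1) %% 3 + 1),
    cdr3_nt = NA_character_,
    cdr3_aa = sprintf("CA%s%dF", prefix, seq_len(n)),
    count = as.integer(counts)
  )
  repertoire(clones, mouse_id = mouse, subset = subset, chain = chain,
             level = "amino_acid")
}

# The literal down-sampling procedure: replicate every clone by its
# count, sample the molecule list without replacement, re-tally.
naive_downsample <- function(counts, target) {
  expanded <- rep(seq_along(counts), counts)
  drawn <- sample(expanded, target)
  tabulate(drawn, nbins = length(counts))
}

# Minimal well-formed clone record table.
toy_records <- function() {
  tibble::tibble(
    v_label = c("TRAV1", "TRAV2", "TRAV1"),
    j_label = c("TRAJ4", "TRAJ4", "TRAJ5"),
    cdr3_nt = c("TGTGCTAGC", "TGTGCTAGT", "TGTTTTAGC"),
    cdr3_aa = NA_character_,
    count = c(3L, 2L, 7L),
    missing_cdr3 = FALSE
  )
}

write_simple_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
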