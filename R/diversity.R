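#' Molecule-count quality control for a subset's chain pair
#'
#' A mouse's CD4+ (or CD8+) data are analysable only if both the alpha
#' and the beta chain libraries are deep enough; if either chain has
#' fewer than `threshold` TCR molecules, both chains of that subset are
#' dropped. Exactly `threshold` molecules is kept (the rule is a strict
#' less-than).
#'
#' @param alpha_rep,beta_rep The alpha- and beta-chain
#'   `tcr_repertoire`s of one mouse x subset, or `NULL` when a chain
#'   was not assayed (which also drops the pair).
#' @param threshold Minimum molecule count per chain (default 5000).
#' @return List: `keep` (logical), `reason` (string or `NA`),
#'   `sizes` (named numeric: alpha, beta).
#' @export
qc_exclude <- function(alpha_rep, beta_rep, threshold = 5000) {
  sizes <- c(
    alpha = if (is.null(alpha_rep)) NA_real_ else repertoire_size(alpha_rep),
    beta = if (is.null(beta_rep)) NA_real_ else repertoire_size(beta_rep)
  )
  if (anyNA(sizes)) {
    return(list(keep = FALSE, reason = "chain_absent", sizes = sizes))
  }
  if (any(sizes < threshold)) {
    low <- names(sizes)[sizes < threshold]
    return(list(keep = FALSE,
                reason = paste0("below_threshold_", paste(low, collapse = "_")),
                sizes = sizes))
  }
  list(keep = TRUE, reason = NA_character_, sizes = sizes)
}

#' Apply molecule-count QC across a cohort
#'
#' Groups repertoires by (mouse, subset), applies [qc_exclude()] to each
#' alpha/beta pair, and returns the surviving repertoires plus a
#' decision log.
#'
#' @param repertoires List of `tcr_repertoire`s.
#' @param threshold Minimum molecule count per chain.
#' @return List: `kept` (repertoires passing QC), `decisions` (tibble
#'   with mouse_id, subset, alpha_size, beta_size, keep, reason).
#' @export
qc_cohort <- function(repertoires, threshold = 5000) {
  key <- vapply(repertoires, function(r) paste(r$mouse_id, r$subset), "")
  decisions <- list()
  kept <- list()
  for (k in unique(key)) {
    group <- repertoires[key == k]
    chains <- vapply(group, function(r) r$chain, "")
    a <- if ("alpha" %in% chains) group[[match("alpha", chains)]] else NULL
    b <- if ("beta" %in% chains) group[[match("beta", chains)]] else NULL
    d <- qc_exclude(a, b, threshold)
    decisions[[k]] <- tibble(
      mouse_id = group[[1]]$mouse_id, subset = group[[1]]$subset,
      alpha_size = d$sizes[["alpha"]], beta_size = d$sizes[["beta"]],
      keep = d$keep, reason = d$reason
    )
    if (d$keep) kept <- c(kept, group)
  }
  list(kept = kept, decisions = dplyr::bind_rows(decisions))
}

#' Down-sample a repertoire without replacement
#'
#' Rarefies a repertoire to exactly `target` molecules, as if the list
#' of molecules (each clone replicated by its count) were sampled
#' without replacement and re-tallied — a multivariate hypergeometric
#' draw. Implemented by sampling `target` distinct molecule positions
#' out of `1:size` and mapping them back to clones through the
#' cumulative counts, which realises exactly that distribution without
#' materialising the expanded molecule list.
#'
#' @param rep A `tcr_repertoire`.
#' @param target Number of molecules to retain; `1 <= target <= `
#'   repertoire size.
#' @param seed Optional integer seed for reproducibility.
#' @return A `tcr_repertoire` of the same identity with total count
#'   exactly `target`; clones drawn zero times are dropped.
#' @export
downsample <- function(rep, target, seed = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  size <- repertoire_size(rep)
  if (target < 1) stop("target must be >= 1")
  if (target > size) stop("target (", target, ") exceeds repertoire size (",
                          size, ")")
  if (target == size) return(rep)
  k <- as.numeric(rep$clones$count)
  draw <- function() {
    pos <- sample.int(size, target)
    tabulate(findInterval(pos, cumsum(k), left.open = TRUE) + 1L,
             nbins = length(k))
  }
  taken <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- rep
  out$clones <- rep$clones[taken > 0, ]
  out$clones$count <- as.integer(taken[taken > 0])
  out
}

as_count_vector <- function(x) {
  if (inherits(x, "tcr_repertoire")) {
    if (nrow(x$clones) == 0) stop("repertoire is empty")
    as.numeric(x$clones$count)
  } else {
    x <- as.numeric(x)
    if (length(x) == 0) stop("no counts supplied")
    if (any(x <= 0)) stop("counts must be positive")
    x
  }
}

#' Shannon diversity of a repertoire
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats, where \eqn{p_i} is the
#' proportional abundance of the i-th unique clonotype. `H` ranges from
#' 0 (a single clone) to `ln`(number of unique clonotypes) (all clones
#' equally abundant).
#'
#' @param x A `tcr_repertoire` or a vector of positive clone counts.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(x) {
  k <- as_count_vector(x)
  p <- k / sum(k)
  -sum(p * log(p))
}

#' Simpson diversity of a repertoire
#'
#' \eqn{\lambda = \sum_i p_i^2}, the probability that two molecules
#' drawn at random (with replacement) belong to the same clonotype,
#' together with the log-transformed form \eqn{\ln(1/\lambda)} on which
#' larger values mean higher diversity.
#'
#' @inheritParams shannon_index
#' @return List with `lambda` in (0, 1\] and `log_inverse`
#'   \eqn{= \ln(1/\lambda) \ge 0}.
#' @export
simpson_index <- function(x) {
  k <- as_count_vector(x)
  p <- k / sum(k)
  lambda <- sum(p^2)
  list(lambda = lambda, log_inverse = log(1 / lambda))
}

#' Cohort diversity table
#'
#' For each receptor type, every mouse's repertoire is down-sampled
#' without replacement to the smallest repertoire size observed for
#' that receptor type, and Shannon and Simpson indices are computed on
#' the down-sampled repertoire. Down-sampling is performed
#' independently for the two indices, each with a deterministic
#' per-(mouse, receptor type, index) sub-seed, so adding or removing a
#' mouse leaves the other mice's draws unchanged. Richness is computed
#' on the full repertoire: it is already normalised by repertoire size.
#'
#' @param repertoires List of amino-acid-level `tcr_repertoire`s that
#'   have passed QC.
#' @param seed Master integer seed.
#' @param richness_on_downsampled Compute richness on the (Shannon-)
#'   down-sampled repertoire instead of the full one. Default `FALSE`.
#' @return Tibble, one row per mouse x receptor type: repertoire size,
#'   unique count, richness, down-sampling target, `shannon`,
#'   `simpson_lambda`, `simpson_log`, and the two sub-seeds used.
#' @export
diversity_table <- function(repertoires, seed = 1L,
                            richness_on_downsampled = FALSE) {
  rts <- vapply(repertoires, receptor_type, "")
  rows <- list()
  for (rt in unique(rts)) {
    group <- repertoires[rts == rt]
    if (length(group) < 2) {
      warning("fewer than 2 mice for receptor type ", rt,
              "; diversity rows still emitted")
    }
    target <- min(vapply(group, repertoire_size, numeric(1)))
    for (rep in group) {
      seed_sh <- derive_seed(seed, rep$mouse_id, rt, "shannon")
      seed_si <- derive_seed(seed, rep$mouse_id, rt, "simpson")
      ds_sh <- downsample(rep, target, seed = seed_sh)
      ds_si <- downsample(rep, target, seed = seed_si)
      si <- simpson_index(ds_si)
      rows[[length(rows) + 1L]] <- tibble(
        mouse_id = rep$mouse_id,
        receptor_type = rt,
        repertoire_size = repertoire_size(rep),
        unique_count = unique_count(rep),
        richness = if (richness_on_downsampled) richness(ds_sh) else richness(rep),
        downsample_target = target,
        shannon = shannon_index(ds_sh),
        simpson_lambda = si$lambda,
        simpson_log = si$log_inverse,
        seed_shannon = seed_sh,
        seed_simpson = seed_si
      )
    }
  }
  dplyr::bind_rows(rows)
}
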