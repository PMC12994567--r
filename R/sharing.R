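#' Pairwise clonotype-sharing matrix
#'
#' For one receptor type, down-samples every mouse's amino-acid
#' repertoire to the smallest repertoire size in the cohort, reduces
#' each to its set of unique clonotype keys, and counts shared keys for
#' every mouse pair. Mice are processed in sorted `mouse_id` order with
#' per-mouse sub-seeds, so the result does not depend on input order.
#'
#' @param repertoires List of amino-acid-level `tcr_repertoire`s (may
#'   mix receptor types; the relevant ones are selected).
#' @param receptor_type One of `"CD4_alpha"`, `"CD4_beta"`,
#'   `"CD8_alpha"`, `"CD8_beta"`.
#' @param seed Master seed for the down-sampling draws.
#' @param downsample_target Optional explicit target; defaults to the
#'   minimum repertoire size across the selected mice.
#' @return An object of class `sharing_matrix`: list with `mouse_ids`,
#'   `receptor_type`, `S` (symmetric integer matrix; diagonal = each
#'   mouse's down-sampled unique count), `downsample_target`, `seed`,
#'   and `key_sets` (named list of unique clonotype keys per mouse).
#' @export
pairwise_shared <- function(repertoires, receptor_type, seed = 1L,
                            downsample_target = NULL) {
  rt <- match.arg(receptor_type, RECEPTOR_TYPES)
  rts <- vapply(repertoires, function(r) paste(r$subset, r$chain, sep = "_"), "")
  sel <- repertoires[rts == rt]
  if (length(sel) < 2) stop("need at least 2 mice for receptor type ", rt)
  ids <- vapply(sel, function(r) r$mouse_id, "")
  if (anyDuplicated(ids) > 0) stop("duplicate mouse_id for receptor type ", rt)
  sel <- sel[order(ids)]
  ids <- sort(ids)
  target <- if (is.null(downsample_target)) {
    min(vapply(sel, repertoire_size, numeric(1)))
  } else downsample_target
  key_sets <- lapply(sel, function(r) {
    ds <- downsample(r, target,
                     seed = derive_seed(seed, r$mouse_id, rt, "sharing"))
    clone_keys(ds)
  })
  names(key_sets) <- ids
  n <- length(ids)
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, i] <- length(key_sets[[i]])
    if (i < n) {
      for (j in (i + 1):n) {
        s <- length(intersect(key_sets[[i]], key_sets[[j]]))
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  structure(
    list(mouse_ids = ids, receptor_type = rt, S = S,
         downsample_target = target, seed = seed, key_sets = key_sets),
    class = "sharing_matrix"
  )
}

#' @export
print.sharing_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf(
    "<sharing_matrix> %s: %d mice, target %d molecules\n  shared clonotypes per pair: mean %.1f, range %d-%d\n",
    x$receptor_type, length(x$mouse_ids), as.integer(x$downsample_target),
    mean(off), min(off), max(off)))
  invisible(x)
}

#' Mean sharing as a percentage of unique clonotypes
#'
#' Mean off-diagonal shared count divided by the mean down-sampled
#' unique count, times 100: the fraction of a typical repertoire that a
#' typical pair of mice has in common.
#'
#' @param sm A `sharing_matrix`.
#' @return A percentage.
#' @export
sharing_percent <- function(sm) {
  stopifnot(inherits(sm, "sharing_matrix"))
  off <- sm$S[upper.tri(sm$S)]
  100 * mean(off) / mean(diag(sm$S))
}

#' Detect public clonotypes
#'
#' A clonotype is public when it occurs in at least
#' `ceiling(threshold * n_mice)` of the mice's (down-sampled) unique
#' clonotype sets.
#'
#' @param key_sets Named list of character vectors of clonotype keys
#'   (one per mouse), or a `sharing_matrix` (its `key_sets` are used).
#' @param threshold Prevalence threshold in (0, 1\]; default 0.75.
#' @return Tibble of public clonotypes (`key`, `n_mice`, `prevalence`),
#'   sorted by decreasing prevalence, with attributes `n_required`
#'   and `fraction_of_unique` (public keys as a share of all unique
#'   keys observed cohort-wide).
#' @export
public_clonotypes <- function(key_sets, threshold = 0.75) {
  if (inherits(key_sets, "sharing_matrix")) key_sets <- key_sets$key_sets
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  n_mice <- length(key_sets)
  if (n_mice < 2) stop("need at least 2 mice")
  tab <- table(unlist(lapply(key_sets, unique)))
  need <- ceiling(threshold * n_mice)
  pub <- tab[tab >= need]
  out <- tibble(
    key = names(pub),
    n_mice = as.integer(pub),
    prevalence = as.integer(pub) / n_mice
  )
  out <- out[order(-out$prevalence, out$key), ]
  attr(out, "n_required") <- as.integer(need)
  attr(out, "fraction_of_unique") <- nrow(out) / length(tab)
  out
}

#' Re-scaled dissimilarity from a sharing matrix
#'
#' The default re-scaling subtracts each shared count from the largest
#' off-diagonal shared count, so the most similar pair of mice has
#' dissimilarity exactly 0. The alternative `"proportional"` form is
#' `1 - S / max(S)`.
#'
#' @param sm A `sharing_matrix` (or a plain symmetric matrix of shared
#'   counts).
#' @param method `"shift"` (default, `max(S) - S`) or
#'   `"proportional"`.
#' @return Symmetric non-negative dissimilarity matrix with zero
#'   diagonal.
#' @export
sharing_to_dissimilarity <- function(sm, method = c("shift", "proportional")) {
  method <- match.arg(method)
  S <- if (inherits(sm, "sharing_matrix")) sm$S else as.matrix(sm)
  off <- S[upper.tri(S)]
  if (length(unique(off)) == 1) {
    warning("all pairs share equally; dissimilarity matrix is constant 0")
  }
  s_max <- max(off)
  d <- switch(method,
    shift = s_max - S,
    proportional = 1 - S / s_max
  )
  diag(d) <- 0
  d
}

#' Dendrogram over mice from a dissimilarity matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering; the leaf order
#' places more similar mice adjacently, the order used to arrange
#' sharing heatmaps.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal (row and
#'   column names identify the mice).
#' @return List: `order` (mouse labels in leaf order), `hclust` (the
#'   merge tree), `newick` (Newick serialisation).
#' @export
dendrogram_order <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10)) stop("d must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("d must have a zero diagonal")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("m", seq_len(nrow(d)))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  newick <- if (nrow(d) >= 3) ape::write.tree(ape::as.phylo(hc)) else NA_character_
  list(order = hc$labels[hc$order], hclust = hc, newick = newick)
}

#' Weighted principal coordinates analysis of repertoire dissimilarity
#'
#' Classical metric ordination (Gower double-centering of
#' \eqn{-d^2/2}, eigendecomposition), optionally with per-mouse row
#' weights. With uniform (or absent) weights this is classical PCoA.
#' Negative eigenvalues, which arise when `d` is not Euclidean, are
#' retained and reported; coordinates are returned for the positive
#' axes.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param weights Optional non-negative per-mouse weights (sum > 0).
#' @return List of class `tcr_pcoa`: `coordinates` (mice x axes),
#'   `eigenvalues` (decreasing; may include negatives),
#'   `proportion_explained` (per positive axis, relative to the sum of
#'   positive eigenvalues).
#' @export
repertoire_pcoa <- function(d, weights = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("d must be symmetric")
  n <- nrow(d)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be ", n, " non-negative numbers with positive sum")
  }
  if (all(d == 0)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PCo1"))
    return(structure(list(coordinates = coords, eigenvalues = rep(0, n - 1),
                          proportion_explained = numeric(0)),
                     class = "tcr_pcoa"))
  }
  fit <- vegan::wcmdscale(stats::as.dist(d), k = n - 1, eig = TRUE, w = weights)
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  coords <- as.matrix(fit$points)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords,
         eigenvalues = eig,
         proportion_explained = eig[pos] / sum(eig[pos])),
    class = "tcr_pcoa"
  )
}

#' Pair table for sharing covariate models
#'
#' One row per unordered pair of mice in a sharing matrix, carrying the
#' shared clonotype count and the pair covariates used by the sharing
#' model: same-sex indicator, absolute age difference, and age sum.
#' Optionally restricted to mice from given site(s) to remove
#' between-site structure.
#'
#' @param sm A `sharing_matrix`.
#' @param metadata Metadata tibble covering every mouse in `sm`.
#' @param site_filter Optional character vector of site labels to keep.
#' @return Tibble: `mouse_a`, `mouse_b`, `shared`, `same_sex`,
#'   `age_diff`, `age_sum`, `receptor_type`.
#' @export
build_pair_table <- function(sm, metadata, site_filter = NULL) {
  stopifnot(inherits(sm, "sharing_matrix"))
  ids <- sm$mouse_ids
  missing_ids <- setdiff(ids, metadata$mouse_id)
  if (length(missing_ids) > 0) {
    stop("mice in sharing matrix absent from metadata: ",
         paste(missing_ids, collapse = ", "))
  }
  md <- metadata[match(ids, metadata$mouse_id), ]
  keep <- if (is.null(site_filter)) rep(TRUE, length(ids)) else md$site %in% site_filter
  idx <- which(keep)
  if (length(idx) < 2) stop("fewer than 2 mice after site filter")
  pairs <- utils::combn(idx, 2)
  a <- pairs[1, ]
  b <- pairs[2, ]
  tibble(
    mouse_a = ids[a],
    mouse_b = ids[b],
    shared = sm$S[cbind(a, b)],
    same_sex = md$sex[a] == md$sex[b],
    age_diff = abs(md$age_weeks[a] - md$age_weeks[b]),
    age_sum = md$age_weeks[a] + md$age_weeks[b],
    receptor_type = sm$receptor_type
  )
}
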