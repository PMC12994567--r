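# Two repertoires with exactly `overlap` clonotype keys in common.
overlap_pair <- function(n1, n2, overlap) {
  shared <- toy_repertoire(rep(1, overlap), mouse = "a", prefix = "S")
  r1 <- toy_repertoire(rep(1, n1), mouse = "m1", prefix = "A")
  r2 <- toy_repertoire(rep(1, n2), mouse = "m2", prefix = "B")
  r1$clones[seq_len(overlap), ] <- shared$clones
  r2$clones[seq_len(overlap), ] <- shared$clones
  list(r1, r2)
}

test_that("pairwise shared counts equal brute-force set intersections", {
  pair <- overlap_pair(40, 40, 17)  # equal sizes: down-sampling is the identity
  sm <- pairwise_shared(pair, "CD4_alpha", seed = 1)
  expect_equal(sm$S["m1", "m2"], 17L)
  oracle <- length(intersect(clone_keys(pair[[1]]), clone_keys(pair[[2]])))
  expect_equal(sm$S["m1", "m2"], oracle)

  # identical repertoires share their full unique count
  twin <- toy_repertoire(rep(1, 25), mouse = "t1")
  twin2 <- twin
  twin2$mouse_id <- "t2"
  sm2 <- pairwise_shared(list(twin, twin2), "CD4_alpha", seed = 1)
  expect_equal(sm2$S["t1", "t2"], 25L)

  # disjoint repertoires share nothing
  dis <- list(toy_repertoire(rep(1, 20), mouse = "d1", prefix = "X"),
              toy_repertoire(rep(1, 20), mouse = "d2", prefix = "Y"))
  expect_equal(pairwise_shared(dis, "CD4_alpha", seed = 1)$S["d1", "d2"], 0L)

  expect_error(pairwise_shared(list(twin), "CD4_alpha"), "at least 2")
})

test_that("sharing matrices are symmetric, bounded, order-invariant", {
  set.seed(12)
  reps <- lapply(1:5, function(i) {
    r <- toy_repertoire(sample(1:8, 60, replace = TRUE),
                        mouse = paste0("m", i), prefix = "G")
    # shift a block of keys to be mouse-specific
    k <- sample(60, 25)
    r$clones$cdr3_aa[k] <- paste0(r$clones$cdr3_aa[k], "M", i)
    r
  })
  sm <- pairwise_shared(reps, "CD4_alpha", seed = 2)
  expect_true(isSymmetric(sm$S))
  off <- sm$S[upper.tri(sm$S)]
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lte(sm$S[i, j], min(sm$S[i, i], sm$S[j, j]))
  }
  sm_rev <- pairwise_shared(rev(reps), "CD4_alpha", seed = 2)
  expect_identical(sm$S, sm_rev$S)
})

test_that("public clonotype detection matches exhaustive prevalence counting", {
  sets <- list(
    m1 = c("a", "b", "c", "d"),
    m2 = c("a", "b", "x"),
    m3 = c("a", "b", "y"),
    m4 = c("a", "z")
  )
  pub <- public_clonotypes(sets, threshold = 0.75)
  # threshold 0.75 of 4 mice -> >= 3 mice
  expect_setequal(pub$key, c("a", "b"))
  expect_equal(pub$n_mice[pub$key == "a"], 4L)
  expect_equal(pub$n_mice[pub$key == "b"], 3L)

  # exhaustive oracle
  all_keys <- unique(unlist(sets))
  prev <- vapply(all_keys, function(k) {
    sum(vapply(sets, function(s) k %in% s, logical(1)))
  }, numeric(1))
  expect_setequal(pub$key, all_keys[prev >= ceiling(0.75 * 4)])

  strict <- public_clonotypes(sets, threshold = 1.0)
  expect_equal(strict$key, "a")
  # public count is non-increasing in the threshold
  counts <- vapply(c(0.25, 0.5, 0.75, 1), function(t) {
    nrow(public_clonotypes(sets, threshold = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(public_clonotypes(sets, threshold = 0), "threshold")
  expect_error(public_clonotypes(sets, threshold = 1.5), "threshold")
})

test_that("dissimilarity re-scaling zeroes the most similar pair", {
  S <- matrix(c(50, 10, 4,
                10, 50, 7,
                4, 7, 50), 3, 3,
              dimnames = rep(list(c("m1", "m2", "m3")), 2))
  d <- sharing_to_dissimilarity(S)
  expect_equal(d[upper.tri(d)], c(0, 6, 3))
  expect_equal(diag(d), c(m1 = 0, m2 = 0, m3 = 0))
  expect_equal(min(d[upper.tri(d)]), 0)
  expect_true(isSymmetric(d))

  # similarity and dissimilarity order reverse each other
  set.seed(5)
  S2 <- matrix(0L, 6, 6)
  S2[upper.tri(S2)] <- sample(0:40, 15)
  S2 <- S2 + t(S2)
  diag(S2) <- 60L
  d2 <- sharing_to_dissimilarity(S2)
  expect_equal(which.max(S2[upper.tri(S2)]), which.min(d2[upper.tri(d2)]))

  dp <- sharing_to_dissimilarity(S, method = "proportional")
  expect_equal(dp[1, 2], 0)
  expect_equal(dp[1, 3], 1 - 4 / 10)

  Sc <- matrix(5L, 3, 3)
  diag(Sc) <- 20L
  expect_warning(dc <- sharing_to_dissimilarity(Sc), "equally")
  expect_true(all(dc == 0))
})

test_that("UPGMA dendrograms order planted blocks contiguously", {
  set.seed(8)
  # two well-separated blocks of mice
  n <- 8
  block <- rep(1:2, each = n / 2)
  d <- matrix(9 + stats::runif(n * n), n, n)
  for (i in 1:n) for (j in 1:n) {
    if (block[i] == block[j]) d[i, j] <- stats::runif(1)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("m", 1:n)
  dend <- dendrogram_order(d)
  ord_blocks <- block[match(dend$order, rownames(d))]
  expect_equal(length(rle(ord_blocks)$lengths), 2)
  expect_match(dend$newick, "^\\(")

  # permutation invariance up to relabelling
  perm <- sample(n)
  dend_p <- dendrogram_order(d[perm, perm])
  expect_equal(sort(dend_p$hclust$height), sort(dend$hclust$height))

  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(dendrogram_order(d2)$hclust$height, 3)
  bad <- d
  bad[1, 2] <- 99
  expect_error(dendrogram_order(bad), "symmetric")
})

test_that("PCoA recovers planted configurations up to rotation", {
  set.seed(10)
  X <- matrix(stats::rnorm(10), 5, 2)
  d <- as.matrix(stats::dist(X))
  p <- repertoire_pcoa(d)
  expect_true(all(p$eigenvalues[1:2] > 0))
  # Euclidean input: no meaningfully negative eigenvalues
  expect_gt(min(p$eigenvalues), -1e-8 * max(p$eigenvalues))
  # Procrustes alignment of the first two axes onto the planted points
  Y <- p$coordinates[, 1:2]
  Xc <- scale(X, scale = FALSE)
  sv <- svd(t(Xc) %*% Y)
  rot <- sv$v %*% t(sv$u)
  expect_lt(max(abs(Y %*% rot - Xc)), 1e-8)

  # uniform weights reduce to classical PCoA
  cl <- stats::cmdscale(d, k = 2)
  pw <- repertoire_pcoa(d, weights = rep(1, 5))
  expect_lt(max(abs(abs(pw$coordinates[, 1:2]) - abs(cl))), 1e-10)

  expect_true(all(repertoire_pcoa(matrix(0, 4, 4))$coordinates == 0))

  # non-Euclidean dissimilarity: negative eigenvalues are retained
  dn <- matrix(1, 4, 4) - diag(4)
  dn[2, 3] <- dn[3, 2] <- 5
  pn <- repertoire_pcoa(dn)
  expect_true(any(pn$eigenvalues < 0))
  expect_equal(sum(pn$proportion_explained), 1)
})

test_that("pair tables enumerate unordered pairs with age covariates", {
  pair4 <- lapply(1:4, function(i) {
    toy_repertoire(rep(1, 10), mouse = paste0("m", i), prefix = paste0("Q", i))
  })
  sm <- pairwise_shared(pair4, "CD4_alpha", seed = 1)
  md <- tibble::tibble(
    mouse_id = paste0("m", 1:4), sex = c("M", "F", "F", "M"),
    age_weeks = c(10, 30, 5, 20), site = c("N", "N", "N", "W"),
    cohort = "wild")
  pt <- build_pair_table(sm, md)
  expect_equal(nrow(pt), 6)
  row12 <- pt[pt$mouse_a == "m1" & pt$mouse_b == "m2", ]
  expect_equal(row12$age_diff, 20)
  expect_equal(row12$age_sum, 40)
  expect_false(row12$same_sex)
  expect_true(pt$same_sex[pt$mouse_a == "m2" & pt$mouse_b == "m3"])

  ptN <- build_pair_table(sm, md, site_filter = "N")
  expect_equal(nrow(ptN), 3)
  expect_error(build_pair_table(sm, md[-1, ]), "absent")
})
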