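#' Hurwitz zeta function
#'
#' \eqn{\zeta(s, a) = \sum_{k=0}^{\infty} (a + k)^{-s}} for `s > 1`,
#' `a > 0`; the normalising constant of the discrete power law with
#' lower cutoff `a`. Computed by direct summation of the first `nterms`
#' terms plus an Euler–Maclaurin tail correction, accurate to well below
#' 1e-10 over the range used in fitting (`s` in (1, 25], integer `a`).
#'
#' @param s Exponent, scalar > 1.
#' @param a Shift, numeric vector > 0.
#' @param nterms Number of directly summed terms.
#' @return Numeric vector, same length as `a`.
#' @export
zeta_hurwitz <- function(s, a, nterms = 64L) {
  if (length(s) != 1 || s <= 1) stop("s must be a scalar > 1")
  if (any(a <= 0)) stop("a must be positive")
  k <- 0:(nterms - 1L)
  direct <- rowSums(outer(a, k, `+`)^(-s))
  b <- a + nterms
  tail <- b^(1 - s) / (s - 1) + 0.5 * b^(-s) +
    s * b^(-s - 1) / 12 - s * (s + 1) * (s + 2) * b^(-s - 3) / 720
  direct + tail
}

# P(X >= x) and P(X <= x) for the discrete power law p(k) ∝ k^(-alpha),
# k = xmin, xmin+1, ...
powerlaw_sf <- function(x, alpha, xmin) {
  zeta_hurwitz(alpha, x) / zeta_hurwitz(alpha, xmin)
}

powerlaw_cdf <- function(x, alpha, xmin) {
  1 - powerlaw_sf(x + 1, alpha, xmin)
}

# Inverse-CDF sampler for the discrete power law. Exact CDF inversion via
# an adaptively grown cumulative table for values up to `cap`; the rare
# draws beyond `cap` use the continuous approximation
# x = floor((xmin - 1/2) (1 - u)^(-1/(alpha-1)) + 1/2).
sample_powerlaw_u <- function(u, alpha, xmin, cap = 1e6) {
  z <- zeta_hurwitz(alpha, xmin)
  out <- integer(length(u))
  kmax <- min(1024, cap)
  repeat {
    kv <- xmin:(xmin + kmax - 1)
    cdf <- cumsum(kv^(-alpha)) / z
    if (cdf[length(cdf)] >= max(u) || xmin + kmax - 1 >= cap) break
    kmax <- min(kmax * 4, cap)
  }
  inside <- u <= cdf[length(cdf)]
  out[inside] <- xmin + findInterval(u[inside], cdf, left.open = TRUE)
  if (any(!inside)) {
    uo <- u[!inside]
    out[!inside] <- floor((xmin - 0.5) * (1 - uo)^(-1 / (alpha - 1)) + 0.5)
  }
  out
}

#' Sample clone sizes from a discrete power law
#'
#' Draws clone abundances from \eqn{P(k) \propto k^{-\alpha}},
#' \eqn{k \ge x_{min}}, the distribution family observed for TCR clone
#' sizes. Exact CDF inversion is used for values up to `cap`
#' (default 1e6); the far tail falls back to the rounded continuous
#' approximation.
#'
#' @param n Number of draws.
#' @param alpha Power-law exponent, must exceed 1.
#' @param xmin Positive integer lower cutoff.
#' @param seed Optional integer seed; draws are reproducible given it.
#' @param cap Largest exactly inverted value.
#' @return Integer vector of `n` clone sizes `>= xmin`.
#' @export
sample_clone_sizes <- function(n, alpha, xmin = 1L, seed = NULL, cap = 1e6) {
  if (n < 1) stop("n must be >= 1")
  if (alpha <= 1) stop("alpha must be > 1 (the zeta normaliser diverges)")
  if (xmin < 1) stop("xmin must be a positive integer")
  draw <- function() sample_powerlaw_u(stats::runif(n), alpha, xmin, cap)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Discrete power-law MLE at fixed xmin: minimise the negative
# log-likelihood n log zeta(alpha, xmin) + alpha * sum(log x_tail).
fit_alpha_at_xmin <- function(tail_vals, xmin) {
  n <- length(tail_vals)
  slog <- sum(log(tail_vals))
  nll <- function(alpha) n * log(zeta_hurwitz(alpha, xmin)) + alpha * slog
  stats::optimize(nll, interval = c(1.001, 25), tol = 1e-5)$minimum
}

ks_discrete <- function(tail_vals, alpha, xmin) {
  tab <- table(tail_vals)
  u <- as.numeric(names(tab))
  emp <- cumsum(as.numeric(tab)) / length(tail_vals)
  theo <- powerlaw_cdf(u, alpha, xmin)
  # sup distance over the discrete support: compare at and just below
  # each observed value
  max(abs(emp - theo), abs(c(0, emp[-length(emp)]) - powerlaw_cdf(u - 1, alpha, xmin)))
}

#' Fit a discrete power law to clone sizes
#'
#' Maximum-likelihood fit of \eqn{P(k) \propto k^{-\alpha}} to a clone
#' size distribution, with the lower cutoff `xmin` selected to minimise
#' the Kolmogorov–Smirnov distance between the empirical tail and the
#' fitted law (the standard discrete estimator of Clauset, Shalizi and
#' Newman). The exponent at each candidate cutoff is the zeta-function
#' MLE.
#'
#' @param counts Positive integer clone sizes (>= 10 observations; not
#'   all identical).
#' @param xmin Optional fixed cutoff; when supplied the KS search is
#'   skipped and `alpha` is estimated at that cutoff.
#' @param min_tail Smallest tail size considered during the cutoff
#'   search.
#' @param max_candidates Cap on the number of candidate cutoffs
#'   (quantile-thinned when exceeded).
#' @return An object of class `powerlaw_fit`: list with `alpha`, `xmin`,
#'   `ks_stat`, `n_tail`, `n`, `counts`, and (until [gof_pvalue()] is
#'   run) `p_value = NA`, `classification = NA`.
#' @export
fit_discrete_powerlaw <- function(counts, xmin = NULL, min_tail = 8L,
                                  max_candidates = 100L) {
  counts <- as.numeric(counts)
  if (length(counts) < 10) stop("need at least 10 observations")
  if (any(counts < 1 | counts != round(counts))) {
    stop("counts must be positive integers")
  }
  if (length(unique(counts)) == 1) {
    stop("all counts identical: degenerate distribution, no power-law fit")
  }
  if (is.null(xmin)) {
    vals <- sort(unique(counts))
    n_tail_at <- vapply(vals, function(v) sum(counts >= v), numeric(1))
    cand <- vals[n_tail_at >= max(2L, min_tail)]
    if (length(cand) == 0) cand <- vals[1]
    if (length(cand) > max_candidates) {
      idx <- unique(round(seq(1, length(cand), length.out = max_candidates)))
      cand <- cand[idx]
    }
    best <- NULL
    for (xm in cand) {
      tail_vals <- counts[counts >= xm]
      a <- fit_alpha_at_xmin(tail_vals, xm)
      d <- ks_discrete(tail_vals, a, xm)
      if (is.null(best) || d < best$ks_stat) {
        best <- list(alpha = a, xmin = xm, ks_stat = d,
                     n_tail = length(tail_vals))
      }
    }
  } else {
    tail_vals <- counts[counts >= xmin]
    if (length(tail_vals) < 2) stop("fewer than 2 observations above xmin")
    a <- fit_alpha_at_xmin(tail_vals, xmin)
    best <- list(alpha = a, xmin = xmin,
                 ks_stat = ks_discrete(tail_vals, a, xmin),
                 n_tail = length(tail_vals))
  }
  structure(
    c(best, list(n = length(counts), counts = counts,
                 p_value = NA_real_, classification = NA_character_)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.3f, xmin = %d, KS = %.4f (n_tail = %d / n = %d)\n",
    x$alpha, as.integer(x$xmin), x$ks_stat, x$n_tail, x$n))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap p = %.3f -> %s\n", x$p_value, x$classification))
  }
  invisible(x)
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Semi-parametric KS bootstrap: each replicate keeps the observed
#' sub-cutoff data (resampled with replacement) with probability equal
#' to its observed share, draws the remainder from the fitted law, then
#' refits — including re-selection of `xmin` — and records its KS
#' distance. The p-value is the proportion of replicate KS distances at
#' least as large as the observed one. A large p-value means the
#' power law is a plausible generator of the data.
#'
#' @param fit A `powerlaw_fit` from [fit_discrete_powerlaw()].
#' @param n_sim Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the replicate stream is reproducible.
#' @param cutoffs Classification cutoffs, passed to [classify_fit()].
#' @return The `fit`, with `p_value` set (and `classification`, via
#'   [classify_fit()]).
#' @export
gof_pvalue <- function(fit, n_sim = 500L, seed = NULL,
                       cutoffs = c(0.05, 0.1)) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (n_sim < 1) stop("n_sim must be >= 1")
  counts <- fit$counts
  n <- length(counts)
  body_vals <- counts[counts < fit$xmin]
  p_tail <- fit$n_tail / n
  one_rep <- function() {
    m <- stats::rbinom(1, n, p_tail)
    synth <- c(
      if (m > 0) sample_powerlaw_u(stats::runif(m), fit$alpha, fit$xmin),
      if (m < n) body_vals[sample.int(length(body_vals), n - m, replace = TRUE)]
    )
    if (length(unique(synth)) < 2) return(NA_real_)
    rf <- fit_discrete_powerlaw(synth)
    rf$ks_stat
  }
  run <- function() vapply(seq_len(n_sim), function(i) one_rep(), numeric(1))
  ks_rep <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ks_rep <- ks_rep[!is.na(ks_rep)]
  fit$p_value <- mean(ks_rep >= fit$ks_stat)
  fit$n_sim <- as.integer(n_sim)
  fit$classification <- classify_fit(fit$p_value, cutoffs)
  fit
}

#' Classify a power-law goodness-of-fit p-value
#'
#' Three categories: `fits` (p > 0.1), `borderline` (0.05 < p <= 0.1),
#' `does_not_fit` (p <= 0.05). Boundary values fall in the lower
#' category.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param cutoffs Two ordered cutoffs (lower, upper); defaults 0.05
#'   and 0.1.
#' @return Character vector of classifications.
#' @export
classify_fit <- function(p, cutoffs = c(0.05, 0.1)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  ifelse(p > cutoffs[2], "fits",
         ifelse(p > cutoffs[1], "borderline", "does_not_fit"))
}

#' Per-mouse power-law fits across a cohort
#'
#' Fits the clone-size distribution of every repertoire and classifies
#' its goodness of fit, one row per (mouse, receptor type).
#'
#' @param repertoires List of amino-acid-level `tcr_repertoire`s.
#' @param n_sim Bootstrap replicates per repertoire.
#' @param seed Master seed; each repertoire gets a deterministic
#'   sub-seed so results do not depend on cohort order.
#' @param cutoffs Classification cutoffs, passed to [classify_fit()].
#' @return Tibble: `mouse_id`, `receptor_type`, `alpha`, `xmin`,
#'   `ks_stat`, `p_value`, `classification`, `n_sim`, `seed`.
#' @export
powerlaw_table <- function(repertoires, n_sim = 500L, seed = 1L,
                           cutoffs = c(0.05, 0.1)) {
  rows <- lapply(repertoires, function(rep) {
    sub_seed <- derive_seed(seed, rep$mouse_id, receptor_type(rep), "gof")
    fit <- fit_discrete_powerlaw(rep$clones$count)
    fit <- gof_pvalue(fit, n_sim = n_sim, seed = sub_seed, cutoffs = cutoffs)
    tibble(mouse_id = rep$mouse_id, receptor_type = receptor_type(rep),
           alpha = fit$alpha, xmin = as.integer(fit$xmin),
           ks_stat = fit$ks_stat, p_value = fit$p_value,
           classification = fit$classification,
           n_sim = as.integer(n_sim), seed = sub_seed)
  })
  dplyr::bind_rows(rows)
}
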