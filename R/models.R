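tidy_glm <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4]
  )
}

glm_diagnostics <- function(fit) {
  r <- stats::residuals(fit, type = "deviance")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
  sh <- if (length(r) >= 3 && length(r) <= 5000 && stats::sd(r) > 0) {
    stats::shapiro.test(r)$p.value
  } else NA_real_
  list(dispersion = disp, resid_mean = mean(r), shapiro_p = sh,
       pass = is.na(sh) || sh > 1e-3)
}

# Assemble the stated design, dropping single-level factors (with a
# warning) and refusing zero-variance continuous covariates.
build_design <- function(data, response, factors, covariates,
                         interactions) {
  for (cv in covariates) {
    if (stats::var(data[[cv]]) == 0) {
      stop("covariate '", cv, "' has zero variance")
    }
  }
  keep_f <- factors[vapply(factors, function(f) {
    length(unique(data[[f]])) > 1
  }, logical(1))]
  dropped <- setdiff(factors, keep_f)
  if (length(dropped) > 0) {
    warning("single-level factor(s) dropped from design: ",
            paste(dropped, collapse = ", "))
  }
  terms <- c(keep_f, covariates)
  for (ia in interactions) {
    if (all(strsplit(ia, ":")[[1]] %in% terms)) terms <- c(terms, ia)
  }
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

fit_tcr_glm <- function(data, formula, family, family_tag) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (stats::var(y) == 0) stop("response is constant; nothing to model")
  fit <- stats::glm(formula, family = family, data = data)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  structure(
    list(fit = fit, family = family_tag,
         formula = deparse(formula),
         coefficients = tidy_glm(fit),
         n_obs = stats::nobs(fit),
         diagnostics = glm_diagnostics(fit)),
    class = "tcr_glm"
  )
}

#' @export
print.tcr_glm <- function(x, ...) {
  cat(sprintf("<tcr_glm> %s (%s), n = %d\n", x$formula, x$family, x$n_obs))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

join_metadata <- function(div_table, metadata) {
  missing_ids <- setdiff(div_table$mouse_id, metadata$mouse_id)
  if (length(missing_ids) > 0) {
    stop("mice absent from metadata: ", paste(missing_ids, collapse = ", "))
  }
  out <- dplyr::left_join(div_table, metadata, by = "mouse_id")
  out$receptor_type <- factor(out$receptor_type, levels = RECEPTOR_TYPES)
  out$receptor_type <- droplevels(out$receptor_type)
  out$sex <- factor(out$sex)
  out$site <- factor(out$site)
  out
}

#' Richness covariate model
#'
#' Gamma GLM with log link for repertoire richness, with the design
#' receptor type + site + age + sex + age-by-sex interaction. Richness
#' is strictly positive and right-skewed, which the gamma family with a
#' multiplicative (log) link models naturally.
#'
#' @param div_table Diversity table from [diversity_table()].
#' @param metadata Metadata tibble (`mouse_id`, `sex`, `age_weeks`,
#'   `site`, `cohort`).
#' @return A `tcr_glm`.
#' @export
fit_richness_model <- function(div_table, metadata) {
  data <- join_metadata(div_table, metadata)
  f <- build_design(data, "richness",
                    factors = c("receptor_type", "site", "sex"),
                    covariates = "age_weeks",
                    interactions = "age_weeks:sex")
  fit_tcr_glm(data, f, stats::Gamma(link = "log"), "gamma_log")
}

#' Diversity covariate model
#'
#' Gaussian GLM (identity link) for Shannon or log-inverse-Simpson
#' diversity, with the same design as the richness model.
#'
#' @inheritParams fit_richness_model
#' @param index `"shannon"` or `"simpson_log"`.
#' @return A `tcr_glm`.
#' @export
fit_diversity_model <- function(div_table, metadata,
                                index = c("shannon", "simpson_log")) {
  index <- match.arg(index)
  data <- join_metadata(div_table, metadata)
  f <- build_design(data, index,
                    factors = c("receptor_type", "site", "sex"),
                    covariates = "age_weeks",
                    interactions = "age_weeks:sex")
  fit_tcr_glm(data, f, stats::gaussian(), "gaussian")
}

#' Pairwise sharing covariate model
#'
#' Gaussian GLM for the number of clonotypes shared by a mouse pair:
#' receptor type, same-sex indicator, pairwise age difference, pairwise
#' age sum, and the two age-by-receptor-type interactions. The age-sum
#' and age-difference terms ask whether repertoires converge or diverge
#' as mice age. Pair rows are not independent (each mouse appears in
#' many pairs); an optional permutation test (shuffling ages across
#' mice) provides significance robust to that dependence.
#'
#' @param pairs Pair table from [build_pair_table()] (rows from one or
#'   more receptor types bound together).
#' @param permutations Number of age-permutation replicates for
#'   permutation p-values (0, the default, skips them and matches the
#'   plain GLM analysis).
#' @param metadata Metadata tibble; required when `permutations > 0`
#'   (ages are shuffled across mice and the pair covariates rebuilt).
#' @param seed Seed for the permutation draws.
#' @return A `tcr_glm`; when `permutations > 0` the coefficient table
#'   gains a `p_perm` column.
#' @export
fit_sharing_model <- function(pairs, permutations = 0L, metadata = NULL,
                              seed = 1L) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 10) stop("need at least 10 pair rows")
  if (length(unique(c(pairs$mouse_a, pairs$mouse_b))) < 3) {
    stop("pair table covers fewer than 3 distinct mice")
  }
  pairs$receptor_type <- droplevels(factor(pairs$receptor_type,
                                           levels = RECEPTOR_TYPES))
  pairs$same_sex <- factor(pairs$same_sex, levels = c(FALSE, TRUE),
                           labels = c("different", "same"))
  f <- build_design(pairs, "shared",
                    factors = c("receptor_type", "same_sex"),
                    covariates = c("age_diff", "age_sum"),
                    interactions = c("age_diff:receptor_type",
                                     "age_sum:receptor_type"))
  model <- fit_tcr_glm(pairs, f, stats::gaussian(), "gaussian")
  if (permutations > 0) {
    if (is.null(metadata)) {
      stop("metadata is required for the permutation test")
    }
    obs <- abs(model$coefficients$statistic)
    mice <- unique(c(pairs$mouse_a, pairs$mouse_b))
    age_of <- stats::setNames(
      metadata$age_weeks[match(mice, metadata$mouse_id)], mice)
    if (anyNA(age_of)) stop("metadata lacks ages for some paired mice")
    exceed <- rep(0, length(obs))
    withr::with_seed(seed, {
      for (b in seq_len(permutations)) {
        perm <- stats::setNames(sample(age_of), names(age_of))
        pp <- pairs
        pp$age_diff <- abs(perm[pp$mouse_a] - perm[pp$mouse_b])
        pp$age_sum <- perm[pp$mouse_a] + perm[pp$mouse_b]
        pfit <- stats::glm(f, family = stats::gaussian(), data = pp)
        pt <- summary(pfit)$coefficients[, 3]
        exceed <- exceed + (abs(pt)[model$coefficients$term] >= obs)
      }
    })
    model$coefficients$p_perm <- (exceed + 1) / (permutations + 1)
  }
  model
}

# Weighted-average model-matrix rows for EMMs: all factor-level
# combinations (equal weight), continuous covariates at their means.
emm_grid <- function(fit) {
  mf <- stats::model.frame(fit)
  vars <- attr(stats::terms(fit), "dataClasses")
  vars <- vars[names(vars) != names(mf)[1]]
  levs <- list()
  for (v in names(vars)) {
    levs[[v]] <- if (vars[v] %in% c("factor", "character", "logical")) {
      levels(factor(mf[[v]]))
    } else {
      mean(mf[[v]])
    }
  }
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  tt <- stats::delete.response(stats::terms(fit))
  X <- stats::model.matrix(tt, grid, xlev = fit$xlevels,
                           contrasts.arg = fit$contrasts)
  list(grid = grid, X = X)
}

#' Estimated marginal means and pairwise contrasts
#'
#' Model-based means for each level of a factor, averaged with equal
#' weight over the levels of the other factors and with continuous
#' covariates at their means, followed by all pairwise contrasts on the
#' link scale with Tukey (studentised-range) multiplicity adjustment.
#'
#' @param model A `tcr_glm`.
#' @param factor_name A factor term of the model (e.g.
#'   `"receptor_type"`).
#' @return List: `emmeans` (tibble of level, emmean, std_error) and
#'   `contrasts` (tibble of contrast, estimate, std_error, statistic,
#'   `p_value` Tukey-adjusted, `p_unadjusted`).
#' @export
emm_contrasts <- function(model, factor_name) {
  stopifnot(inherits(model, "tcr_glm"))
  fit <- model$fit
  g <- emm_grid(fit)
  if (!factor_name %in% names(g$grid) ||
      !is.character(g$grid[[factor_name]]) &&
      !is.factor(g$grid[[factor_name]])) {
    stop("'", factor_name, "' is not a factor term of the model")
  }
  levs <- unique(as.character(g$grid[[factor_name]]))
  L <- t(vapply(levs, function(l) {
    colMeans(g$X[g$grid[[factor_name]] == l, , drop = FALSE])
  }, numeric(ncol(g$X))))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  emm <- unname(drop(L %*% beta))
  emm_se <- unname(sqrt(diag(L %*% V %*% t(L))))
  k <- length(levs)
  pr <- utils::combn(k, 2)
  C <- matrix(0, ncol(pr), k)
  C[cbind(seq_len(ncol(pr)), pr[1, ])] <- 1
  C[cbind(seq_len(ncol(pr)), pr[2, ])] <- -1
  Lc <- C %*% L
  est <- unname(drop(Lc %*% beta))
  se <- unname(sqrt(diag(Lc %*% V %*% t(Lc))))
  tval <- est / se
  df <- stats::df.residual(fit)
  p_tukey <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                           lower.tail = FALSE)
  p_raw <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(
    emmeans = tibble(level = levs, emmean = emm, std_error = emm_se),
    contrasts = tibble(
      contrast = paste(levs[pr[1, ]], "-", levs[pr[2, ]]),
      estimate = est, std_error = se, statistic = tval,
      p_value = pmin(1, p_tukey), p_unadjusted = p_raw,
      adjustment = "tukey"
    )
  )
}

#' Per-level slopes of a continuous covariate
#'
#' The model-implied slope of a covariate within each level of a factor
#' (the analogue of estimated marginal trends), used post hoc to ask,
#' for example, how sharing changes with pair age sum within each
#' receptor type.
#'
#' @param model A `tcr_glm`.
#' @param covariate A continuous term of the model (e.g. `"age_sum"`).
#' @param by_factor Factor whose levels index the slopes.
#' @return Tibble: level, slope, std_error, statistic, p_value
#'   (unadjusted t-tests).
#' @export
emm_slopes <- function(model, covariate, by_factor) {
  stopifnot(inherits(model, "tcr_glm"))
  fit <- model$fit
  g <- emm_grid(fit)
  if (!covariate %in% names(g$grid)) {
    stop("'", covariate, "' is not a term of the model")
  }
  grid1 <- g$grid
  grid1[[covariate]] <- grid1[[covariate]] + 1
  tt <- stats::delete.response(stats::terms(fit))
  X1 <- stats::model.matrix(tt, grid1, xlev = fit$xlevels,
                            contrasts.arg = fit$contrasts)
  D <- X1 - g$X
  levs <- unique(as.character(g$grid[[by_factor]]))
  L <- t(vapply(levs, function(l) {
    colMeans(D[g$grid[[by_factor]] == l, , drop = FALSE])
  }, numeric(ncol(D))))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  est <- unname(drop(L %*% beta))
  se <- unname(sqrt(diag(L %*% V %*% t(L))))
  tval <- est / se
  df <- stats::df.residual(fit)
  tibble(level = levs, slope = est, std_error = se, statistic = tval,
         p_value = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE))
}
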