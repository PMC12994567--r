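#' Simulation configuration for synthetic TCR cohorts
#'
#' Assembles (and range-checks) the parameters of the synthetic cohort
#' generator. The generator emulates the statistical structure the
#' repertoire analysis assumes: power-law-distributed clone sizes,
#' greater clonotype sharing for alpha than for beta chains via a
#' chain-specific public clonotype pool, and an age- and sex-linked
#' multiplicative expansion of a small "chronic" clone subset that
#' lowers diversity with age while leaving the number of unique
#' clonotypes untouched.
#'
#' @param n_mice Number of mice in the cohort.
#' @param seed Master integer seed; every stage derives deterministic
#'   sub-seeds from it.
#' @param chains Per-chain settings: a named list (`alpha`, `beta`) of
#'   lists with `exponent` (power-law exponent > 1), `xmin` (positive
#'   integer cutoff), `n_unique` (unique clonotypes per repertoire) and
#'   `public_fraction` (share of a repertoire drawn from the chain's
#'   public pool, in \[0, 1\]).
#' @param age_effect_beta Per-week log-multiplier applied to chronic
#'   clone counts (0 disables the age effect).
#' @param sex_effect Multiplier on `age_effect_beta` for mice of sex
#'   `sex_effect_sex`.
#' @param sex_effect_sex Which sex receives `sex_effect` (default "F").
#' @param chronic_fraction Fraction of each repertoire's clonotypes
#'   designated chronic (default 0.01).
#' @param chronic_from Where chronic clones are drawn from:
#'   `"private"` (default; expansions are idiosyncratic), `"public"`,
#'   or `"any"`.
#' @param age_range Age range in weeks, uniform sampling (default
#'   2-49 weeks, the span observed in wild-caught animals).
#' @param sites Named numeric vector of site mixture weights.
#' @param cohort Cohort label for the metadata table.
#' @param cdr3_length_range CDR3 amino-acid length range (uniform).
#' @param v_catalog,j_catalog Gene-segment label catalogues.
#' @param pool_factor Public pool size as a multiple of the number of
#'   public clonotypes each mouse carries; pool membership is sampled
#'   with Zipf (1/rank) weights so top-ranked pool keys recur in nearly
#'   every mouse and form the detectable public set.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_mice = 60L,
    seed = 1L,
    chains = list(
      alpha = list(exponent = 2.5, xmin = 1L, n_unique = 1000L,
                   public_fraction = 0.06),
      beta = list(exponent = 2.5, xmin = 1L, n_unique = 1000L,
                  public_fraction = 0.025)
    ),
    age_effect_beta = 0.02,
    sex_effect = 1.5,
    sex_effect_sex = "F",
    chronic_fraction = 0.01,
    chronic_from = c("private", "public", "any"),
    age_range = c(2, 49),
    sites = c(Nottingham = 0.94, Wirral = 0.06),
    cohort = "wild",
    cdr3_length_range = c(9L, 17L),
    v_catalog = sprintf("V%02d", 1:30),
    j_catalog = sprintf("J%02d", 1:12),
    pool_factor = 2) {
  chronic_from <- match.arg(chronic_from)
  for (ch in c("alpha", "beta")) {
    cs <- chains[[ch]]
    if (is.null(cs)) stop("chains must contain settings for '", ch, "'")
    if (cs$exponent <= 1) stop(ch, ": power-law exponent must be > 1")
    if (cs$n_unique < 1) stop(ch, ": n_unique must be >= 1")
    if (cs$public_fraction < 0 || cs$public_fraction > 1) {
      stop(ch, ": public_fraction must lie in [0, 1]")
    }
  }
  if (cdr3_length_range[1] > cdr3_length_range[2]) {
    stop("cdr3_length_range must be (min, max) with min <= max")
  }
  if (age_range[1] > age_range[2]) stop("age_range must be (min, max)")
  if (length(v_catalog) == 0 || length(j_catalog) == 0) {
    stop("gene-segment catalogues must be non-empty")
  }
  structure(
    list(n_mice = as.integer(n_mice), seed = as.integer(seed), chains = chains,
         age_effect_beta = age_effect_beta, sex_effect = sex_effect,
         sex_effect_sex = sex_effect_sex, chronic_fraction = chronic_fraction,
         chronic_from = chronic_from, age_range = age_range, sites = sites,
         cohort = cohort, cdr3_length_range = as.integer(cdr3_length_range),
         v_catalog = v_catalog, j_catalog = j_catalog,
         pool_factor = pool_factor),
    class = "simulation_config"
  )
}

# amino acids and a flat codon table (stops excluded) for fast
# vectorised reverse translation
aa_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      gc <- gc[gc != "*"]
      ord <- order(gc)
      codons <- names(gc)[ord]
      aa <- unname(gc[ord])
      aas <- unique(aa)
      start <- match(aas, aa)
      n_codons <- as.integer(table(factor(aa, levels = aas)))
      tab <<- list(aas = aas, codons = codons, start = start,
                   n_codons = n_codons)
    }
    tab
  }
})

# n random clonotypes: uniform V/J labels, CDR3 amino-acid sequences of
# uniform length over the configured range, residues uniform over the 20
# amino acids, plus one reverse-translated (stop-free) nucleotide
# sequence per clonotype. Fully vectorised (all residues drawn in one
# call; sequences cut out of one concatenated string); consumes the
# current RNG stream.
generate_clonotypes <- function(n, config) {
  tab <- aa_codon_table()
  lr <- config$cdr3_length_range
  lens <- if (lr[1] == lr[2]) rep(lr[1], n) else sample(lr[1]:lr[2], n, replace = TRUE)
  v <- sample(config$v_catalog, n, replace = TRUE)
  j <- sample(config$j_catalog, n, replace = TRUE)
  total <- sum(lens)
  ai <- sample.int(length(tab$aas), total, replace = TRUE)
  pick <- tab$start[ai] + floor(stats::runif(total) * tab$n_codons[ai])
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  aa_seq <- substring(paste(tab$aas[ai], collapse = ""), starts, ends)
  nt_seq <- substring(paste(tab$codons[pick], collapse = ""),
                      3L * starts - 2L, 3L * ends)
  tibble(v_label = v, j_label = j, cdr3_nt = nt_seq, cdr3_aa = aa_seq)
}

#' Generate a public clonotype pool
#'
#' Builds `n` distinct amino-acid clonotypes (collision-free by
#' rejection) to serve as a chain's public pool: the clonotypes that
#' can recur across mice.
#'
#' @param n Pool size (>= 1).
#' @param config A `simulation_config` (catalogues and CDR3 lengths are
#'   taken from it).
#' @param seed Integer seed.
#' @return Tibble of `n` unique clonotypes with columns `v_label`,
#'   `j_label`, `cdr3_nt`, `cdr3_aa`.
#' @export
make_clonotype_pool <- function(n, config, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(seed, {
    pool <- generate_clonotypes(n, config)
    key <- paste(pool$v_label, pool$cdr3_aa, pool$j_label, sep = "|")
    while (anyDuplicated(key) > 0) {
      dup <- which(duplicated(key))
      pool[dup, ] <- generate_clonotypes(length(dup), config)
      key <- paste(pool$v_label, pool$cdr3_aa, pool$j_label, sep = "|")
    }
    pool
  })
}

chain_pool_size <- function(config, chain) {
  cs <- config$chains[[chain]]
  m <- round(cs$public_fraction * cs$n_unique)
  max(1L, as.integer(ceiling(config$pool_factor * max(m, 1L))))
}

#' Simulate the four repertoires of one mouse
#'
#' Builds CD4/CD8 x alpha/beta amino-acid repertoires for one mouse.
#' Each repertoire holds exactly `n_unique` clonotypes:
#' `round(public_fraction * n_unique)` drawn from the chain's public
#' pool with 1/rank weights, the remainder private. Base counts come
#' from the chain's discrete power law; the designated chronic subset
#' (a fraction `chronic_fraction` of clonotypes) has its counts
#' multiplied by `exp(age_effect_beta * age * sex_multiplier)` and
#' rounded up. The ceiling keeps every count >= 1, so the unique
#' clonotype count (richness numerator) is unchanged by the age
#' effect while Shannon/Simpson diversity decreases.
#'
#' @param meta One-row metadata (list or tibble row) with `mouse_id`,
#'   `sex`, `age_weeks`.
#' @param config A `simulation_config`.
#' @param pools Named list (`alpha`, `beta`) of pool tibbles from
#'   [make_clonotype_pool()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return Named list of four `tcr_repertoire`s
#'   (`CD4_alpha`, `CD4_beta`, `CD8_alpha`, `CD8_beta`).
#' @export
simulate_mouse <- function(meta, config, pools, seed = config$seed) {
  meta <- as.list(meta)
  age <- as.numeric(meta$age_weeks)
  sex_mult <- if (identical(meta$sex, config$sex_effect_sex)) config$sex_effect else 1
  out <- list()
  for (subset in SUBSETS) {
    for (chain in CHAINS) {
      rt <- paste(subset, chain, sep = "_")
      cs <- config$chains[[chain]]
      pool <- pools[[chain]]
      sub_seed <- derive_seed(seed, meta$mouse_id, rt, "sim")
      clones <- withr::with_seed(sub_seed, {
        n_pub <- round(cs$public_fraction * cs$n_unique)
        n_priv <- cs$n_unique - n_pub
        pub <- if (n_pub > 0) {
          w <- 1 / seq_len(nrow(pool))
          pool[sample(nrow(pool), n_pub, prob = w), ]
        } else pool[0, ]
        priv <- generate_clonotypes(n_priv, config)
        all_cl <- dplyr::bind_rows(pub, priv)
        key <- paste(all_cl$v_label, all_cl$cdr3_aa, all_cl$j_label, sep = "|")
        while (anyDuplicated(key) > 0) {
          dup <- which(duplicated(key) & seq_along(key) > n_pub)
          if (length(dup) == 0) break
          all_cl[dup, ] <- generate_clonotypes(length(dup), config)
          key <- paste(all_cl$v_label, all_cl$cdr3_aa, all_cl$j_label, sep = "|")
        }
        counts <- sample_clone_sizes(cs$n_unique, cs$exponent, cs$xmin)
        n_chronic <- ceiling(config$chronic_fraction * cs$n_unique)
        candidates <- switch(config$chronic_from,
          private = if (n_priv > 0) n_pub + seq_len(n_priv) else seq_len(cs$n_unique),
          public = if (n_pub > 0) seq_len(n_pub) else seq_len(cs$n_unique),
          any = seq_len(cs$n_unique)
        )
        chronic <- candidates[sample.int(length(candidates),
                                         min(n_chronic, length(candidates)))]
        mult <- exp(config$age_effect_beta * age * sex_mult)
        counts[chronic] <- ceiling(counts[chronic] * mult)
        all_cl$count <- as.integer(counts)
        all_cl
      })
      out[[rt]] <- repertoire(clones, mouse_id = meta$mouse_id,
                              subset = subset, chain = chain,
                              level = "amino_acid")
    }
  }
  out
}

#' Simulate a full cohort
#'
#' Draws the metadata table (sex Bernoulli(0.5), age uniform on the age
#' range, site by mixture weights), builds the per-chain public pools,
#' and simulates every mouse. Optionally writes the cohort to disk as
#' AIRR TSV clonotype tables (one per mouse x subset x chain), a
#' metadata TSV, and a JSON echo of the configuration. Fully
#' reproducible: the same config gives byte-identical outputs.
#'
#' @param config A `simulation_config`.
#' @param dir Optional output directory (created if needed).
#' @return List: `metadata` (tibble), `repertoires` (flat named list of
#'   `tcr_repertoire`s, names `<mouse>.<receptor_type>`), `pools`, and
#'   `files` (written paths, when `dir` is given).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  metadata <- withr::with_seed(derive_seed(seed, "metadata"), {
    n <- config$n_mice
    tibble(
      mouse_id = sprintf("M%03d", seq_len(n)),
      sex = ifelse(stats::runif(n) < 0.5, "F", "M"),
      age_weeks = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
      site = sample(names(config$sites), n, replace = TRUE,
                    prob = config$sites),
      cohort = config$cohort
    )
  })
  pools <- list(
    alpha = make_clonotype_pool(chain_pool_size(config, "alpha"), config,
                                seed = derive_seed(seed, "pool", "alpha")),
    beta = make_clonotype_pool(chain_pool_size(config, "beta"), config,
                               seed = derive_seed(seed, "pool", "beta"))
  )
  repertoires <- list()
  for (i in seq_len(nrow(metadata))) {
    mouse <- simulate_mouse(metadata[i, ], config, pools, seed = seed)
    names(mouse) <- paste(metadata$mouse_id[i], names(mouse), sep = ".")
    repertoires <- c(repertoires, mouse)
  }
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
    files <- character(0)
    for (nm in names(repertoires)) {
      path <- file.path(dir, paste0(sub("\\.", "_", nm), ".tsv"))
      write_clonotype_table(repertoires[[nm]], path, dialect = "airr")
      files <- c(files, path)
    }
    meta_path <- file.path(dir, "metadata.tsv")
    write_metadata(metadata, meta_path)
    cfg_path <- file.path(dir, "simulation_config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    files <- c(files, meta_path, cfg_path)
  }
  list(metadata = metadata, repertoires = repertoires, pools = pools,
       files = files)
}
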