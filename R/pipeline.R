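#' Validate a pipeline configuration
#'
#' Reads a JSON pipeline configuration (or takes an equivalent list),
#' fills defaults, and range-checks every field, reporting all
#' violations at once. A configuration holds either a `simulate` block
#' (arguments for [simulation_config()]) or an `input_dir` of clonotype
#' tables plus `metadata.tsv`.
#'
#' @param config Path to a JSON file, or a list.
#' @return The validated configuration (class `pipeline_config`) with
#'   defaults filled; if any check fails, an error listing every
#'   violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a JSON object or a list")
  defaults <- list(qc_threshold = 5000, gof_n_sim = 500L,
                   public_threshold = 0.75,
                   powerlaw_p_cutoffs = c(0.05, 0.1),
                   master_seed = 1L, site_filter = NULL, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  has_sim <- !is.null(config$simulate)
  has_dir <- !is.null(config$input_dir)
  if (!has_sim && !has_dir) note("one of 'simulate' or 'input_dir' is required")
  if (has_sim && has_dir) note("'simulate' and 'input_dir' are mutually exclusive")
  if (has_dir && !dir.exists(config$input_dir)) {
    note(paste0("input_dir does not exist: ", config$input_dir))
  }
  if (!is.numeric(config$qc_threshold) || config$qc_threshold < 1) {
    note("qc_threshold must be a positive number")
  }
  if (!is.numeric(config$gof_n_sim) || config$gof_n_sim < 1) {
    note("gof_n_sim must be >= 1")
  }
  if (!is.numeric(config$public_threshold) ||
      config$public_threshold <= 0 || config$public_threshold > 1) {
    note("public_threshold must lie in (0, 1]")
  }
  pc <- config$powerlaw_p_cutoffs
  if (!is.numeric(pc) || length(pc) != 2 || pc[1] >= pc[2] ||
      any(pc < 0 | pc > 1)) {
    note("powerlaw_p_cutoffs must be two ordered values in [0, 1]")
  }
  if (!is.numeric(config$master_seed) || config$master_seed < 0 ||
      config$master_seed != round(config$master_seed)) {
    note("master_seed must be a non-negative integer")
  }
  if (has_sim) {
    sim_ok <- tryCatch({
      do.call(simulation_config, config$simulate)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(sim_ok)) note(paste0("simulate block: ", sim_ok))
  }
  if (length(errs) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  config$master_seed <- as.integer(config$master_seed)
  structure(config, class = "pipeline_config")
}

#' Ingest a cohort from a directory of clonotype tables
#'
#' Expects `metadata.tsv` plus one AIRR TSV per repertoire named
#' `<mouse>_<subset>_<chain>.tsv` (the layout [simulate_cohort()]
#' writes). Each table is read, filtered to productive CDR3s, and
#' collapsed to an amino-acid repertoire.
#'
#' @param input_dir Directory path.
#' @param dialect Clonotype table dialect.
#' @return List: `metadata`, `repertoires` (named list), `filter_report`
#'   (summed exclusion counts by reason).
#' @export
ingest_cohort <- function(input_dir, dialect = "airr") {
  metadata <- read_metadata(file.path(input_dir, "metadata.tsv"))
  files <- list.files(input_dir, pattern = "_(CD4|CD8)_(alpha|beta)\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no clonotype tables found in ", input_dir)
  repertoires <- list()
  report <- c(missing_cdr3 = 0L, out_of_frame = 0L, stop_codon = 0L)
  for (f in files) {
    parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
    np <- length(parts)
    subset <- parts[np - 1]
    chain <- parts[np]
    mouse_id <- paste(parts[seq_len(np - 2)], collapse = "_")
    recs <- read_clonotype_table(f, dialect = dialect)
    fl <- apply_record_filters(recs)
    for (nm in names(fl$report)) report[nm] <- report[nm] + fl$report[nm]
    rep <- collapse_to_aa(fl$kept, mouse_id = mouse_id, subset = subset,
                          chain = chain)
    repertoires[[paste0(mouse_id, ".", subset, "_", chain)]] <- rep
  }
  list(metadata = metadata, repertoires = repertoires,
       filter_report = report[report > 0])
}

write_tsv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full repertoire analysis pipeline
#'
#' Orchestrates simulate/ingest, molecule-count QC, the diversity
#' table, per-mouse power-law fits, sharing matrices with public
#' clonotypes, dendrograms and PCoA, and the richness/diversity/sharing
#' covariate models. Every stage's table is written to the output
#' directory together with a JSON manifest; a rerun with the same
#' configuration reproduces all outputs byte-identically.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a
#'   list/path accepted by it).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  manifest <- list(package_version = as.character(utils::packageVersion("wildtcr")),
                   config = unclass(config), stages = list())

  cohort <- if (!is.null(config$simulate)) {
    stage("simulate", {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      simulate_cohort(do.call(simulation_config, sim_args))
    })
  } else {
    stage("ingest", ingest_cohort(config$input_dir))
  }
  metadata <- cohort$metadata
  write_tsv_out(metadata, out_dir, "metadata.tsv")
  manifest$stages$input <- list(n_mice = nrow(metadata),
                                n_repertoires = length(cohort$repertoires))

  qc <- stage("qc", qc_cohort(cohort$repertoires, threshold = config$qc_threshold))
  write_tsv_out(qc$decisions, out_dir, "qc_decisions.tsv")
  manifest$stages$qc <- list(n_pairs = nrow(qc$decisions),
                             n_kept_pairs = sum(qc$decisions$keep),
                             n_repertoires_kept = length(qc$kept))
  if (length(qc$kept) == 0) {
    message("[qc] no repertoires pass the molecule-count threshold; stopping")
    manifest$stages$result <- "no_analysable_mice"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  div <- stage("diversity", diversity_table(qc$kept, seed = seed))
  write_tsv_out(div, out_dir, "diversity.tsv")
  manifest$stages$diversity <- list(n_rows = nrow(div),
                                    n_mice = length(unique(div$mouse_id)))

  pl <- stage("powerlaw", powerlaw_table(qc$kept, n_sim = config$gof_n_sim,
                                         seed = seed,
                                         cutoffs = config$powerlaw_p_cutoffs))
  write_tsv_out(pl, out_dir, "powerlaw.tsv")
  manifest$stages$powerlaw <- list(
    n_rows = nrow(pl),
    classification = as.list(table(pl$classification)))

  rts <- sort(unique(vapply(qc$kept, receptor_type, "")))
  pair_tables <- list()
  manifest$stages$sharing <- list()
  for (rt in rts) {
    n_rt <- sum(vapply(qc$kept, receptor_type, "") == rt)
    if (n_rt < 2) next
    sm <- stage(paste0("sharing_", rt), pairwise_shared(qc$kept, rt, seed = seed))
    write_tsv_out(cbind(mouse_id = rownames(sm$S), as.data.frame(sm$S)),
                  out_dir, paste0("sharing_", rt, ".tsv"))
    pub <- public_clonotypes(sm, threshold = config$public_threshold)
    write_tsv_out(pub, out_dir, paste0("public_", rt, ".tsv"))
    d <- sharing_to_dissimilarity(sm)
    if (length(sm$mouse_ids) >= 3) {
      dend <- dendrogram_order(d)
      writeLines(dend$newick, file.path(out_dir, paste0("dendrogram_", rt, ".nwk")))
      pc <- repertoire_pcoa(d)
      write_tsv_out(cbind(mouse_id = rownames(pc$coordinates),
                          as.data.frame(pc$coordinates)),
                    out_dir, paste0("pcoa_", rt, ".tsv"))
    }
    pair_tables[[rt]] <- build_pair_table(sm, metadata,
                                          site_filter = config$site_filter)
    manifest$stages$sharing[[rt]] <- list(
      n_mice = length(sm$mouse_ids),
      downsample_target = sm$downsample_target,
      mean_shared = mean(sm$S[upper.tri(sm$S)]),
      sharing_percent = sharing_percent(sm),
      n_public = nrow(pub))
  }
  pairs <- dplyr::bind_rows(pair_tables)
  if (nrow(pairs) > 0) write_tsv_out(pairs, out_dir, "pairs.tsv")

  models <- stage("models", {
    out <- list()
    out$richness <- fit_richness_model(div, metadata)
    out$shannon <- fit_diversity_model(div, metadata, index = "shannon")
    out$simpson <- fit_diversity_model(div, metadata, index = "simpson_log")
    if (nrow(pairs) >= 10) out$sharing <- fit_sharing_model(pairs)
    out
  })
  for (nm in names(models)) {
    write_tsv_out(models[[nm]]$coefficients, out_dir,
                  paste0("model_", nm, ".tsv"))
    if ("receptor_type" %in% names(models[[nm]]$fit$xlevels)) {
      emm <- emm_contrasts(models[[nm]], "receptor_type")
      write_tsv_out(emm$contrasts, out_dir, paste0("emm_", nm, ".tsv"))
    }
  }
  if (!is.null(models$sharing)) {
    slopes <- dplyr::bind_rows(
      cbind(covariate = "age_diff",
            emm_slopes(models$sharing, "age_diff", "receptor_type")),
      cbind(covariate = "age_sum",
            emm_slopes(models$sharing, "age_sum", "receptor_type"))
    )
    write_tsv_out(slopes, out_dir, "emm_sharing_slopes.tsv")
  }
  manifest$stages$models <- lapply(models, function(m) {
    list(formula = m$formula, family = m$family, n_obs = m$n_obs)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
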