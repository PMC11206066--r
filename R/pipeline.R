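#' Run the full community-assembly analysis pipeline
#'
#' Orchestrates every stage in dependency order on one dataset with one
#' seed: data loading (or synthesis), multivariate-regression-tree banding,
#' per-band and overall niche classification, neutral-model fits, C-score /
#' SES null analysis, RDA + envfit + variance partitioning, and diversity
#' statistics. All outputs are TSV files under `output_dir` plus a JSON
#' manifest recording the configuration, seed, package version and md5
#' hashes of every output. Stage progress is logged to stderr; nothing is
#' written to stdout.
#'
#' Per-stage RNG seeds are derived deterministically from the master seed,
#' so the same configuration reproduces every stochastic output byte for
#' byte. If the metadata lacks a full covariate block, the RDA/VPA stage is
#' skipped with a notice and the rest proceeds.
#'
#' @param config a [run_config()]; `output_dir` must be set.
#' @param table,metadata an [otu_table] and `sample_metadata` to analyze;
#'   leave `NULL` to synthesize a dataset from `synth`.
#' @param synth a [synth_spec()] used when no table is given.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, table = NULL, metadata = NULL,
                         synth = NULL) {
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(),
                                             "%H:%M:%S")), ...)
  seed_for <- function(k) (config$rng_seed + 7919L * k) %% 2147483647L
  stages <- list()
  files <- character(0)
  record <- function(stage, fs) {
    stages[[stage]] <<- list(outputs = basename(fs))
    files <<- c(files, fs)
  }

  # -- stage: data ----------------------------------------------------------
  log_stage("stage data")
  truth <- NULL
  if (is.null(table)) {
    if (is.null(synth)) synth <- synth_spec(rng_seed = seed_for(1L))
    sim <- simulate_dataset(synth)
    table <- sim$table; metadata <- sim$metadata; truth <- sim$truth
    write_ground_truth(truth, out("ground_truth_otus.tsv"),
                       out("ground_truth_samples.tsv"))
    record("simulate", c(out("ground_truth_otus.tsv"),
                         out("ground_truth_samples.tsv")))
  }
  validate_otu_table(table)
  write_otu_table(table, out("otu_table.tsv"))
  fs <- out("otu_table.tsv")
  if (!is.null(metadata)) {
    write_metadata(metadata, out("metadata.tsv"))
    fs <- c(fs, out("metadata.tsv"))
  }
  record("data", fs)

  # -- stage: elevation banding (MRT) --------------------------------------
  band <- NULL
  if (!is.null(metadata) && "MEA" %in% names(metadata)) {
    log_stage("stage mrt")
    mrt_fit <- fit_mrt(table, metadata, seed = seed_for(2L))
    band <- mrt_fit$band
    sp <- summary(mrt_fit$model)
    if (!is.null(sp))
      utils::write.table(sp, out("mrt_splits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    utils::write.table(mrt_fit$model$cv_table, out("mrt_cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(band),
                                  band = as.character(band)),
                       out("bands.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("mrt", c(out("mrt_cv.tsv"), out("bands.tsv")))
  } else {
    message("no MEA in metadata: banding skipped")
  }

  band_subsets <- list(overall = seq_len(ncol(table)))
  if (!is.null(band) && nlevels(band) > 1)
    for (b in levels(band))
      band_subsets[[b]] <- which(as.character(band) == b)

  subset_table <- function(idx) {
    sub <- unclass(table)[, idx, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    otu_table(sub)
  }

  # -- stage: niche classification -----------------------------------------
  log_stage("stage niche classification")
  niche_all <- NULL
  niche_rows <- list()
  for (nm in names(band_subsets)) {
    sub <- subset_table(band_subsets[[nm]])
    cls <- classify_otus(sub, run_config(seed_for(3L), config$n_permutations,
                                         ci_level = config$ci_level))
    cls$scope <- nm
    niche_rows[[nm]] <- cls
    if (nm == "overall") niche_all <- cls
  }
  niche_df <- do.call(rbind, niche_rows)
  utils::write.table(niche_df, out("niche_classification.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  record("niche", out("niche_classification.tsv"))

  # -- stage: neutral model -------------------------------------------------
  log_stage("stage neutral model")
  ncm_rows <- list(); ncm_otus <- list()
  for (nm in names(band_subsets)) {
    fit <- tryCatch(fit_ncm(subset_table(band_subsets[[nm]]), config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("NCM failed for scope ", nm, ": ", conditionMessage(fit))
      next
    }
    ncm_rows[[nm]] <- data.frame(scope = nm, m = fit$m, Nm = fit$Nm,
                                 N = fit$N, r_squared = fit$r_squared,
                                 frac_above = fit$partition_fractions[1],
                                 frac_within = fit$partition_fractions[2],
                                 frac_below = fit$partition_fractions[3])
    po <- fit$otus; po$scope <- nm
    ncm_otus[[nm]] <- po
  }
  utils::write.table(do.call(rbind, ncm_rows), out("ncm_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, ncm_otus), out("ncm_otus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  record("ncm", c(out("ncm_summary.tsv"), out("ncm_otus.tsv")))

  # -- stage: co-occurrence null -------------------------------------------
  log_stage("stage C-score / SES")
  cs_rows <- list()
  for (nm in names(band_subsets)) {
    res <- ses_cscore(subset_table(band_subsets[[nm]]),
                      run_config(seed_for(4L), config$n_permutations))
    cs_rows[[nm]] <- data.frame(scope = nm, c_score_obs = res$c_score_obs,
                                null_mean = res$null_mean,
                                null_sd = res$null_sd, ses = res$ses,
                                n_null = res$n_null,
                                direction = res$direction)
  }
  utils::write.table(do.call(rbind, cs_rows), out("cscore.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  record("cscore", out("cscore.tsv"))

  # -- stage: ordination / VPA ----------------------------------------------
  blocks_def <- covariate_blocks()
  have_blocks <- !is.null(metadata) &&
    all(unlist(blocks_def) %in% names(metadata))
  if (have_blocks) {
    log_stage("stage RDA / envfit / VPA")
    meta <- metadata[match(colnames(table), metadata$sample_id), ]
    y <- hellinger(table)
    env <- meta[, unlist(blocks_def), drop = FALSE]
    ord <- rda(y, env)
    eig <- data.frame(
      axis = c(paste0("RDA", seq_along(ord$constrained_eigenvalues)),
               paste0("PC", seq_along(ord$unconstrained_eigenvalues))),
      eigenvalue = c(ord$constrained_eigenvalues,
                     ord$unconstrained_eigenvalues),
      constrained = rep(c(TRUE, FALSE),
                        c(length(ord$constrained_eigenvalues),
                          length(ord$unconstrained_eigenvalues))))
    utils::write.table(eig, out("rda_eigenvalues.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ef <- envfit_axes(ord$site_scores, env,
                      n_perm = config$envfit_permutations,
                      seed = seed_for(5L))
    utils::write.table(ef, out("envfit.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vpa_rows <- list()
    for (nm in names(band_subsets)) {
      idx <- band_subsets[[nm]]
      if (length(idx) <= max(lengths(blocks_def)) + 1) next
      vp <- variance_partition(y[idx, , drop = FALSE],
                               lapply(blocks_def, function(v)
                                 meta[idx, v, drop = FALSE]))
      vpa_rows[[nm]] <- data.frame(scope = nm,
                                   fraction = names(vp$fractions),
                                   adj_r2 = unname(vp$fractions))
    }
    utils::write.table(do.call(rbind, vpa_rows), out("vpa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("ordination", c(out("rda_eigenvalues.tsv"), out("envfit.tsv"),
                           out("vpa.tsv")))
  } else {
    message("metadata lacks full covariate blocks: RDA/VPA skipped")
  }

  # -- stage: diversity / shared OTUs ---------------------------------------
  log_stage("stage diversity")
  div <- diversity_summary(table)
  utils::write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fs <- out("diversity.tsv")
  if (!is.null(band) && nlevels(droplevels(band)) >= 2) {
    kw <- rbind(
      cbind(measure = "richness", kruskal_wallis(div$richness, band)),
      cbind(measure = "shannon", kruskal_wallis(div$shannon, band)))
    utils::write.table(kw, out("kruskal_wallis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fs <- c(fs, out("kruskal_wallis.tsv"))
    if (nlevels(droplevels(band)) == 3) {
      vn <- venn_shared(table, band, niche_all)
      sf <- attr(vn, "shared_fraction")
      utils::write.table(vn, out("venn_regions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(category = names(sf),
                                    shared_fraction = unname(sf)),
                         out("venn_shared_fraction.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fs <- c(fs, out("venn_regions.tsv"), out("venn_shared_fraction.tsv"))
    }
  }
  record("stats", fs)

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    seed = config$rng_seed,
    config = list(n_permutations = config$n_permutations,
                  envfit_permutations = config$envfit_permutations,
                  ci_level = config$ci_level),
    package_version = as.character(utils::packageVersion("elevassembly")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages,
    output_hashes = as.list(tools::md5sum(files))
  )
  names(manifest$output_hashes) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("done (", length(files), " outputs)")
  invisible(manifest)
}
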