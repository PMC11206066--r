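#' Construct an OTU count table
#'
#' The single community object every analysis stage consumes: a non-negative
#' integer matrix of read counts with OTUs as rows and samples as columns.
#' This orientation is the canonical internal convention (as in the BIOM
#' format); readers accept either orientation and normalize on input.
#'
#' @param counts numeric matrix of non-negative integers, OTUs in rows.
#' @param otu_ids character vector of unique OTU identifiers; defaults to
#'   rownames of `counts`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to colnames of `counts`.
#' @return An object of class `otu_table`: an integer matrix with `otu_ids`
#'   as rownames and `sample_ids` as colnames.
#' @examples
#' tab <- otu_table(matrix(c(5, 1, 0, 0, 2, 7), nrow = 3),
#'                  otu_ids = paste0("OTU", 1:3),
#'                  sample_ids = c("S1", "S2"))
#' colSums(tab)
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  storage <- counts
  mode(storage) <- "double"
  if (any(!is.finite(storage))) {
    bad <- which(!is.finite(storage), arr.ind = TRUE)[1, ]
    stop("non-numeric or non-finite count at row ", bad[1], ", column ", bad[2])
  }
  if (any(storage < 0)) {
    bad <- which(storage < 0, arr.ind = TRUE)[1, ]
    stop("negative count at OTU '", otu_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  if (any(abs(storage - round(storage)) > 1e-8)) {
    bad <- which(abs(storage - round(storage)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at OTU '", otu_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  x <- round(storage)
  storage.mode(x) <- "integer"
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids: ",
    paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(otu_ids) != nrow(x) || length(sample_ids) != ncol(x))
    stop("id vectors do not match matrix dimensions")
  dimnames(x) <- list(otu_ids, sample_ids)
  class(x) <- c("otu_table", class(x))
  x
}

#' Validate an OTU table for analysis
#'
#' Checks the invariants all downstream stages rely on: unique ids, integer
#' non-negative counts, at least 2 OTUs and 2 samples, and positive total
#' count in every sample.
#'
#' @param x an `otu_table`.
#' @param require_min logical; enforce the >= 2 x 2 minimum analysis size.
#' @return `x` invisibly, or an error naming the offending row/column.
#' @export
validate_otu_table <- function(x, require_min = TRUE) {
  if (!inherits(x, "otu_table")) stop("not an otu_table")
  if (require_min && (nrow(x) < 2L || ncol(x) < 2L))
    stop("analysis requires at least 2 OTUs and 2 samples")
  cs <- colSums(x)
  if (any(cs == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  invisible(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x), "OTUs x", ncol(x), "samples; total reads",
      sum(x), "\n")
  invisible(x)
}

#' Read an OTU table from a tab-delimited file
#'
#' Expects a TSV with a header row and ids in the first column. Orientation
#' is declared by the caller and normalized to OTUs-as-rows internally.
#'
#' @param path file path.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return a validated [otu_table].
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (any(is.na(v) & !is.na(body[[j]])))
      stop("non-numeric count in column '", names(body)[j], "'")
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as TSV (OTUs as rows)
#'
#' @param x an `otu_table`.
#' @param path output file path.
#' @param id_column name for the leading id column.
#' @export
write_otu_table <- function(x, path, id_column = "otu_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Covariate block membership used by metadata validation, simulation and VPA.
covariate_blocks <- function() {
  list(
    topography = c("MEA", "CON", "SLO", "ASP"),
    light      = c("ALA", "CC", "TR", "SR", "DR", "LT", "LAI"),
    soil       = c("soil_pH", "organic_matter", "alkaline_N", "available_P",
                   "water_content")
  )
}

#' Read per-sample environmental metadata
#'
#' One row per sample. Recognized covariates fall into three blocks:
#' topography (MEA mean altitude in m, CON convexity, SLO slope and ASP
#' aspect in degrees), light (ALA average leaf angle, CC canopy coverage,
#' TR/SR/DR total/scattered/direct radiation, LT light transmittance, LAI
#' leaf area index) and soil (soil_pH, organic_matter, alkaline_N,
#' available_P, water_content). An optional `band` column carries elevation
#' band labels. Missing covariate columns are recorded in the
#' `"missing_fields"` attribute, never fabricated: stages that need a block
#' refuse to run rather than imputing.
#'
#' @param path TSV file path.
#' @param table optional companion [otu_table]; if given, every `sample_id`
#'   must match one of its columns.
#' @return a `sample_metadata` data.frame.
#' @export
read_metadata <- function(path, table = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df, table = table)
}

#' Construct and validate sample metadata
#'
#' @param df data.frame with a `sample_id` column and any subset of the
#'   recognized covariates.
#' @param table optional companion [otu_table] for id cross-checking.
#' @return `df` with class `sample_metadata` and attribute `missing_fields`.
#' @export
sample_metadata <- function(df, table = NULL) {
  if (!"sample_id" %in% names(df)) stop("metadata lacks a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  known <- unlist(covariate_blocks(), use.names = FALSE)
  missing_fields <- setdiff(known, names(df))
  for (f in c("CC", "LT", "water_content")) {
    if (f %in% names(df)) {
      v <- df[[f]]
      bad <- which(!is.na(v) & (v < 0 | v > 1))
      if (length(bad))
        stop(f, " outside [0,1] for sample(s): ",
             paste(df$sample_id[bad], collapse = ", "))
    }
  }
  if (!is.null(table)) {
    orphans <- setdiff(df$sample_id, colnames(table))
    if (length(orphans))
      stop("metadata samples absent from OTU table: ",
           paste(orphans, collapse = ", "))
  }
  attr(df, "missing_fields") <- missing_fields
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Write sample metadata as TSV
#' @param meta a `sample_metadata` data.frame.
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative abundance matrix
#'
#' `per_sample` divides each sample (column) by its total, so columns sum
#' to 1; `per_otu` divides each OTU (row) by its own total across samples,
#' the normalization the Levins niche breadth uses. All-zero OTU rows under
#' `per_otu` are returned as zeros and listed in the `"zero_rows"` attribute.
#'
#' @param table an [otu_table].
#' @param axis `"per_sample"` or `"per_otu"`.
#' @return numeric matrix with the same dimnames as `table`.
#' @export
relative_abundance <- function(table, axis = c("per_sample", "per_otu")) {
  axis <- match.arg(axis)
  x <- unclass(table)
  storage.mode(x) <- "double"
  if (axis == "per_sample") {
    cs <- colSums(x)
    if (any(cs == 0))
      stop("sample(s) with zero total: ",
           paste(colnames(x)[cs == 0], collapse = ", "))
    out <- sweep(x, 2, cs, "/")
  } else {
    rs <- rowSums(x)
    zero <- rs == 0
    rs[zero] <- 1
    out <- sweep(x, 1, rs, "/")
    attr(out, "zero_rows") <- rownames(x)[zero]
  }
  out
}

#' Run configuration shared by all stochastic stages
#'
#' @param rng_seed integer seed recorded in every output.
#' @param n_permutations permutations for niche-classification and C-score
#'   nulls (default 1000, the convention of the niche-breadth null).
#' @param envfit_permutations permutations for envfit tests (default 999).
#' @param ci_level confidence level for permutation bounds and prediction
#'   bands (default 0.95).
#' @param output_dir optional output directory for pipeline runs.
#' @return a `run_config` list.
#' @export
run_config <- function(rng_seed = 1L, n_permutations = 1000L,
                       envfit_permutations = 999L, ci_level = 0.95,
                       output_dir = NULL) {
  stopifnot(n_permutations >= 1, ci_level > 0, ci_level < 1)
  structure(list(rng_seed = as.integer(rng_seed),
                 n_permutations = as.integer(n_permutations),
                 envfit_permutations = as.integer(envfit_permutations),
                 ci_level = ci_level,
                 output_dir = output_dir),
            class = "run_config")
}
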