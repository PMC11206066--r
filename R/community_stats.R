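#' Per-sample diversity: richness and Shannon index
#'
#' Richness is the number of OTUs with count > 0; the Shannon-Wiener index
#' is H = -sum p log p in natural log units (nats), over the sample's
#' relative abundances. H is 0 for a single OTU and at most ln(richness),
#' attained by the uniform composition.
#'
#' @param table an [otu_table].
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
diversity_summary <- function(table) {
  validate_otu_table(table, require_min = FALSE)
  x <- unclass(table)
  ra <- relative_abundance(table, "per_sample")
  shannon <- apply(ra, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  data.frame(sample_id = colnames(x), richness = colSums(x > 0),
             shannon = shannon, row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison across groups
#'
#' Rank-based test of whether a diversity or niche-width measure differs
#' between groups (e.g. elevation bands), with tie correction and the
#' chi-squared approximation on k-1 degrees of freedom — adequate at the
#' band sizes of an elevation-gradient design. When all values are
#' identical, H = 0 and p = 1.
#'
#' @param values numeric vector.
#' @param groups grouping labels, same length; >= 2 non-empty groups.
#' @return data.frame with `statistic` (H), `df`, `p_value` and per-group
#'   medians as a `medians` attribute.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1) {
    out <- data.frame(statistic = 0, df = nlevels(groups) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    out <- data.frame(statistic = unname(kt$statistic),
                      df = unname(kt$parameter),
                      p_value = kt$p.value)
  }
  attr(out, "medians") <- tapply(values, groups, stats::median)
  out
}

#' Shared and unique OTU counts across three elevation bands
#'
#' An OTU is "present" in a band when it has count > 0 in at least one of
#' the band's samples. For each OTU category (all OTUs, plus generalist /
#' neutral / specialist when a classification is supplied) the 7 Venn
#' regions over the three bands are counted; the shared fraction is the
#' triple-overlap count divided by the category's total present OTUs.
#'
#' @param table an [otu_table].
#' @param bands factor/character of band labels per sample (3 bands,
#'   each non-empty), aligned with the table's columns.
#' @param categories optional `niche_classification` from [classify_otus()].
#' @return data.frame: one row per (category, region) with `count`, plus a
#'   per-category `shared_fraction` attribute.
#' @export
venn_shared <- function(table, bands, categories = NULL) {
  bands <- factor(bands)
  if (nlevels(bands) != 3) stop("exactly 3 bands required")
  if (any(table(bands) == 0)) stop("band with zero samples")
  x <- unclass(table) > 0
  lv <- levels(bands)
  present <- sapply(lv, function(b)
    rowSums(x[, bands == b, drop = FALSE]) > 0)
  cats <- list(all = rownames(table))
  if (!is.null(categories)) {
    for (cl in c("generalist", "neutral", "specialist"))
      cats[[cl]] <- categories$otu_id[categories$category == cl]
  }
  region_names <- c(lv, paste(lv[1], lv[2], sep = "&"),
                    paste(lv[1], lv[3], sep = "&"),
                    paste(lv[2], lv[3], sep = "&"),
                    paste(lv, collapse = "&"))
  rows <- list()
  shared <- numeric(0)
  for (cn in names(cats)) {
    sel <- rownames(table) %in% cats[[cn]]
    p1 <- present[sel, 1]; p2 <- present[sel, 2]; p3 <- present[sel, 3]
    counts <- c(sum(p1 & !p2 & !p3), sum(!p1 & p2 & !p3), sum(!p1 & !p2 & p3),
                sum(p1 & p2 & !p3), sum(p1 & !p2 & p3), sum(!p1 & p2 & p3),
                sum(p1 & p2 & p3))
    total <- sum(p1 | p2 | p3)
    shared[cn] <- if (total > 0) counts[7] / total else NA_real_
    rows[[cn]] <- data.frame(category = cn, region = region_names,
                             count = counts, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "shared_fraction") <- shared
  out
}
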