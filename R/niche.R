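#' Levins niche breadth per OTU
#'
#' For OTU j with relative abundance P_ij in habitat (sample) i, normalized
#' over the OTU's own total, the Levins breadth is B_j = 1 / sum_i P_ij^2 —
#' the inverse Simpson concentration of the OTU's distribution across
#' habitats. B equals the number of occupied habitats when the OTU is spread
#' evenly over them, so B ranges from 1 (single sample) to the number of
#' samples. A wider B means a broader realized niche.
#'
#' @param table an [otu_table]; each sample is treated as one habitat.
#' @return named numeric vector of B, one per OTU with nonzero total.
#'   All-zero OTUs are excluded with a warning (breadth undefined).
#' @examples
#' tab <- otu_table(matrix(c(2, 1, 1, 4, 0, 0), nrow = 2, byrow = TRUE))
#' levins_breadth(tab)  # first OTU: 1/(0.5^2+0.25^2+0.25^2) = 2.6667
#' @export
levins_breadth <- function(table) {
  x <- unclass(table)
  storage.mode(x) <- "double"
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero OTU(s) excluded: breadth undefined")
    x <- x[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  p <- x / rs
  b <- 1 / rowSums(p * p)
  names(b) <- rownames(x)
  b
}

# internal: breadth from a plain count matrix, zero rows -> NA (kept in place
# so permutation columns stay aligned)
.levins_raw <- function(x) {
  rs <- rowSums(x)
  rs[rs == 0] <- NA_real_
  p <- x / rs
  1 / rowSums(p * p, na.rm = FALSE)
}

#' Count-preserving quasiswap permutations of an OTU table
#'
#' Each permuted matrix preserves the original's row sums, column sums,
#' grand total and fill (number of nonzero cells). A draw is produced by an
#' r2dtable (Patefield) randomization that fixes the margins, followed by
#' random one-unit 2x2 diagonal shifts that restore the fill — the standard
#' count quasiswap construction — and finally a fill-preserving mixing
#' phase (2 x cells swap trials) that removes the bias of stopping at the
#' greedy repair endpoint: with a symmetric proposal and a hard fill
#' constraint the mixing chain is uniform over the reachable
#' margin-and-fill-preserving matrices. Matrices too small to swap (a
#' single row or column) are returned unchanged with a warning.
#'
#' @param table an [otu_table] (or integer matrix).
#' @param n number of permuted matrices.
#' @param seed integer RNG seed; same seed, same stream of matrices.
#' @param max_trials repair trial steps per burst; default
#'   `max(30000, 30 * cells)`. Repair continues in bursts on the same
#'   matrix until the fill is restored (up to 500 bursts, then an error:
#'   margins incompatible with the target fill).
#' @return list of `n` integer matrices.
#' @export
quasiswap_counts <- function(table, n, seed = NULL, max_trials = NULL) {
  x <- unclass(table)
  storage.mode(x) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    warning("matrix too small to swap; returning the original")
    return(replicate(n, x, simplify = FALSE))
  }
  if (is.null(max_trials)) max_trials <- max(30000L, 30L * length(x))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    perm <- .quasiswap_draw(x, as.integer(max_trials))
    dimnames(perm) <- dimnames(x)
    out[[k]] <- perm
  }
  out
}

# one count-quasiswap draw: Patefield start, fill repair (continued in
# bursts on the same matrix until the fill is restored), mixing phase
.quasiswap_draw <- function(x, max_trials) {
  rs <- rowSums(x); cs <- colSums(x)
  fill <- sum(x > 0L)
  start <- stats::r2dtable(1, rs, cs)[[1]]
  storage.mode(start) <- "integer"
  perm <- start
  for (burst in seq_len(500L)) {
    perm <- quasiswap_count_repair(perm, fill, max_trials)
    if (isTRUE(attr(perm, "fill_restored"))) break
  }
  if (!isTRUE(attr(perm, "fill_restored")))
    stop("quasiswap could not restore fill; margins may be incompatible ",
         "with the target fill")
  attr(perm, "fill_restored") <- NULL
  quasiswap_count_mix(perm, max(1000L, 2L * length(x)))
}

#' Classify OTUs into habitat generalists, neutral taxa and specialists
#'
#' The observed Levins breadth of each OTU is compared with its null
#' distribution over count-quasiswap permutations of the whole table.
#' Bounds are the empirical `(1-ci)/2` and `1-(1-ci)/2` quantiles of the
#' per-OTU null (default 2.5% and 97.5%). An OTU above the upper bound is a
#' generalist (broader niche than expected at its abundance), below the
#' lower bound a specialist, otherwise neutral. Ties with a bound are
#' classified neutral (conservative). No multiple-testing correction is
#' applied, matching the conventional use of this classification.
#'
#' @param table an [otu_table].
#' @param config a [run_config]; `n_permutations` (>= 100 recommended),
#'   `ci_level` and `rng_seed` are used.
#' @return data.frame of class `niche_classification`: `otu_id`, `B_obs`,
#'   `null_low`, `null_high`, `category`, `n_permutations`. All-zero OTUs
#'   are excluded.
#' @export
classify_otus <- function(table, config = run_config()) {
  validate_otu_table(table)
  x <- unclass(table)
  storage.mode(x) <- "integer"
  rs <- rowSums(x)
  keep <- rs > 0L
  set.seed(config$rng_seed)
  nperm <- config$n_permutations
  b_obs <- .levins_raw(x)
  null_b <- matrix(NA_real_, nrow(x), nperm)
  max_trials <- max(30000L, 30L * length(x))
  for (k in seq_len(nperm))
    null_b[, k] <- .levins_raw(.quasiswap_draw(x, max_trials))
  alpha <- (1 - config$ci_level) / 2
  lo <- apply(null_b, 1, stats::quantile, probs = alpha, na.rm = TRUE,
              names = FALSE)
  hi <- apply(null_b, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE,
              names = FALSE)
  category <- rep("neutral", nrow(x))
  category[b_obs > hi] <- "generalist"
  category[b_obs < lo] <- "specialist"
  out <- data.frame(otu_id = rownames(x), B_obs = b_obs, null_low = lo,
                    null_high = hi, category = category,
                    n_permutations = nperm,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ci_level") <- config$ci_level
  attr(out, "rng_seed") <- config$rng_seed
  class(out) <- c("niche_classification", class(out))
  out
}
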