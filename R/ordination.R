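#' Hellinger transformation
#'
#' Square root of per-sample relative abundances, returned with samples in
#' rows — the orientation ordination and tree methods expect. Euclidean
#' distances between Hellinger-transformed samples are ecologically
#' meaningful, which is why this is the default response for the regression
#' tree, RDA and variance partitioning.
#'
#' @param table an [otu_table].
#' @return numeric matrix, samples x OTUs.
#' @export
hellinger <- function(table) {
  t(sqrt(relative_abundance(table, "per_sample")))
}

#' Centered log-ratio transformation
#'
#' Treats each sample as compositional: log of each abundance divided by the
#' sample's geometric mean, so each sample's CLR values sum to zero. Zeros
#' are handled by adding `pseudocount` to zero cells only (multiplicative
#' replacement is deliberately not applied; zero cells are the only ones
#' perturbed).
#'
#' @param table an [otu_table].
#' @param pseudocount positive value added to zero counts (default 0.5).
#' @return numeric matrix, samples x OTUs, rows summing to 0.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  x <- unclass(table)
  storage.mode(x) <- "double"
  x[x == 0] <- pseudocount
  lx <- log(x)
  out <- sweep(lx, 2, colMeans(lx))   # per sample (column) centering
  t(out)
}

#' Redundancy analysis (RDA)
#'
#' PCA of the fitted values of the multivariate least-squares regression of
#' a (column-centered) community response on standardized environmental
#' predictors. Constrained eigenvalues come from the fitted matrix, the
#' unconstrained ones from the residual matrix; the constrained proportion
#' is trace(fitted' fitted)/trace(Y'Y), the multivariate redundancy
#' statistic. Collinear predictors are dropped with a warning and reported
#' in `aliased`.
#'
#' @param response numeric matrix, samples x species (e.g. [hellinger()] or
#'   [clr_transform()] output).
#' @param predictors numeric matrix or data.frame of environmental
#'   variables, samples in rows.
#' @return object of class `rda_result`: eigenvalues (constrained and
#'   unconstrained, each non-increasing), `proportion_constrained`, site
#'   scores and biplot scores for the first two constrained axes, `rank`,
#'   `aliased`.
#' @export
rda <- function(response, predictors) {
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  n <- nrow(y)
  if (nrow(x) != n) stop("response and predictors disagree on sample count")
  x <- scale(x)
  constant <- attr(x, "scaled:scale") == 0 | is.na(attr(x, "scaled:scale"))
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  qrx <- qr(x)
  aliased <- character(0)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    aliased <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    warning("dropping collinear predictor(s): ", paste(aliased, collapse = ", "))
    x <- x[, keep, drop = FALSE]
    qrx <- qr(x)
  }
  if (n <= qrx$rank) stop("more predictors than samples")
  fitted <- qr.fitted(qrx, y)
  resid <- y - fitted
  tot <- sum(y * y)
  sv_c <- svd(fitted)
  sv_u <- svd(resid)
  eig_c <- sv_c$d^2 / (n - 1)
  eig_u <- sv_u$d^2 / (n - 1)
  eig_c <- eig_c[eig_c > max(eig_c[1], 1) * 1e-12]
  eig_u <- eig_u[eig_u > max(eig_u[1], 1) * 1e-12]
  naxes <- min(2, length(eig_c))
  site <- sv_c$u[, seq_len(naxes), drop = FALSE] %*%
    diag(sv_c$d[seq_len(naxes)], naxes)
  colnames(site) <- paste0("RDA", seq_len(naxes))
  rownames(site) <- rownames(response)
  biplot <- stats::cor(x, site)
  structure(list(constrained_eigenvalues = eig_c,
                 unconstrained_eigenvalues = eig_u,
                 proportion_constrained = sum(fitted * fitted) / tot,
                 total_inertia = tot / (n - 1),
                 site_scores = site, biplot_scores = biplot,
                 rank = qrx$rank, aliased = aliased, n = n),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: %d constrained axes, %.1f%% of variance constrained (n = %d)\n",
    length(x$constrained_eigenvalues), 100 * x$proportion_constrained, x$n))
  invisible(x)
}

#' Permutation test of an environmental variable on ordination axes
#'
#' The squared multiple correlation r2 of the variable regressed on the
#' first two ordination axes, with a permutation p-value obtained by
#' shuffling the variable across samples:
#' p = (1 + #\{permuted r2 >= observed\}) / (n_perm + 1). A constant
#' variable has r2 = 0 and p = 1 by convention.
#'
#' @param scores matrix of site scores (axes in columns; the first two are
#'   used), e.g. `rda(...)$site_scores`.
#' @param variable numeric vector, one value per sample, or a data.frame of
#'   such variables (tested one at a time).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame with `variable`, `r2`, `p`.
#' @export
envfit_axes <- function(scores, variable, n_perm = 999, seed = 1L) {
  sc <- as.matrix(scores)[, seq_len(min(2, ncol(scores))), drop = FALSE]
  sc <- scale(sc, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(sc))
  vars <- if (is.data.frame(variable)) variable
          else stats::setNames(data.frame(variable), deparse(substitute(variable)))
  set.seed(seed)
  n <- nrow(q)
  res <- lapply(names(vars), function(nm) {
    v <- as.numeric(vars[[nm]])
    vc <- v - mean(v)
    ssv <- sum(vc^2)
    if (ssv == 0) return(data.frame(variable = nm, r2 = 0, p = 1))
    r2 <- sum(crossprod(q, vc)^2) / ssv
    perm <- replicate(n_perm, sample.int(n))
    vp <- matrix(vc[perm], n, n_perm)
    r2p <- colSums(crossprod(q, vp)^2) / colSums(vp^2)
    data.frame(variable = nm, r2 = r2,
               p = (1 + sum(r2p >= r2)) / (n_perm + 1))
  })
  do.call(rbind, res)
}

# multivariate (trace) R-squared of response on a predictor matrix,
# with Ezekiel's adjustment; rank-deficient predictors are reduced first
.trace_r2 <- function(y, x) {
  qrx <- qr(scale(x))
  if (qrx$rank < ncol(x))
    qrx <- qr(scale(x)[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE])
  fitted <- qr.fitted(qrx, y)
  r2 <- sum(fitted^2) / sum(y^2)
  n <- nrow(y); k <- qrx$rank
  adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  c(r2 = r2, adj = adj, k = k)
}

#' Three-block variance partitioning
#'
#' Partitions the adjusted multivariate R-squared of community composition
#' into unique and joint fractions of three predictor blocks (topography,
#' light, soil) by inclusion-exclusion over the 7 non-empty block unions.
#' R-squared is the redundancy (trace) statistic; the adjustment is
#' Ezekiel's `1 - (1-R2)(n-1)/(n-k-1)`. Individual fractions can be
#' slightly negative — an expected artifact of the adjustment — and are
#' reported as computed.
#'
#' @param response samples x species matrix (centered internally).
#' @param blocks named list of three predictor matrices/data.frames:
#'   `topography`, `light`, `soil` (any three names work; order defines
#'   the fraction labels).
#' @return object of class `vpa_result`: `fractions` (pure_1, pure_2,
#'   pure_3, joint_12, joint_13, joint_23, joint_123, residual),
#'   `adjusted_r2` for each union, block names.
#' @export
variance_partition <- function(response, blocks) {
  if (length(blocks) != 3) stop("exactly three blocks required")
  nm <- names(blocks)
  if (is.null(nm)) nm <- c("topography", "light", "soil")
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  n <- nrow(y)
  xs <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    if (ncol(b) == 0) stop("empty block")
    if (ncol(b) >= n) stop("block with >= as many columns as samples")
    if (nrow(b) != n) stop("block row count mismatch")
    b
  })
  adj_of <- function(ix) .trace_r2(y, do.call(cbind, xs[ix]))[["adj"]]
  A <- adj_of(1); B <- adj_of(2); C <- adj_of(3)
  AB <- adj_of(c(1, 2)); AC <- adj_of(c(1, 3)); BC <- adj_of(c(2, 3))
  ABC <- adj_of(1:3)
  a <- ABC - BC
  b <- ABC - AC
  cc <- ABC - AB
  d <- ABC - C - a - b
  e <- ABC - A - b - cc
  f <- ABC - B - a - cc
  g <- ABC - (a + b + cc + d + e + f)
  fr <- c(a, b, cc, d, f, e, g, 1 - ABC)
  names(fr) <- c(paste0("pure_", nm),
                 paste0("joint_", nm[1], "_", nm[2]),
                 paste0("joint_", nm[1], "_", nm[3]),
                 paste0("joint_", nm[2], "_", nm[3]),
                 paste0("joint_", nm[1], "_", nm[2], "_", nm[3]),
                 "residual")
  structure(list(fractions = fr,
                 adjusted_r2 = c(stats::setNames(c(A, B, C), nm),
                                 stats::setNames(c(AB, AC, BC),
                                          c(paste0(nm[1], "+", nm[2]),
                                            paste0(nm[1], "+", nm[3]),
                                            paste0(nm[2], "+", nm[3]))),
                                 full = ABC),
                 blocks = nm, n = n),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variance partitioning (adjusted R2 fractions):\n")
  print(round(x$fractions, 4))
  invisible(x)
}
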