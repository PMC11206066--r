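# Independent oracles: deliberately naive re-implementations used to check
# the package's optimized code paths. Keep these loop-based and obvious.

# O(n^2) pairwise C-score
brute_cscore <- function(a) {
  a <- (a > 0) * 1
  n <- nrow(a)
  r <- rowSums(a)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sum(a[i, ] & a[j, ])
    acc <- acc + (r[i] - s) * (r[j] - s)
  }
  acc / choose(n, 2)
}

# all binary matrices with the given margins (tiny instances only)
enum_binary_margins <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  out <- list()
  cells <- nr * nc
  for (code in 0:(2^cells - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(cells)]
    m <- matrix(bits, nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs))
      out[[length(out) + 1]] <- m
  }
  out
}

# all non-negative integer matrices with the given margins (tiny instances)
enum_count_margins <- function(rs, cs) {
  out <- list()
  rec <- function(mat, i) {
    if (i > length(rs)) {
      if (all(colSums(mat) == cs)) out[[length(out) + 1]] <<- mat
      return(invisible(NULL))
    }
    rem <- cs - if (i == 1) rep(0, length(cs)) else
      colSums(mat[seq_len(i - 1), , drop = FALSE])
    fill_row <- function(row, j, left) {
      if (j == length(cs)) {
        if (left <= rem[j]) rec(rbind(mat, c(row, left)), i + 1)
        return(invisible(NULL))
      }
      for (v in 0:min(left, rem[j])) fill_row(c(row, v), j + 1, left - v)
    }
    fill_row(integer(0), 1, rs[i])
  }
  rec(matrix(0L, 0, length(cs)), 1)
  out
}

# margin-preserving greedy swaps pushing the C-score down (sign = -1,
# aggregation) or up (sign = +1, segregation): lands the matrix in the
# stated tail of its own fixed-margin ensemble by construction
greedy_cscore_matrix <- function(a, sign, iters = 3000) {
  cur <- c_score(a)
  for (i in seq_len(iters)) {
    rr <- sample(nrow(a), 2); cc <- sample(ncol(a), 2)
    sub <- a[rr, cc]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
        sub[1, 1] != sub[1, 2]) {
      b <- a
      b[rr, cc] <- 1 - sub
      cb <- c_score(b)
      if (sign * (cb - cur) > 0) { a <- b; cur <- cb }
    }
  }
  a
}

# brute-force best split on one predictor: try every midpoint, recompute
# child SS from scratch
brute_split_scan <- function(y, x, min_node) {
  xs <- sort(unique(x))
  best <- NULL
  ssq <- function(m) if (nrow(m) == 0) 0 else
    sum(sweep(m, 2, colMeans(m))^2)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- y[x <= thr, , drop = FALSE]
    r <- y[x > thr, , drop = FALSE]
    if (nrow(l) < min_node || nrow(r) < min_node) next
    w <- ssq(l) + ssq(r)
    if (is.null(best) || w < best$within - 1e-12) best <- list(threshold = thr, within = w)
  }
  best
}

# Kruskal-Wallis H computed longhand from mid-ranks with tie correction
hand_kruskal <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small random count table
random_table <- function(nr, nc, lambda = 2, sparsity = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- matrix(rpois(nr * nc, lambda), nr, nc)
    x[runif(nr * nc) < sparsity] <- 0L
    if (all(colSums(x) > 0) && all(rowSums(x) > 0)) break
  }
  otu_table(x)
}
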