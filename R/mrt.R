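# Multivariate regression tree on a single numeric predictor.
#
# The response is a multivariate community matrix (samples x species,
# typically Hellinger-transformed); each binary split on the predictor
# minimizes the total within-child sum of squared deviations from the child
# centroids, i.e. CART with a multivariate sum-of-squares impurity. Trees
# are grown greedily, then pruned by k-fold cross-validation with the
# 1-SE rule.

# sum of squares of rows about their centroid
.node_ss <- function(y) {
  n <- nrow(y)
  if (n == 0) return(0)
  sum(y * y) - sum(colSums(y)^2) / n
}

# best split of rows `idx` on x: brute-force scan over midpoints between
# consecutive distinct sorted predictor values, via cumulative sums.
# Ties in impurity reduction break toward the lower threshold.
.best_split <- function(y, x, min_node) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord, , drop = FALSE]
  cs <- apply(ys, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  sq <- cumsum(rowSums(ys * ys))
  tot_ss <- sq[n] - sum(cs[n, ]^2) / n
  ks <- which(xs[-n] < xs[-1])              # boundaries between distinct values
  ks <- ks[ks >= min_node & (n - ks) >= min_node]
  if (!length(ks)) return(NULL)
  left_ss <- sq[ks] - rowSums(cs[ks, , drop = FALSE]^2) / ks
  rsums <- sweep(cs[ks, , drop = FALSE], 2, cs[n, ], function(a, b) b - a)
  right_ss <- (sq[n] - sq[ks]) - rowSums(rsums^2) / (n - ks)
  within <- left_ss + right_ss
  k <- ks[which.min(within)]                # first minimum = lowest threshold
  list(threshold = (xs[k] + xs[k + 1]) / 2,
       improvement = tot_ss - min(within))
}

.grow_node <- function(y, x, idx, depth, min_node, max_depth) {
  yy <- y[idx, , drop = FALSE]
  node <- list(idx = idx, n = length(idx), ss = .node_ss(yy),
               centroid = colMeans(yy), mean_x = mean(x[idx]),
               threshold = NA_real_, left = NULL, right = NULL)
  if (depth >= max_depth || length(idx) < 2 * min_node || node$ss <= 1e-12)
    return(node)
  sp <- .best_split(yy, x[idx], min_node)
  if (is.null(sp) || sp$improvement <= 1e-12) return(node)
  node$threshold <- sp$threshold
  li <- idx[x[idx] <= sp$threshold]
  ri <- idx[x[idx] > sp$threshold]
  node$left <- .grow_node(y, x, li, depth + 1, min_node, max_depth)
  node$right <- .grow_node(y, x, ri, depth + 1, min_node, max_depth)
  node
}

.is_leaf <- function(node) is.null(node$left)

.leaves <- function(node) {
  if (.is_leaf(node)) return(list(node))
  c(.leaves(node$left), .leaves(node$right))
}

.tree_size <- function(node) length(.leaves(node))

.splits <- function(node) {
  if (.is_leaf(node)) return(NULL)
  rbind(data.frame(threshold = node$threshold, n_left = node$left$n,
                   n_right = node$right$n),
        .splits(node$left), .splits(node$right))
}

# weakest-link statistic per internal node: cost-complexity
# g = (node ss - sum of leaf ss below) / (leaves below - 1)
.weakest_g <- function(node) {
  if (.is_leaf(node)) return(NULL)
  lv <- .leaves(node)
  g <- (node$ss - sum(vapply(lv, `[[`, numeric(1), "ss"))) / (length(lv) - 1)
  c(g, .weakest_g(node$left), .weakest_g(node$right))
}

# collapse the internal node with the smallest g (first on ties, preorder)
.collapse_weakest <- function(node) {
  gs <- .weakest_g(node)
  target <- min(gs)
  collapse <- function(nd) {
    if (.is_leaf(nd)) return(list(node = nd, done = FALSE))
    lv <- .leaves(nd)
    g <- (nd$ss - sum(vapply(lv, `[[`, numeric(1), "ss"))) / (length(lv) - 1)
    if (g <= target + 1e-12) {
      nd$left <- NULL; nd$right <- NULL; nd$threshold <- NA_real_
      return(list(node = nd, done = TRUE))
    }
    l <- collapse(nd$left)
    nd$left <- l$node
    if (l$done) return(list(node = nd, done = TRUE))
    r <- collapse(nd$right)
    nd$right <- r$node
    list(node = nd, done = r$done)
  }
  collapse(node)$node
}

.prune_to_size <- function(node, size) {
  while (.tree_size(node) > size) node <- .collapse_weakest(node)
  node
}

.predict_centroid <- function(node, xnew) {
  one <- function(nd, v) {
    while (!.is_leaf(nd)) nd <- if (v <= nd$threshold) nd$left else nd$right
    nd$centroid
  }
  t(vapply(xnew, function(v) one(node, v), numeric(length(node$centroid))))
}

#' Grow a multivariate regression tree on an elevation predictor
#'
#' @param community numeric matrix, samples in rows (use [hellinger()] on an
#'   [otu_table] for the standard transformation).
#' @param predictor numeric vector, one value per sample (mean altitude MEA
#'   in the elevation-gradient design). Names, or `rownames(community)`,
#'   carry the sample ids.
#' @param min_node minimum samples per leaf (default 5).
#' @param max_depth maximum tree depth (default 4).
#' @param predictor_name label used in reports.
#' @return object of class `mrt`: the grown (unpruned) tree plus bookkeeping.
#'   A constant predictor yields a single-leaf tree with a warning.
#' @export
grow_mrt <- function(community, predictor, min_node = 5, max_depth = 4,
                     predictor_name = "MEA") {
  community <- as.matrix(community)
  stopifnot(nrow(community) == length(predictor))
  ids <- names(predictor)
  if (is.null(ids)) ids <- rownames(community)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(community)))
  if (length(unique(predictor)) == 1) {
    warning("constant predictor: single-leaf tree")
  }
  root <- .grow_node(community, predictor, seq_along(predictor), 0,
                     min_node, max_depth)
  structure(list(root = root, predictor = predictor,
                 predictor_name = predictor_name, sample_ids = ids,
                 min_node = min_node, max_depth = max_depth,
                 cv_table = NULL, chosen_size = .tree_size(root)),
            class = "mrt")
}

#' Prune a multivariate regression tree by cross-validation
#'
#' Computes k-fold cross-validated relative error (held-out sum of squares
#' about the training leaf centroids, divided by the total sum of squares)
#' for every subtree size on the weakest-link pruning path, then keeps the
#' smallest size whose error is within one standard error of the minimum
#' (1-SE rule). Fold assignment is seed-controlled.
#'
#' @param model an `mrt` from [grow_mrt()].
#' @param community,predictor the data the model was grown on.
#' @param k_folds number of folds (default 10; must be >= 2).
#' @param seed RNG seed for fold assignment.
#' @return the pruned `mrt`, with `cv_table` (size, rel_error, se) and
#'   `chosen_size` filled in.
#' @export
prune_mrt <- function(model, community, predictor, k_folds = 10, seed = 1L) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  community <- as.matrix(community)
  n <- nrow(community)
  max_size <- .tree_size(model$root)
  sizes <- seq_len(max_size)
  if (max_size == 1) {
    model$cv_table <- data.frame(size = 1L, rel_error = 1, se = 0)
    model$chosen_size <- 1L
    return(model)
  }
  sst <- .node_ss(community)
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  err <- matrix(0, k_folds, length(sizes))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    tree_f <- .grow_node(community[tr, , drop = FALSE], predictor[tr],
                         seq_along(tr), 0, model$min_node, model$max_depth)
    for (s in seq_along(sizes)) {
      sub <- .prune_to_size(tree_f, sizes[s])
      pred <- .predict_centroid(sub, predictor[te])
      # normalize each fold by its share of the total SS
      err[f, s] <- sum((community[te, , drop = FALSE] - pred)^2) /
        (sst * length(te) / n)
    }
  }
  rel <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(k_folds)
  i_min <- which.min(rel)
  chosen <- sizes[which(rel <= rel[i_min] + se[i_min])[1]]
  model$cv_table <- data.frame(size = sizes, rel_error = rel, se = se)
  model$chosen_size <- chosen
  model$root <- .prune_to_size(model$root, chosen)
  model
}

#' Assign elevation band labels from a fitted tree
#'
#' Leaves are ordered by their mean predictor (elevation); with exactly 3
#' leaves they are labeled LEG/MEG/HEG (low/medium/high elevation gradient),
#' otherwise L1..Lk in ascending elevation with a note that the 3-band
#' convention does not apply.
#'
#' @param model a (pruned) `mrt`.
#' @return factor of band labels named by sample id, ordered by elevation.
#' @export
assign_bands <- function(model) {
  lv <- .leaves(model$root)
  ord <- order(vapply(lv, `[[`, numeric(1), "mean_x"))
  lv <- lv[ord]
  k <- length(lv)
  labels <- if (k == 3) c("LEG", "MEG", "HEG") else paste0("L", seq_len(k))
  if (k != 3)
    message("tree has ", k, " leaves; 3-band LEG/MEG/HEG convention not applied")
  band <- character(length(model$sample_ids))
  for (i in seq_len(k)) band[lv[[i]]$idx] <- labels[i]
  factor(stats::setNames(band, model$sample_ids), levels = labels)
}

#' Summary of the splits of a fitted tree
#' @param object an `mrt`.
#' @param ... unused.
#' @return data.frame of split thresholds and child sizes (NULL if no split).
#' @export
summary.mrt <- function(object, ...) {
  sp <- .splits(object$root)
  if (is.null(sp)) return(invisible(NULL))
  sp$variable <- object$predictor_name
  sp[, c("variable", "threshold", "n_left", "n_right")]
}

#' @export
print.mrt <- function(x, ...) {
  cat("Multivariate regression tree on", x$predictor_name, "—",
      .tree_size(x$root), "leaves\n")
  sp <- .splits(x$root)
  if (!is.null(sp))
    for (i in seq_len(nrow(sp)))
      cat(sprintf("  split at %s <= %.3f (%d | %d)\n", x$predictor_name,
                  sp$threshold[i], sp$n_left[i], sp$n_right[i]))
  invisible(x)
}

#' One-call elevation banding of a community table
#'
#' Hellinger-transforms the table, grows and cross-validation-prunes the
#' tree on the metadata's MEA column, and returns the model with bands.
#'
#' @param table an [otu_table].
#' @param metadata `sample_metadata` with an `MEA` column aligned to the
#'   table's samples.
#' @param k_folds,seed,min_node,max_depth passed through.
#' @return list with `model` (pruned `mrt`) and `band` (factor per sample).
#' @export
fit_mrt <- function(table, metadata, k_folds = 10, seed = 1L,
                    min_node = 5, max_depth = 4) {
  if (!"MEA" %in% names(metadata)) stop("metadata lacks MEA")
  meta <- metadata[match(colnames(table), metadata$sample_id), ]
  y <- hellinger(table)
  x <- stats::setNames(meta$MEA, meta$sample_id)
  model <- grow_mrt(y, x, min_node = min_node, max_depth = max_depth)
  model <- prune_mrt(model, y, x, k_folds = k_folds, seed = seed)
  list(model = model, band = assign_bands(model))
}
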