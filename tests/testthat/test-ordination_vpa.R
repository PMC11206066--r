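test_that("CLR transform: uniform, zero-sum, hand check", {
  tab <- otu_table(matrix(1L, 4, 3))
  expect_equal(unname(clr_transform(tab)), matrix(0, 3, 4))

  set.seed(31)
  tab2 <- random_table(10, 6)
  clr <- clr_transform(tab2)
  expect_equal(unname(rowSums(clr)), rep(0, 6), tolerance = 1e-12)

  x <- otu_table(matrix(c(1L, 10L, 100L), 3, 1,
                        dimnames = list(NULL, "S1")))
  v <- log(c(1, 10, 100)) - mean(log(c(1, 10, 100)))
  expect_equal(unname(clr_transform(x)[1, ]), v)
  expect_error(clr_transform(tab2, pseudocount = 0), "pseudocount")
})

test_that("RDA: null, perfect and oracle cases", {
  set.seed(32)
  n <- 30
  y <- matrix(rnorm(n * 8), n)
  # perfect: response IS a linear map of the predictors
  x <- matrix(rnorm(n * 3), n)
  y_perfect <- x %*% matrix(rnorm(3 * 8), 3)
  expect_equal(rda(y_perfect, x)$proportion_constrained, 1,
               tolerance = 1e-10)

  # independent predictors explain ~ k/(n-1) by chance only
  ord <- rda(y, x)
  expect_lt(ord$proportion_constrained, 0.3)

  # oracle: trace R^2 from explicit least squares
  yc <- scale(y, scale = FALSE)
  xs <- scale(x)
  beta <- solve(crossprod(xs), crossprod(xs, yc))
  expect_equal(ord$proportion_constrained,
               sum((xs %*% beta)^2) / sum(yc^2), tolerance = 1e-10)

  # eigenvalue bookkeeping: constrained + unconstrained = total variance
  expect_equal(sum(ord$constrained_eigenvalues) +
                 sum(ord$unconstrained_eigenvalues),
               sum(yc^2) / (n - 1), tolerance = 1e-8)
  expect_true(all(diff(ord$constrained_eigenvalues) <= 1e-12))

  # collinear predictors are dropped and reported
  x_bad <- cbind(a = x[, 1], b = x[, 2], c = x[, 1] + x[, 2])
  expect_warning(ord2 <- rda(y, x_bad), "collinear")
  expect_length(ord2$aliased, 1)
})

test_that("RDA agrees with the vegan reference on a fixture", {
  set.seed(33)
  tab <- random_table(25, 18)
  y <- hellinger(tab)
  x <- data.frame(a = rnorm(18), b = rnorm(18), c = rnorm(18))
  ours <- rda(y, x)
  ref <- vegan::rda(y ~ a + b + c, data = x)
  expect_equal(ours$proportion_constrained,
               ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-8)
  expect_equal(ours$constrained_eigenvalues,
               unname(ref$CCA$eig), tolerance = 1e-8)
})

test_that("envfit: perfect alignment, constant variable, determinism", {
  set.seed(34)
  scores <- matrix(rnorm(60), 30, 2)
  ef <- envfit_axes(scores, scores[, 1], n_perm = 199, seed = 1)
  expect_equal(ef$r2, 1, tolerance = 1e-12)
  expect_equal(ef$p, 1 / 200)

  ef0 <- envfit_axes(scores, rep(2, 30), n_perm = 99, seed = 1)
  expect_equal(ef0$r2, 0)
  expect_equal(ef0$p, 1)

  v <- rnorm(30)
  expect_identical(envfit_axes(scores, v, n_perm = 99, seed = 7),
                   envfit_axes(scores, v, n_perm = 99, seed = 7))
})

test_that("VPA: inclusion-exclusion identity and block structure", {
  set.seed(35)
  n <- 200
  y <- matrix(rnorm(n * 10), n)
  blocks <- list(topography = matrix(rnorm(n * 2), n),
                 light = matrix(rnorm(n * 3), n),
                 soil = matrix(rnorm(n * 2), n))
  y <- y + blocks$topography %*% matrix(rnorm(20), 2) +
    blocks$light %*% matrix(rnorm(30), 3)
  vp <- variance_partition(y, blocks)
  fr <- vp$fractions
  adj <- vp$adjusted_r2
  # reconstruct every union's adjusted R2 from the 7 fractions
  expect_equal(unname(fr["pure_topography"] +
                        fr["joint_topography_light"] +
                        fr["joint_topography_soil"] +
                        fr["joint_topography_light_soil"]),
               unname(adj["topography"]), tolerance = 1e-8)
  expect_equal(unname(sum(fr) - fr["residual"]),
               unname(adj["full"]), tolerance = 1e-8)
  expect_equal(unname(fr["pure_topography"] + fr["pure_light"] +
                        fr["joint_topography_light"] +
                        fr["joint_topography_soil"] +
                        fr["joint_light_soil"] +
                        fr["joint_topography_light_soil"]),
               unname(adj["topography+light"]), tolerance = 1e-8)
  # orthogonal blocks: joint fractions vanish, pure fractions carry signal
  expect_lt(abs(fr["joint_topography_light"]), 0.03)
  expect_gt(fr["pure_topography"], 0.05)
  expect_gt(fr["pure_light"], 0.05)
  expect_lt(abs(fr["pure_soil"]), 0.03)
})

test_that("duplicated blocks move all signal into the joint fraction", {
  set.seed(36)
  n <- 50
  x <- matrix(rnorm(n * 3), n)
  y <- x %*% matrix(rnorm(3 * 8), 3) + matrix(rnorm(n * 8), n)
  vp <- variance_partition(y, list(topography = x, light = x, soil = x))
  fr <- vp$fractions
  expect_lt(max(abs(fr[c("pure_topography", "pure_light", "pure_soil")])),
            0.02)
  expect_gt(fr["joint_topography_light_soil"], 0.3)

  expect_error(variance_partition(y, list(a = x, b = x,
                                          c = matrix(rnorm(n * 60), n))),
               ">= as many columns")
})
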