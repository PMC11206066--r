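test_that("diversity: exact Shannon values and bounds", {
  tab <- otu_table(cbind(uniform = rep(3L, 10), single = c(7L, rep(0L, 9))))
  div <- diversity_summary(tab)
  expect_equal(div$shannon[div$sample_id == "uniform"], log(10))
  expect_equal(div$shannon[div$sample_id == "single"], 0)
  expect_equal(div$richness, c(10, 1))

  # uniform maximizes Shannon at fixed richness; H <= ln(richness)
  set.seed(41)
  tab2 <- random_table(12, 8, lambda = 3)
  div2 <- diversity_summary(tab2)
  expect_true(all(div2$shannon <= log(div2$richness) + 1e-12))

  mixed <- otu_table(matrix(c(2L, 1L, 1L), 3, 1,
                            dimnames = list(NULL, "s")))
  expect_equal(diversity_summary(mixed)$shannon,
               -sum(c(.5, .25, .25) * log(c(.5, .25, .25))))
})

test_that("Shannon agrees with the vegan reference", {
  set.seed(42)
  tab <- random_table(30, 10)
  div <- diversity_summary(tab)
  expect_equal(div$shannon,
               unname(vegan::diversity(t(unclass(tab)), "shannon")),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis: degenerate case, oracle, invariance", {
  expect_equal(kruskal_wallis(rep(1, 9), rep(letters[1:3], 3))$statistic, 0)
  expect_equal(kruskal_wallis(rep(1, 9), rep(letters[1:3], 3))$p_value, 1)

  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$statistic, hand_kruskal(v, g), tolerance = 1e-12)
  expect_equal(kw$p_value,
               stats::pchisq(kw$statistic, 2, lower.tail = FALSE))

  set.seed(43)
  v2 <- rnorm(30); g2 <- sample(rep(1:3, 10))
  expect_equal(kruskal_wallis(exp(v2), g2)$statistic,
               kruskal_wallis(v2, g2)$statistic, tolerance = 1e-12)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Venn regions: exact cases and set-algebra oracle", {
  bands <- factor(rep(c("LEG", "MEG", "HEG"), each = 2),
                  levels = c("LEG", "MEG", "HEG"))
  x <- rbind(everywhere = rep(1L, 6),
             leg_only = c(1L, 1L, 0L, 0L, 0L, 0L),
             leg_meg = c(1L, 0L, 1L, 0L, 0L, 0L))
  vn <- venn_shared(otu_table(x), bands)
  expect_equal(vn$count[vn$region == "LEG&MEG&HEG"], 1)
  expect_equal(vn$count[vn$region == "LEG"], 1)
  expect_equal(vn$count[vn$region == "LEG&MEG"], 1)
  expect_equal(attr(vn, "shared_fraction")[["all"]], 1 / 3)

  # disjoint band-specific sets share nothing
  y <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L, 0L, 0L),
             c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(attr(venn_shared(otu_table(y), bands),
                    "shared_fraction")[["all"]], 0)

  set.seed(44)
  tab <- random_table(40, 12)
  b <- factor(sample(rep(c("LEG", "MEG", "HEG"), each = 4)),
              levels = c("LEG", "MEG", "HEG"))
  vn <- venn_shared(tab, b)
  pres <- sapply(levels(b), function(k)
    rowSums(unclass(tab)[, b == k, drop = FALSE]) > 0)
  oracle <- c(sum(pres[, 1] & !pres[, 2] & !pres[, 3]),
              sum(!pres[, 1] & pres[, 2] & !pres[, 3]),
              sum(!pres[, 1] & !pres[, 2] & pres[, 3]),
              sum(pres[, 1] & pres[, 2] & !pres[, 3]),
              sum(pres[, 1] & !pres[, 2] & pres[, 3]),
              sum(!pres[, 1] & pres[, 2] & pres[, 3]),
              sum(pres[, 1] & pres[, 2] & pres[, 3]))
  expect_equal(vn$count[vn$category == "all"], oracle)
  # regions partition the OTUs present in at least one band
  expect_equal(sum(vn$count[vn$category == "all"]),
               sum(pres[, 1] | pres[, 2] | pres[, 3]))

  expect_error(venn_shared(tab, factor(rep("LEG", 12))), "3 bands")
})
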