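test_that("OTU table TSV parsing, orientation and round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS2", "OTU1\t5\t0", "OTU2\t1\t2", "OTU3\t0\t7"),
             path)
  tab <- read_otu_table(path)
  expect_equal(unname(colSums(tab)), c(6, 9))
  expect_equal(rownames(tab), c("OTU1", "OTU2", "OTU3"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, out)
  back <- read_otu_table(out)
  expect_identical(unclass(back), unclass(tab))

  flipped <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tOTU1\tOTU2\tOTU3", "S1\t5\t1\t0", "S2\t0\t2\t7"),
             flipped)
  expect_identical(unclass(read_otu_table(flipped, "samples_as_rows")),
                   unclass(tab))
})

test_that("invalid tables are rejected with the offender named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS2", "OTU1\t5\t0", "OTU2\t-3\t2"), path)
  expect_error(read_otu_table(path), "OTU2.*S1")

  expect_error(otu_table(matrix(1:4, 2), c("A", "A"), c("S1", "S2")),
               "duplicate OTU")
  expect_error(otu_table(matrix(c(1, 2, 0.5, 1), 2)), "non-integer")
  zero_col <- otu_table(matrix(c(1, 2, 0, 0), 2,
                               dimnames = list(NULL, c("S1", "S2"))))
  expect_error(validate_otu_table(zero_col), "S2")
  expect_error(validate_otu_table(otu_table(matrix(1:2, 1, 2))),
               "at least 2")
})

test_that("validation rejects randomly corrupted matrices", {
  set.seed(42)
  for (rep in 1:20) {
    tab <- random_table(6, 5)
    x <- matrix(as.numeric(unclass(tab)), nrow(tab))
    kind <- sample(c("negative", "fraction", "nonfinite", "zero_sample"), 1)
    ij <- c(sample(nrow(x), 1), sample(ncol(x), 1))
    if (kind == "negative") x[ij[1], ij[2]] <- -sample(5, 1)
    if (kind == "fraction") x[ij[1], ij[2]] <- x[ij[1], ij[2]] + 0.25
    if (kind == "nonfinite") x[ij[1], ij[2]] <- NA
    if (kind == "zero_sample") x[, ij[2]] <- 0
    expect_error(validate_otu_table(otu_table(x)), class = "simpleError")
  }
})

test_that("metadata reading, validation and missing blocks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  spec <- synth_spec(n_samples = 12, n_otus = 40, rng_seed = 3)
  d <- simulate_dataset(spec)
  write_metadata(d$metadata, path)
  meta <- read_metadata(path, table = d$table)
  expect_s3_class(meta, "sample_metadata")
  expect_equal(nrow(meta), 12)
  expect_length(attr(meta, "missing_fields"), 0)

  bad <- d$metadata
  bad$CC[3] <- 1.2
  expect_error(sample_metadata(as.data.frame(bad)), "CC outside")

  nosoil <- as.data.frame(d$metadata)
  nosoil <- nosoil[, setdiff(names(nosoil), covariate_blocks_soil <-
    c("soil_pH", "organic_matter", "alkaline_N", "available_P",
      "water_content"))]
  m2 <- sample_metadata(nosoil)
  expect_setequal(attr(m2, "missing_fields"), covariate_blocks_soil)

  orphan <- as.data.frame(d$metadata)
  orphan$sample_id[1] <- "NOT_A_SAMPLE"
  expect_error(sample_metadata(orphan, table = d$table), "NOT_A_SAMPLE")
})

test_that("relative abundance: both axes, scale invariance, zero rows", {
  tab <- otu_table(matrix(c(2, 2, 2, 6), 2))
  per_sample <- relative_abundance(tab, "per_sample")
  expect_equal(unname(per_sample), cbind(c(0.5, 0.5), c(0.25, 0.75)))

  tab2 <- otu_table(rbind(c(2, 1, 1), c(0, 0, 0), c(3, 3, 3)))
  per_otu <- relative_abundance(tab2, "per_otu")
  expect_equal(unname(per_otu[1, ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(per_otu[2, ]), c(0, 0, 0))
  expect_equal(attr(per_otu, "zero_rows"), rownames(tab2)[2])

  set.seed(7)
  tab3 <- random_table(8, 6)
  scaled <- unclass(tab3)
  scaled[, 3] <- scaled[, 3] * 5L
  expect_equal(relative_abundance(otu_table(scaled), "per_sample"),
               relative_abundance(tab3, "per_sample"), ignore_attr = TRUE)
})
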