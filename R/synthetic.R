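#' Specification for the synthetic elevation-gradient dataset
#'
#' Describes the generative world the analysis assumes: a neutral-assembly
#' backbone with a known migration rate, planted habitat specialists and
#' generalists, and elevation-structured environmental covariates. Defaults
#' mirror the study design the package targets: 120 quadrat samples in three
#' elevation bands of 49/27/44, and an OTU pool whose composition follows
#' the observed category proportions (~6% generalists, ~41.5% specialists,
#' the rest neutral). The OTU pool defaults to 2,000 taxa — scaled down from
#' the study's ~12,850 so permutation suites stay desk-sized; pass a larger
#' `n_otus` for full-scale runs.
#'
#' @param n_samples number of samples (default 120).
#' @param band_sizes samples per elevation band, low to high; must sum to
#'   `n_samples`. Default: 49/27/44 at 120 samples, rescaled proportionally
#'   otherwise.
#' @param n_otus metacommunity richness (default 2000).
#' @param reads_per_sample sequencing depth N per sample (default 2000).
#' @param m_true migration rate of the neutral backbone, in (0, 1]
#'   (default 0.5, the magnitude reported for forest soil communities).
#' @param frac_generalist,frac_specialist fractions of OTUs planted as
#'   habitat generalists / specialists (defaults 0.06 / 0.415); must sum
#'   to <= 1.
#' @param metacommunity_shape `"lognormal"` (default) or `"logseries"`.
#' @param sdlog lognormal shape parameter of the metacommunity abundance
#'   distribution (default 1: moderately uneven, so most taxa carry signal).
#' @param band_ranges 3x2 matrix of per-band elevation ranges in m
#'   (non-overlapping, ascending); default 1300-1480 / 1520-1680 /
#'   1720-1900.
#' @param covariate_effects named numeric: per-block strength of the linear
#'   elevation dependence of covariates, in units of the covariate noise SD
#'   (default 1 for topography, light and soil).
#' @param covariate_noise_sd SD of the covariate noise term (default 1).
#' @param rng_seed integer seed.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_samples = 120L, band_sizes = NULL,
                       n_otus = 2000L, reads_per_sample = 2000L,
                       m_true = 0.5, frac_generalist = 0.06,
                       frac_specialist = 0.415,
                       metacommunity_shape = c("lognormal", "logseries"),
                       sdlog = 1,
                       band_ranges = rbind(c(1300, 1480), c(1520, 1680),
                                           c(1720, 1900)),
                       covariate_effects = c(topography = 1, light = 1,
                                             soil = 1),
                       covariate_noise_sd = 1, rng_seed = 1L) {
  metacommunity_shape <- match.arg(metacommunity_shape)
  if (is.null(band_sizes)) {
    # study proportions 49/27/44, rescaled to n_samples
    band_sizes <- floor(c(49, 27, 44) / 120 * n_samples)
    band_sizes[1] <- band_sizes[1] + (n_samples - sum(band_sizes))
  }
  if (sum(band_sizes) != n_samples)
    stop("band_sizes must sum to n_samples")
  if (m_true <= 0 || m_true > 1) stop("m_true must be in (0, 1]")
  if (frac_generalist < 0 || frac_specialist < 0 ||
      frac_generalist + frac_specialist > 1)
    stop("category fractions must be in [0,1] and sum to <= 1")
  structure(list(n_samples = as.integer(n_samples),
                 band_sizes = as.integer(band_sizes),
                 n_otus = as.integer(n_otus),
                 reads_per_sample = as.integer(reads_per_sample),
                 m_true = m_true, frac_generalist = frac_generalist,
                 frac_specialist = frac_specialist,
                 metacommunity_shape = metacommunity_shape, sdlog = sdlog,
                 band_ranges = band_ranges,
                 covariate_effects = covariate_effects,
                 covariate_noise_sd = covariate_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_spec")
}

.band_labels <- function(k) {
  if (k == 3) c("LEG", "MEG", "HEG") else paste0("L", seq_len(k))
}

# deterministic largest-remainder rounding of a weight vector to integer
# counts summing to n (ties broken toward lower index)
.round_to_total <- function(w, n) {
  if (sum(w) <= 0) stop("cannot renormalize an all-zero sample")
  raw <- w / sum(w) * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    rem <- raw - base
    add <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Simulate a purely neutral community
#'
#' The generative twin of the Sloan neutral model. Metacommunity relative
#' abundances p are drawn from the chosen species-abundance distribution;
#' each sample's composition is Dirichlet with concentration N * m * p, so
#' each taxon's local relative abundance is marginally
#' Beta(N m p_i, N m (1 - p_i)) — exactly the law the neutral fit assumes —
#' and reads are then drawn multinomially with total N.
#'
#' @param spec a [synth_spec()] (category fractions are ignored here: the
#'   backbone is fully neutral).
#' @param seed optional seed; defaults to `spec$rng_seed`. Pass `NA` to
#'   continue the current RNG stream.
#' @return list with `table` (an [otu_table]) and `truth` (per-OTU category
#'   — all `"neutral"` —, `m_true`, per-sample `band`, planted elevation
#'   `breakpoints`, and the metacommunity `p`).
#' @export
simulate_neutral_community <- function(spec, seed = spec$rng_seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- spec$n_samples; k <- spec$n_otus; N <- spec$reads_per_sample
  p <- switch(spec$metacommunity_shape,
    lognormal = stats::rlnorm(k, meanlog = 0, sdlog = spec$sdlog),
    logseries = {
      # Fisher log-series: abundance n with probability proportional to
      # theta^n / n (logarithmic distribution), sampled by inversion
      theta <- 0.999
      nmax <- 100000L
      pr <- theta^(seq_len(nmax)) / seq_len(nmax)
      sample.int(nmax, k, replace = TRUE, prob = pr)
    })
  p <- p / sum(p)
  alpha <- N * spec$m_true * p
  counts <- matrix(0L, k, n)
  for (j in seq_len(n)) {
    repeat {
      g <- stats::rgamma(k, shape = alpha)
      if (sum(g) > 0) break
    }
    counts[, j] <- stats::rmultinom(1, N, g / sum(g))[, 1]
  }
  otu_ids <- sprintf("OTU%04d", seq_len(k))
  sample_ids <- sprintf("S%03d", seq_len(n))
  tab <- otu_table(counts, otu_ids, sample_ids)
  band <- factor(rep(.band_labels(length(spec$band_sizes)),
                     times = spec$band_sizes),
                 levels = .band_labels(length(spec$band_sizes)))
  names(band) <- sample_ids
  mids <- (spec$band_ranges[-1, 1] + spec$band_ranges[-nrow(spec$band_ranges), 2]) / 2
  truth <- list(category = stats::setNames(rep("neutral", k), otu_ids),
                m_true = spec$m_true, band = band, breakpoints = mids,
                p = stats::setNames(p, otu_ids),
                specialist_band = character(0))
  list(table = tab, truth = truth)
}

#' Plant generalist and specialist niche structure
#'
#' Overwrites the neutral backbone for randomly chosen OTUs: specialists
#' have their reads confined to a single (randomly assigned) elevation
#' band — counts outside the home band are zeroed; generalists are spread
#' deterministically even across all samples. Every sample is then
#' re-normalized to exactly `reads_per_sample` reads by largest-remainder
#' rounding, which is deterministic and keeps planted zeros exactly zero.
#' With both fractions 0 the table is returned untouched.
#'
#' @param table the neutral [otu_table].
#' @param truth its ground truth.
#' @param spec the [synth_spec()].
#' @param seed optional seed (`NA` continues the current stream; default
#'   continues the stream, so [simulate_dataset()] stays reproducible from
#'   a single seed).
#' @return list with the modified `table` and updated `truth`.
#' @export
plant_niche_structure <- function(table, truth, spec, seed = NA) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  k <- nrow(table)
  n_spec <- round(spec$frac_specialist * k)
  n_gen <- round(spec$frac_generalist * k)
  if (n_spec + n_gen == 0) return(list(table = table, truth = truth))
  if (n_spec + n_gen > k) stop("category fractions exceed available OTUs")
  planted <- sample.int(k, n_spec + n_gen)
  spec_idx <- planted[seq_len(n_spec)]
  gen_idx <- planted[n_spec + seq_len(n_gen)]
  band <- truth$band
  bl <- levels(band)
  home <- sample(bl, n_spec, replace = TRUE)
  x <- unclass(table)
  storage.mode(x) <- "double"
  for (i in seq_along(spec_idx)) {
    out_band <- band != home[i]
    row <- x[spec_idx[i], ]
    tot <- sum(row)
    row[out_band] <- 0
    if (sum(row) == 0 && tot > 0) {
      # specialist that happened to miss its home band: move its mass there
      row[!out_band] <- tot / sum(!out_band)
    }
    x[spec_idx[i], ] <- row
  }
  if (length(gen_idx)) {
    tots <- rowSums(x[gen_idx, , drop = FALSE])
    x[gen_idx, ] <- matrix(tots / ncol(x), length(gen_idx), ncol(x))
  }
  counts <- apply(x, 2, .round_to_total, n = spec$reads_per_sample)
  tab <- otu_table(counts, rownames(table), colnames(table))
  truth$category[spec_idx] <- "specialist"
  truth$category[gen_idx] <- "generalist"
  truth$specialist_band <- stats::setNames(home, rownames(table)[spec_idx])
  list(table = tab, truth = truth)
}

# covariate recipes: block, direction of elevation trend, mean, sd, range
.covariate_recipes <- function() {
  r <- function(block, dir, mean, sd, lo = -Inf, hi = Inf)
    list(block = block, dir = dir, mean = mean, sd = sd, lo = lo, hi = hi)
  list(
    CON = r("topography", +1, 0, 5),
    SLO = r("topography", +1, 25, 8, 0, 60),
    ASP = r("topography", -1, 180, 60, 0, 360),
    ALA = r("light", +1, 45, 8, 0, 90),
    CC = r("light", -1, 0.7, 0.1, 0, 1),
    TR = r("light", +1, 30, 5, 0, Inf),
    SR = r("light", +1, 12, 2, 0, Inf),
    DR = r("light", +1, 18, 4, 0, Inf),
    LT = r("light", +1, 0.25, 0.08, 0, 1),
    LAI = r("light", -1, 3, 0.8, 0, Inf),
    soil_pH = r("soil", -1, 6.5, 0.5, 3, 9),
    organic_matter = r("soil", +1, 0.05, 0.015, 0, 1),
    alkaline_N = r("soil", +1, 0.0010, 0.0003, 0, 1),
    available_P = r("soil", -1, 0.0005, 0.00015, 0, 1),
    water_content = r("soil", +1, 0.30, 0.08, 0, 1)
  )
}

#' Simulate elevation-structured sample metadata
#'
#' Mean altitude (MEA) is drawn per band from non-overlapping uniform
#' ranges, so the planted band breakpoints are recoverable by the
#' regression tree. Every other covariate is a linear function of
#' standardized MEA plus Gaussian noise; the per-block effect sizes and
#' the noise SD come from the spec, and bounded covariates (fractions,
#' degrees, pH) are clipped to their valid ranges.
#'
#' @param spec a [synth_spec()].
#' @param truth ground truth carrying the per-sample band assignment.
#' @param seed optional seed (`NA` = continue the current stream).
#' @return a `sample_metadata` data.frame.
#' @export
simulate_metadata <- function(spec, truth, seed = NA) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  band <- truth$band
  n <- length(band)
  mea <- numeric(n)
  for (i in seq_along(levels(band))) {
    sel <- band == levels(band)[i]
    mea[sel] <- stats::runif(sum(sel), spec$band_ranges[i, 1],
                             spec$band_ranges[i, 2])
  }
  z <- as.numeric(scale(mea))
  df <- data.frame(sample_id = names(band), MEA = mea,
                   stringsAsFactors = FALSE)
  for (nm in names(.covariate_recipes())) {
    rc <- .covariate_recipes()[[nm]]
    eff <- spec$covariate_effects[[rc$block]]
    noise <- spec$covariate_noise_sd
    scale_to_sd <- sqrt(eff^2 + noise^2)
    v <- rc$dir * eff * z + stats::rnorm(n, sd = noise)
    if (scale_to_sd > 0) v <- v / scale_to_sd
    df[[nm]] <- pmin(rc$hi, pmax(rc$lo, rc$mean + rc$sd * v))
  }
  sample_metadata(df)
}

#' Simulate a full synthetic dataset with ground truth
#'
#' Neutral backbone first, then planted niche structure, then
#' elevation-structured metadata — all from a single seed, so the same
#' seed reproduces the dataset byte for byte.
#'
#' @param spec a [synth_spec()].
#' @return list with `table`, `metadata`, `truth`.
#' @export
simulate_dataset <- function(spec) {
  sim <- simulate_neutral_community(spec)
  sim <- plant_niche_structure(sim$table, sim$truth, spec)
  meta <- simulate_metadata(spec, sim$truth)
  list(table = sim$table, metadata = meta, truth = sim$truth)
}

#' Write ground truth as TSV
#' @param truth ground truth from [simulate_dataset()].
#' @param path_otus,path_samples output paths for the per-OTU and
#'   per-sample truth tables.
#' @export
write_ground_truth <- function(truth, path_otus, path_samples) {
  ot <- data.frame(otu_id = names(truth$category),
                   category = unname(truth$category),
                   stringsAsFactors = FALSE)
  ot$specialist_band <- truth$specialist_band[ot$otu_id]
  utils::write.table(ot, path_otus, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  st <- data.frame(sample_id = names(truth$band),
                   band = as.character(truth$band),
                   stringsAsFactors = FALSE)
  utils::write.table(st, path_samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
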