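#' Per-platform variable counts of the six-platform rice-grain design
#'
#' Default block widths for the synthetic generator: headspace SPME-GC-MS
#' (518 reconstructed peaks), 1H-NMR (95 frequency bins), direct-infusion MS
#' in negative (634) and positive (367) ionisation mode, GC-TOF-MS of
#' derivatised polar extracts (82 compounds) and ICP-MS micronutrients
#' (13 elements) -- 1709 variables in total.
#'
#' @return Named integer vector of platform widths.
#' @export
#' @examples
#' sum(rice_platform_dims())
rice_platform_dims <- function() {
  c(gcms = 518L, nmr = 95L, dims_neg = 634L, dims_pos = 367L,
    gctofms = 82L, icpms = 13L)
}

#' Configuration for the synthetic multi-platform study generator
#'
#' Bundles the design of a simulated class-structured metabolomics study:
#' how many samples and classes, the width of each platform block, how many
#' variables per platform carry a true class effect, and the size of that
#' effect. Intensities are log-normal: within a class, log-intensity is
#' Gaussian with standard deviation `noise_sd`, and a discriminative
#' variable's class means differ by `effect_size * noise_sd` on the log
#' scale, i.e. a standardized mean shift of `effect_size`.
#'
#' @param n_per_class Samples per class (default 22, so the default
#'   two-class design has 44 samples).
#' @param n_classes Number of classes (>= 2).
#' @param platform_dims Named integer vector of variables per platform.
#' @param n_discriminative Named integer vector (same names) of class-shifted
#'   variables per platform; default roughly 5% of each block.
#' @param effect_size Standardized between-class mean shift (units of
#'   within-class SD) of discriminative variables; 0 gives null data.
#' @param noise_sd Within-class SD of log-intensity.
#' @param blank_sd SD of ICP-MS blank measurements (concentration units).
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 22L, n_classes = 2L,
                       platform_dims = rice_platform_dims(),
                       n_discriminative = NULL,
                       effect_size = 2, noise_sd = 0.5,
                       blank_sd = 0.05, seed = 1L) {
  stopifnot_scalar_count(n_per_class, "n_per_class")
  stopifnot_scalar_count(n_classes, "n_classes", min = 2L)
  if (is.null(names(platform_dims)) || anyDuplicated(names(platform_dims)))
    stop("`platform_dims` must have unique names", call. = FALSE)
  platform_dims <- vapply(platform_dims, stopifnot_scalar_count,
                          integer(1), name = "platform_dims")
  if (is.null(n_discriminative))
    n_discriminative <- pmax(1L, as.integer(round(0.05 * platform_dims)))
  if (is.null(names(n_discriminative)))
    names(n_discriminative) <- names(platform_dims)
  n_discriminative <- n_discriminative[names(platform_dims)]
  if (anyNA(n_discriminative) || any(n_discriminative < 0) ||
      any(n_discriminative > platform_dims))
    stop("`n_discriminative` must satisfy 0 <= n_discriminative[p] <= ",
         "platform_dims[p] for every platform", call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("`effect_size` must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be > 0", call. = FALSE)
  if (!is.numeric(blank_sd) || blank_sd <= 0)
    stop("`blank_sd` must be > 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes),
                 platform_dims = platform_dims,
                 n_discriminative = stats::setNames(
                   as.integer(n_discriminative), names(platform_dims)),
                 effect_size = effect_size, noise_sd = noise_sd,
                 blank_sd = blank_sd, seed = as.integer(seed)),
            class = "sim_config")
}

sim_n_samples <- function(config) config$n_per_class * config$n_classes

sim_sample_ids <- function(config) {
  sprintf("S%03d", seq_len(sim_n_samples(config)))
}

sim_classes <- function(config) {
  rep(LETTERS[seq_len(config$n_classes)], each = config$n_per_class)
}

#' Generate sample metadata for a simulated study
#'
#' Produces a balanced metadata table mirroring a multi-country rice
#' germplasm panel: one row per sample with the simulated class label
#' (`group`, the factor all downstream comparisons use) plus plausible
#' accessory factors (variety, germplasm class, fragrance, storage,
#' country).
#'
#' @param config A [sim_config()].
#' @return A data.frame with `n_per_class * n_classes` rows.
#' @export
#' @examples
#' table(generate_metadata(sim_config(n_per_class = 5))$group)
generate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sim_n_samples(config)
  grp <- sim_classes(config)
  with_seed(config$seed, {
    germplasm <- sample(c("aromatic", "sadri", "indica", "japonica"),
                        n, replace = TRUE)
    storage <- sample(c("fresh", "stored"), n, replace = TRUE)
    country <- sample(c("Thailand", "India", "Pakistan", "Iran", "Laos",
                        "Italy", "USA", "Surinam", "Nepal", "Bangladesh"),
                      n, replace = TRUE)
    data.frame(sample_id = sim_sample_ids(config),
               variety = sprintf("V%03d", seq_len(n)),
               group = grp,
               germplasm = germplasm,
               fragrance = ifelse(grp == "A", "fragrant", "non-fragrant"),
               storage = storage,
               country = country,
               stringsAsFactors = FALSE)
  })
}

#' Generate per-platform feature blocks with known ground truth
#'
#' Draws one samples-by-variables intensity block per platform.
#' Log-intensities are Gaussian around a variable-specific baseline; a
#' seeded subset of variables per platform (`n_discriminative`) receives
#' class-dependent mean shifts of `effect_size * noise_sd` between adjacent
#' classes, so their population standardized effect equals `effect_size`.
#' All intensities are positive (log-normal), as required by
#' total-intensity normalisation downstream.
#'
#' @param config A [sim_config()].
#' @return A list with elements `blocks` (list of [feature_block()]s, one
#'   per platform) and `truth` (the ground truth: a data.frame
#'   `discriminative` of (platform, variable) pairs and a list
#'   `class_means` of per-platform classes-by-variables log-mean matrices).
#' @export
#' @examples
#' cfg <- sim_config(n_per_class = 4, platform_dims = c(ms = 10, nmr = 5),
#'                   n_discriminative = c(ms = 2, nmr = 1))
#' gen <- generate_feature_blocks(cfg)
#' vapply(gen$blocks, function(b) ncol(b$values), integer(1))
generate_feature_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sim_n_samples(config)
  ids <- sim_sample_ids(config)
  cls <- match(sim_classes(config), LETTERS)  # 1..K
  K <- config$n_classes
  # adjacent classes differ by effect_size * noise_sd on the log scale
  class_shift <- config$effect_size * config$noise_sd *
    (seq_len(K) - (K + 1) / 2)
  with_seed(config$seed, {
    blocks <- list()
    disc <- list()
    class_means <- list()
    for (pf in names(config$platform_dims)) {
      d <- config$platform_dims[[pf]]
      vars <- sprintf("%s:v%04d", pf, seq_len(d))
      mu <- rnorm(d, mean = 5, sd = 1.5)        # per-variable log baseline
      idx <- sort(sample.int(d, config$n_discriminative[[pf]]))
      cm <- matrix(rep(mu, each = K), nrow = K,
                   dimnames = list(LETTERS[seq_len(K)], vars))
      cm[, idx] <- cm[, idx] + class_shift      # recycled down class rows
      logx <- cm[cls, , drop = FALSE] +
        matrix(rnorm(n * d, sd = config$noise_sd), n, d)
      values <- exp(logx)
      dimnames(values) <- list(ids, vars)
      blocks[[pf]] <- feature_block(values, platform = pf)
      disc[[pf]] <- data.frame(platform = pf, variable = vars[idx],
                               stringsAsFactors = FALSE)
      class_means[[pf]] <- cm
    }
    list(blocks = blocks,
         truth = list(discriminative = do.call(rbind, c(disc,
                        list(make.row.names = FALSE))),
                      class_means = class_means))
  })
}

#' Generate a raw GC-MS mass-signal table with noise estimates
#'
#' Emulates the output of peak extraction and alignment: a table of mass
#' signals with a per-signal noise estimate and per-sample intensities,
#' shaped to exercise the signal-to-noise randomisation and prevalence
#' rules. A configurable fraction of cells falls below 3x their noise
#' value, and a configurable number of trailing "rare" signals is present
#' (s/n >= 3) in only `rare_present` samples.
#'
#' @param config A [sim_config()].
#' @param n_signals Number of mass signals.
#' @param fraction_below Fraction of (signal, sample) cells drawn below
#'   s/n 3; 0 gives a table untouched by [snr_filter_randomize()].
#' @param rare_signals Number of signals forced to be rare.
#' @param rare_present Number of samples in which each rare signal is
#'   present (default 3, below the discard threshold).
#' @return A [signal_table()].
#' @export
generate_raw_gcms <- function(config, n_signals = 120L,
                              fraction_below = 0.1, rare_signals = 0L,
                              rare_present = 3L) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot_scalar_count(n_signals, "n_signals")
  if (rare_signals > n_signals)
    stop("`rare_signals` cannot exceed `n_signals`", call. = FALSE)
  n <- sim_n_samples(config)
  if (rare_present > n)
    stop("`rare_present` cannot exceed the sample count", call. = FALSE)
  with_seed(config$seed, {
    noise <- rlnorm(n_signals, meanlog = log(100), sdlog = 0.4)
    snr <- matrix(3 + rlnorm(n * n_signals, meanlog = 1.5, sdlog = 0.8),
                  n, n_signals)
    n_low <- floor(fraction_below * n * n_signals)
    if (n_low > 0) {
      low_cells <- sample.int(n * n_signals, n_low)
      snr[low_cells] <- runif(n_low, 0, 3)
    }
    if (rare_signals > 0) {
      for (j in seq(n_signals - rare_signals + 1L, n_signals)) {
        snr[, j] <- runif(n, 0, 3)
        present <- sample.int(n, rare_present)
        snr[present, j] <- 3 + rlnorm(rare_present, 1.5, 0.8)
      }
    }
    values <- sweep(snr, 2, noise, `*`)
    dimnames(values) <- list(sim_sample_ids(config),
                             sprintf("sig%04d", seq_len(n_signals)))
    signal_table(values, noise)
  })
}

#' Generate raw 1H-NMR spectra on a uniform ppm axis
#'
#' Each sample gets a spectrum of Gaussian peaks at shared chemical shifts
#' with sample-specific log-normal amplitudes, plus a TSP reference peak at
#' 0 ppm, so the reference-region integral over delta `[-0.05, 0.05]` is
#' positive in every sample. The axis step (default 0.001 ppm) puts at
#' least 10 points in every 0.01-ppm bucket.
#'
#' @param config A [sim_config()].
#' @param ppm_range Axis limits in ppm.
#' @param step Axis step in ppm.
#' @param n_peaks Number of metabolite peaks.
#' @return A list of class `nmr_spectra` with elements `ppm` (axis),
#'   `values` (samples x points) and `samples`.
#' @export
generate_raw_nmr <- function(config, ppm_range = c(-0.2, 9.8),
                             step = 0.001, n_peaks = 40L) {
  stopifnot(inherits(config, "sim_config"))
  if (step > 0.001) stop("`step` must be <= 0.001 ppm", call. = FALSE)
  n <- sim_n_samples(config)
  ppm <- seq(ppm_range[1], ppm_range[2], by = step)
  with_seed(config$seed, {
    pos <- runif(n_peaks, 0.5, 9.5)
    wid <- runif(n_peaks, 0.002, 0.008)
    base_amp <- rlnorm(n_peaks, meanlog = 3, sdlog = 1)
    tsp_amp <- rlnorm(n, meanlog = log(100), sdlog = 0.1)
    # fixed peak shapes (n_peaks x npoints); samples differ in amplitude only
    shapes <- vapply(seq_len(n_peaks),
                     function(k) dnorm(ppm, pos[k], wid[k]) * wid[k],
                     numeric(length(ppm)))
    amps <- sweep(matrix(rlnorm(n * n_peaks, 0, config$noise_sd),
                         n, n_peaks), 2, base_amp, `*`)
    values <- amps %*% t(shapes) +
      tsp_amp %*% t(dnorm(ppm, 0, 0.005) * 0.005)
    rownames(values) <- sim_sample_ids(config)
    structure(list(ppm = ppm, values = values,
                   samples = sim_sample_ids(config)),
              class = "nmr_spectra")
  })
}

#' Generate raw direct-infusion MS spectra
#'
#' Per-sample (m/z, intensity) pairs at shared peak positions within the
#' instrument's 50-1000 m/z window, with log-normal per-sample intensities.
#'
#' @param config A [sim_config()].
#' @param mode Ionisation mode label ("negative" or "positive").
#' @param n_peaks Number of distinct m/z positions.
#' @return A list of class `dims_spectra` with elements `mz` (sorted axis),
#'   `values` (samples x positions), `samples` and `mode`.
#' @export
generate_raw_dims <- function(config, mode = c("negative", "positive"),
                              n_peaks = 600L) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  n <- sim_n_samples(config)
  # decouple the two modes' streams
  seed <- config$seed + ifelse(mode == "negative", 0L, 1L)
  with_seed(seed, {
    mz <- sort(runif(n_peaks, 50, 1000))
    base_amp <- rlnorm(n_peaks, meanlog = 4, sdlog = 1.2)
    values <- matrix(rlnorm(n * n_peaks, 0, config$noise_sd), n, n_peaks)
    values <- sweep(values, 2, base_amp, `*`)
    rownames(values) <- sim_sample_ids(config)
    structure(list(mz = mz, values = values,
                   samples = sim_sample_ids(config), mode = mode),
              class = "dims_spectra")
  })
}

#' Names of the 13 elements of the ICP-MS micronutrient panel
#' @return Character vector of element symbols.
#' @export
icpms_elements <- function() {
  c("Na", "Mg", "Al", "P", "S", "K", "Ca", "Mn", "Fe", "Ni", "Cu",
    "Zn", "Mo")
}

#' Generate a raw ICP-MS element panel with blank replicates
#'
#' Concentrations for the 13-element micronutrient panel plus a set of
#' blank replicates per element (default 7, the minimum required for
#' blank-based limit-of-detection estimation). A configurable number of
#' (sample, element) cells can be forced below the LOD to exercise the
#' filter.
#'
#' @param config A [sim_config()]; `blank_sd` sets the blank SD.
#' @param n_blanks Number of blank replicates per element.
#' @param n_below_lod Number of cells forced below the detection limit.
#' @param certified Logical: attach synthetic certified reference means
#'   (within a few percent of the panel means)?
#' @return A list of class `element_panel` with `values`
#'   (samples x elements), `blanks` (replicates x elements) and optional
#'   `certified` (named vector).
#' @export
generate_raw_icpms <- function(config, n_blanks = 7L, n_below_lod = 0L,
                               certified = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot_scalar_count(n_blanks, "n_blanks")
  n <- sim_n_samples(config)
  el <- icpms_elements()
  with_seed(config$seed, {
    base <- rlnorm(length(el), meanlog = 3, sdlog = 1.5)
    values <- sweep(matrix(rlnorm(n * length(el), 0, config$noise_sd),
                           n, length(el)), 2, base, `*`)
    dimnames(values) <- list(sim_sample_ids(config), el)
    blanks <- matrix(rnorm(n_blanks * length(el), mean = 4 * config$blank_sd,
                           sd = config$blank_sd),
                     n_blanks, length(el), dimnames = list(NULL, el))
    if (n_below_lod > 0) {
      cells <- sample.int(n * length(el), n_below_lod)
      values[cells] <- 0
    }
    cert <- NULL
    if (certified)
      cert <- colMeans(values) * runif(length(el), 0.97, 1.03)
    structure(list(values = values, blanks = blanks, certified = cert),
              class = "element_panel")
  })
}
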