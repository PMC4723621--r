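test_that("sub-noise randomization replaces only s/n < 3, within bounds", {
  # s/n 2.9 replaced into [24, 30); s/n 3.0 (boundary) untouched
  st <- signal_table(matrix(c(29, 30, 45), 3, 1), noise = 10)
  out <- snr_filter_randomize(st, seed = 7)
  expect_gte(out$values[1, 1], 24)
  expect_lt(out$values[1, 1], 30)
  expect_identical(out$values[2:3, 1], st$values[2:3, 1])

  # property over a seeded batch: entries >= threshold never altered,
  # replacements always in [2.4, 3.0) x noise
  for (s in 1:5) {
    cfg <- sim_config(n_per_class = 5, seed = s)
    tab <- generate_raw_gcms(cfg, n_signals = 30, fraction_below = 0.3)
    out <- snr_filter_randomize(tab, seed = s)
    snr_in <- sweep(tab$values, 2, tab$noise, `/`)
    keep <- snr_in >= 3
    expect_identical(out$values[keep], tab$values[keep])
    ratio <- sweep(out$values, 2, out$noise, `/`)[!keep]
    expect_true(all(ratio >= 2.4 & ratio < 3))
  }
  expect_error(signal_table(matrix(1, 1, 1), noise = 0), "noise")
})

test_that("prevalence filter drops signals detected in <= 6 samples", {
  # 44 samples; three signals present in 6, 7, 0 samples
  v <- matrix(10, 44, 3)            # s/n 1 everywhere (noise 10)
  v[1:6, 1] <- 100                  # present in 6 -> discarded
  v[1:7, 2] <- 100                  # present in 7 -> retained
  st <- signal_table(v, noise = rep(10, 3))
  out <- prevalence_filter(st)
  expect_identical(colnames(out$values), "sig0002")
  # idempotent, and output is a subset of input signals
  expect_identical(prevalence_filter(out)$values, out$values)
})

test_that("bucketing counts, conserves intensity and localises peaks", {
  b <- bucket_spectrum(seq(0, 0.099, 0.001), rep(1, 100), 0.01, 0, 0.1)
  expect_length(b, 10)
  expect_true(all(b == 10))

  # conservation on an irregular spectrum
  metabofuse:::with_seed(3, {
    axis <- sort(runif(500, 0, 5))
    int <- rlnorm(500)
    bb <- bucket_spectrum(axis, int, 0.13, 0, 5)
    expect_equal(sum(bb), sum(int))
  })

  # Gaussian peak fully inside [2.50, 2.51): trapezoid oracle agrees and
  # >= 99% of its mass lands in that bucket
  axis <- seq(2.4, 2.6, 1e-4)
  int <- dnorm(axis, 2.505, 0.001)
  bb <- bucket_spectrum(axis, int, 0.01, 2.4, 2.6)
  peak_bucket <- bb[["2.5-2.51"]]
  expect_gt(peak_bucket / sum(bb), 0.99)
  inside <- axis >= 2.50 & axis < 2.51
  trapezoid <- sum(diff(axis[inside]) *
                   (head(int[inside], -1) + int[inside][-1]) / 2)
  expect_equal(peak_bucket * 1e-4, trapezoid, tolerance = 1e-3)
})

test_that("reference-region scaling normalises the region to exactly 1", {
  b <- c(2, 1, 3, 2)                 # region = buckets 2:3, sum 4
  out <- scale_to_reference_region(b, 2:3)
  expect_equal(out[1], 0.5, ignore_attr = TRUE)
  expect_equal(sum(out[2:3]), 1)
  # idempotent on normalized input; scale-invariant
  expect_equal(scale_to_reference_region(out, 2:3), out)
  expect_equal(scale_to_reference_region(17.3 * b, 2:3), out)
  expect_error(scale_to_reference_region(c(1, 0, 0, 1), 2:3), "region")
})

test_that("total-intensity normalisation sums to 1 and is scale-invariant", {
  expect_equal(normalize_total_intensity(c(1, 3)), c(0.25, 0.75))
  metabofuse:::with_seed(4, {
    x <- rlnorm(20)
    expect_equal(sum(normalize_total_intensity(x)), 1)
    expect_equal(normalize_total_intensity(5 * x),
                 normalize_total_intensity(x))
  })
  expect_equal(normalize_total_intensity(c(0, 2, 0)), c(0, 1, 0))
  expect_error(normalize_total_intensity(c(0, 0)), "zero")
})

test_that("empty buckets are dropped only when empty in every sample", {
  m <- rbind(a = c(1, 0, 0), b = c(2, 0, 1))
  colnames(m) <- c("50-51", "51-52", "52-53")
  out <- drop_empty_buckets(m, "dims_neg")
  expect_identical(colnames(out$values),
                   c("dims_neg:50-51", "dims_neg:52-53"))
  full <- drop_empty_buckets(m[, c(1, 3)], "dims_neg")
  expect_equal(unname(full$values), unname(m[, c(1, 3)]))
})

test_that("LOD is 3x the blank SD and demands at least 7 blanks", {
  blanks <- matrix(rep(c(1, 1.5, 2, 1, 0.5, 1.5, 1), 2), 7, 2,
                   dimnames = list(NULL, c("Zn", "Ni")))
  panel <- list(values = matrix(5, 2, 2,
                                dimnames = list(NULL, c("Zn", "Ni"))),
                blanks = blanks)
  lod <- compute_lod(panel)
  expect_equal(unname(lod), rep(3 * sd(blanks[, 1]), 2))
  expect_equal(unname(compute_lod(list(blanks = matrix(2, 7, 1)))), 0)
  expect_error(compute_lod(list(blanks = blanks[1:6, , drop = FALSE])),
               "7 blank")
})

test_that("LOD filter drops an element entirely on any sub-LOD sample", {
  v <- matrix(10, 4, 3, dimnames = list(NULL, c("Na", "Ni", "Mo")))
  v[2, 2] <- 0.5                       # one Ni sample below LOD
  v[1, 3] <- 1                         # one Mo sample exactly at LOD
  panel <- list(values = v, blanks = NULL)
  out <- apply_lod_filter(panel, lod = c(Na = 1, Ni = 1, Mo = 1))
  expect_identical(colnames(out$values), "icpms:Na")
  expect_equal(unname(out$values[, 1]), rep(10, 4))
  all_above <- apply_lod_filter(list(values = v * 0 + 10),
                                lod = c(1, 1, 1))
  expect_equal(ncol(all_above$values), 3)
})

test_that("certified-reference check uses a strict 10% boundary", {
  got <- validate_reference_material(
    c(Zn = 95, Cu = 110, Fe = 89.9), c(Zn = 100, Cu = 100, Fe = 100))
  expect_identical(unname(got), c(TRUE, FALSE, FALSE))
  expect_error(validate_reference_material(c(a = 1), c(a = 0)), "0")
})

test_that("platform wrappers deliver complete feature blocks", {
  cfg <- sim_config(n_per_class = 4, seed = 8)
  b1 <- preprocess_gcms(generate_raw_gcms(cfg, n_signals = 50,
                                          fraction_below = 0,
                                          rare_signals = 4), seed = 1)
  expect_s3_class(b1, "feature_block")
  expect_equal(ncol(b1$values), 46)

  b2 <- preprocess_nmr(generate_raw_nmr(cfg, ppm_range = c(-0.2, 4.8)))
  ref <- which(as.numeric(sub("-.*", "", sub("^nmr:", "",
    colnames(b2$values)))) >= -0.051)
  expect_true(all(b2$values >= 0))
  expect_false(anyNA(b2$values))

  b3 <- preprocess_dims(generate_raw_dims(cfg, n_peaks = 200))
  expect_true(all(abs(rowSums(b3$values) - 1) < 1e-12))
  expect_lte(ncol(b3$values), 950)

  b4 <- preprocess_icpms(generate_raw_icpms(cfg))
  expect_s3_class(b4, "feature_block")
  expect_true(all(b4$values > 0))
})
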