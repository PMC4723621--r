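#' Mass-signal table with per-signal noise estimates
#'
#' Container for aligned mass signals: a samples-by-signals intensity
#' matrix and one noise estimate per signal, the denominator of the
#' signal-to-noise ratio used by the filtering rules.
#'
#' @param values Numeric samples x signals matrix (non-negative), with
#'   sample IDs as row names and signal names as column names.
#' @param noise Numeric vector of per-signal noise values (> 0).
#' @return An object of class `signal_table`.
#' @export
signal_table <- function(values, noise) {
  values <- as_num_matrix(values, "values")
  if (length(noise) != ncol(values))
    stop("`noise` must have one value per signal", call. = FALSE)
  bad <- which(!is.finite(noise) | noise <= 0)
  if (length(bad))
    stop("non-positive noise for signal(s): ",
         paste(colnames(values)[bad], collapse = ", "), call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sig%04d", seq_len(ncol(values)))
  names(noise) <- colnames(values)
  structure(list(values = values, noise = noise), class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("signal_table: %d samples x %d signals\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Randomize sub-noise mass signals
#'
#' Replaces every intensity with signal-to-noise ratio strictly below
#' `threshold` by a uniform draw in `[low, high) * noise`; intensities at
#' or above the threshold are untouched. This mirrors the standard
#' treatment of sub-noise cells after peak alignment: the replaced values
#' are placeholders just under the detection limit, not measurements.
#'
#' Draws are made in fixed signal-major, sample-minor order from one
#' seeded stream, so the result is reproducible regardless of how the
#' table was assembled.
#'
#' @param x A [signal_table()].
#' @param threshold s/n below which a cell is randomized (default 3).
#' @param low,high Multipliers of the noise value bounding the replacement
#'   draw (default 2.4 and 3.0).
#' @param seed Optional RNG seed.
#' @return A `signal_table` with the same dimensions.
#' @export
#' @examples
#' st <- signal_table(matrix(c(29, 31), 2, 1), noise = 10)
#' snr_filter_randomize(st, seed = 1)$values
snr_filter_randomize <- function(x, threshold = 3, low = 2.4, high = 3.0,
                                 seed = NULL) {
  stopifnot(inherits(x, "signal_table"), low < high)
  with_seed(seed, {
    v <- x$values
    for (j in seq_len(ncol(v))) {
      nj <- x$noise[[j]]
      below <- which(v[, j] / nj < threshold)
      if (length(below))
        v[below, j] <- runif(length(below), low * nj, high * nj)
    }
    signal_table(v, x$noise)
  })
}

#' Discard rarely detected mass signals
#'
#' Removes signals detected (s/n at or above `threshold`) in fewer than
#' `min_present` samples; with the defaults, signals present in 6 or fewer
#' samples are discarded. Presence is judged on the intensities as given;
#' values replaced by [snr_filter_randomize()] all sit strictly below the
#' detection threshold and therefore never count as detections, so the
#' detected set is the same whether the filter runs before or after the
#' randomization step.
#'
#' @param x A [signal_table()].
#' @param min_present Minimum number of samples a signal must be detected
#'   in to be retained (default 7).
#' @param threshold Detection s/n threshold (default 3).
#' @return A `signal_table` keeping the surviving signals in order.
#' @export
prevalence_filter <- function(x, min_present = 7L, threshold = 3) {
  stopifnot(inherits(x, "signal_table"))
  snr <- sweep(x$values, 2, x$noise, `/`)
  n_present <- colSums(snr >= threshold)
  keep <- n_present >= min_present
  signal_table(x$values[, keep, drop = FALSE], x$noise[keep])
}

#' Integrate a spectrum into fixed-width buckets
#'
#' Reduces a spectrum on a continuous axis (ppm for NMR, m/z for
#' direct-infusion MS) to integrated regions ("buckets") of equal width.
#' Buckets are half-open, left-closed intervals
#' `[start + k*width, start + (k+1)*width)`, except the final bucket,
#' which is closed so the grid partitions `[start, stop]`. A bucket's
#' value is the sum of the intensities at axis points falling inside it;
#' total intensity within `[start, stop]` is conserved.
#'
#' @param axis Strictly increasing numeric axis positions.
#' @param intensity Non-negative intensities, one per axis point.
#' @param width Bucket width in axis units (e.g. 0.01 ppm, 1 m/z).
#' @param start,stop Axis range to bucket (`start < stop`).
#' @return Named numeric vector of `ceiling((stop - start)/width)` bucket
#'   values; names give the bucket boundaries as `"<left>-<right>"`.
#' @export
#' @examples
#' bucket_spectrum(seq(0, 0.099, 0.001), rep(1, 100), 0.01, 0, 0.1)
bucket_spectrum <- function(axis, intensity, width, start, stop) {
  if (length(axis) != length(intensity))
    stop("`axis` and `intensity` lengths differ", call. = FALSE)
  if (is.unsorted(axis, strictly = TRUE))
    stop("`axis` must be strictly increasing", call. = FALSE)
  if (!(width > 0) || !(start < stop))
    stop("need `width` > 0 and `start` < `stop`", call. = FALSE)
  n_buckets <- ceiling((stop - start) / width)
  left <- start + (seq_len(n_buckets) - 1) * width
  out <- numeric(n_buckets)
  names(out) <- sprintf("%g-%g", left, pmin(left + width, stop))
  idx <- floor((axis - start) / width) + 1
  # final bucket is closed: points exactly at `stop` belong to it
  idx[axis == stop] <- n_buckets
  in_range <- axis >= start & axis <= stop & idx <= n_buckets
  if (any(in_range)) {
    sums <- tapply(intensity[in_range], idx[in_range], sum)
    out[as.integer(names(sums))] <- sums
  }
  out
}

#' Scale bucketed intensities to a reference region
#'
#' Divides every bucket by the summed intensity of a reference region
#' (for 1H-NMR, the TSP-d4 region delta 0.05 to -0.05), so the reference
#' region of the output sums to exactly 1. Scale-invariant: multiplying
#' the input by any positive constant leaves the output unchanged.
#'
#' @param buckets Numeric vector (or samples x buckets matrix) of bucket
#'   values.
#' @param region Integer indices of the reference buckets.
#' @return Scaled buckets with the same shape.
#' @export
scale_to_reference_region <- function(buckets, region) {
  if (is.matrix(buckets)) {
    ref <- rowSums(buckets[, region, drop = FALSE])
    if (any(ref <= 0))
      stop("non-positive reference-region integral in sample(s): ",
           paste(which(ref <= 0), collapse = ", "), call. = FALSE)
    return(sweep(buckets, 1, ref, `/`))
  }
  ref <- sum(buckets[region])
  if (ref <= 0)
    stop("reference-region integral must be > 0", call. = FALSE)
  buckets / ref
}

#' Scale bucketed intensities to total spectrum intensity
#'
#' Divides each spectrum by its total intensity so the output sums to 1,
#' removing per-sample differences in overall signal (e.g. infusion
#' efficiency in direct-infusion MS).
#'
#' @param buckets Numeric vector (or samples x buckets matrix).
#' @return Scaled buckets summing to 1 (per row for a matrix).
#' @export
#' @examples
#' normalize_total_intensity(c(1, 3))
normalize_total_intensity <- function(buckets) {
  if (is.matrix(buckets)) {
    tot <- rowSums(buckets)
    if (any(tot <= 0))
      stop("all-zero spectrum in sample(s): ",
           paste(which(tot <= 0), collapse = ", "), call. = FALSE)
    return(sweep(buckets, 1, tot, `/`))
  }
  tot <- sum(buckets)
  if (tot <= 0) stop("all-zero spectrum: total intensity must be > 0",
                     call. = FALSE)
  buckets / tot
}

#' Drop buckets that are empty in every sample
#'
#' Removes columns that are zero across all samples (nominal grid buckets
#' that caught no signal) and wraps the survivors as a [feature_block()].
#' Variable names keep the bucket-boundary labels, prefixed by the
#' platform tag.
#'
#' @param buckets Samples x buckets numeric matrix.
#' @param platform Platform tag for the resulting block.
#' @return A `feature_block`.
#' @export
drop_empty_buckets <- function(buckets, platform) {
  buckets <- as_num_matrix(buckets, "buckets")
  keep <- colSums(buckets != 0) > 0
  out <- buckets[, keep, drop = FALSE]
  colnames(out) <- paste0(platform, ":", colnames(out))
  feature_block(out, platform = platform)
}

#' Blank-based limit of detection
#'
#' LOD per element is `k` times the sample standard deviation of its
#' blank replicates; at least `min_blanks` replicates (default 7) are
#' required for the SD to be meaningful.
#'
#' @param panel An `element_panel` (see [generate_raw_icpms()]): a list
#'   with `values` (samples x elements) and `blanks`
#'   (replicates x elements).
#' @param k Multiplier of the blank SD (default 3).
#' @param min_blanks Minimum blank replicates per element.
#' @return Named numeric vector of per-element LODs.
#' @export
#' @examples
#' p <- generate_raw_icpms(sim_config(n_per_class = 3))
#' compute_lod(p)
compute_lod <- function(panel, k = 3, min_blanks = 7L) {
  stopifnot(is.list(panel), is.matrix(panel$blanks))
  n_blanks <- colSums(!is.na(panel$blanks))
  short <- which(n_blanks < min_blanks)
  if (length(short))
    stop("fewer than ", min_blanks, " blank replicates for element(s): ",
         paste(colnames(panel$blanks)[short], collapse = ", "),
         call. = FALSE)
  k * apply(panel$blanks, 2, sd, na.rm = TRUE)
}

#' Apply the limit-of-detection filter to an element panel
#'
#' Values not strictly above the element's LOD are below the detection
#' limit; any element with at least one such value in any sample is
#' dropped entirely, so the resulting block is complete (no missing
#' values) as required by the downstream multivariate models.
#'
#' @param panel An `element_panel`.
#' @param lod Named per-element LOD vector, e.g. from [compute_lod()].
#' @param platform Platform tag (default `"icpms"`).
#' @return A `feature_block` of the surviving elements, values unchanged.
#' @export
apply_lod_filter <- function(panel, lod, platform = "icpms") {
  v <- panel$values
  stopifnot(is.matrix(v), length(lod) == ncol(v))
  keep <- colSums(sweep(v, 2, lod, `<=`)) == 0
  out <- v[, keep, drop = FALSE]
  colnames(out) <- paste0(platform, ":", colnames(out))
  feature_block(out, platform = platform)
}

#' Check measured element means against certified reference values
#'
#' An element passes when its measured mean deviates from the certified
#' reference mean by strictly less than `tol` (default 10%); a deviation
#' of exactly 10% fails.
#'
#' @param measured Named per-element measured means.
#' @param certified Named per-element certified means (non-zero).
#' @param tol Maximum allowed relative deviation (default 0.10).
#' @return Named logical vector, `TRUE` = accepted.
#' @export
#' @examples
#' validate_reference_material(c(Zn = 95), c(Zn = 100))
validate_reference_material <- function(measured, certified, tol = 0.10) {
  if (!is.null(names(measured)) && !is.null(names(certified)))
    certified <- certified[names(measured)]
  if (length(measured) != length(certified) || anyNA(certified))
    stop("`measured` and `certified` must cover the same elements",
         call. = FALSE)
  if (any(certified == 0))
    stop("certified value of 0 for element(s): ",
         paste(names(measured)[certified == 0], collapse = ", "),
         call. = FALSE)
  ok <- abs(measured - certified) / abs(certified) < tol
  names(ok) <- names(measured)
  ok
}

#' One-call preprocessing of a raw GC-MS signal table
#'
#' Applies sub-noise randomization and then the prevalence filter. The two
#' steps commute here: randomized replacements all lie strictly below the
#' detection threshold, so the set of detections the prevalence filter sees
#' is the pre-randomization one.
#'
#' @param x A [signal_table()].
#' @param platform Platform tag.
#' @param min_present,threshold,seed Passed to the two filters.
#' @return A `feature_block`.
#' @export
preprocess_gcms <- function(x, platform = "gcms", min_present = 7L,
                            threshold = 3, seed = NULL) {
  x <- snr_filter_randomize(x, threshold = threshold, seed = seed)
  x <- prevalence_filter(x, min_present = min_present, threshold = threshold)
  feature_block(x$values, platform = platform)
}

#' One-call preprocessing of raw NMR spectra
#'
#' Buckets every spectrum into equal-width ppm regions (default 0.01 ppm),
#' scales each sample to its TSP reference region (default delta
#' `[-0.05, 0.05]`), and drops buckets empty in all samples.
#'
#' @param x An `nmr_spectra` object (see [generate_raw_nmr()]).
#' @param width Bucket width in ppm.
#' @param ref_region Length-2 ppm bounds of the reference region.
#' @param range Length-2 ppm bounds to bucket; defaults to the axis range.
#' @param platform Platform tag.
#' @return A `feature_block`.
#' @export
preprocess_nmr <- function(x, width = 0.01, ref_region = c(-0.05, 0.05),
                           range = NULL, platform = "nmr") {
  stopifnot(inherits(x, "nmr_spectra"))
  if (is.null(range)) range <- c(min(x$ppm), max(x$ppm))
  b <- t(apply(x$values, 1, bucket_spectrum, axis = x$ppm, width = width,
               start = range[1], stop = range[2]))
  left <- range[1] + (seq_len(ncol(b)) - 1) * width
  region <- which(left + width > ref_region[1] & left < ref_region[2])
  b <- scale_to_reference_region(b, region)
  drop_empty_buckets(b, platform)
}

#' One-call preprocessing of raw direct-infusion MS spectra
#'
#' Buckets each spectrum into unit-m/z regions over 50-1000 (grid
#' `[50,51), ..., [999,1000]`, final bucket closed), scales each sample to
#' total spectrum intensity, and drops buckets empty in all samples.
#'
#' @param x A `dims_spectra` object (see [generate_raw_dims()]).
#' @param width Bucket width in m/z.
#' @param range Length-2 m/z bounds (default `c(50, 1000)`).
#' @param platform Platform tag; defaults to `dims_<mode>`.
#' @return A `feature_block`.
#' @export
preprocess_dims <- function(x, width = 1, range = c(50, 1000),
                            platform = NULL) {
  stopifnot(inherits(x, "dims_spectra"))
  if (is.null(platform)) platform <- paste0("dims_", substr(x$mode, 1, 3))
  b <- t(apply(x$values, 1, bucket_spectrum, axis = x$mz, width = width,
               start = range[1], stop = range[2]))
  b <- normalize_total_intensity(b)
  drop_empty_buckets(b, platform)
}

#' One-call preprocessing of a raw ICP-MS panel
#'
#' Computes blank-based LODs, optionally drops elements failing the
#' certified-reference check, and applies the LOD filter.
#'
#' @param panel An `element_panel`.
#' @param k,min_blanks Passed to [compute_lod()].
#' @param check_reference Apply [validate_reference_material()] when the
#'   panel carries certified means?
#' @param platform Platform tag.
#' @return A `feature_block`.
#' @export
preprocess_icpms <- function(panel, k = 3, min_blanks = 7L,
                             check_reference = TRUE, platform = "icpms") {
  lod <- compute_lod(panel, k = k, min_blanks = min_blanks)
  if (check_reference && !is.null(panel$certified)) {
    ok <- validate_reference_material(colMeans(panel$values),
                                      panel$certified)
    panel$values <- panel$values[, ok, drop = FALSE]
    lod <- lod[ok]
  }
  apply_lod_filter(panel, lod, platform = platform)
}
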