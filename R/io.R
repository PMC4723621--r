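#' Write a feature block as delimited text
#'
#' Tab-delimited table: header row `sample_id` + variable names, one row
#' per sample. Values are printed with 17 significant digits so a
#' read-back reproduces the block to full double precision.
#'
#' @param block A [feature_block()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_block <- function(block, path) {
  stopifnot(inherits(block, "feature_block"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", block$variable_names), collapse = "\t"),
             con)
  for (i in seq_len(nrow(block$values)))
    writeLines(paste(c(block$sample_ids[i],
                       sprintf("%.17g", block$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a feature block from delimited text
#'
#' Inverse of [write_feature_block()]. The table is validated: sample IDs
#' and variable names must be unique, rows must not be ragged, and every
#' cell must be a non-missing number — violations raise an error naming
#' the offending row/column.
#'
#' @param path File path.
#' @param platform Platform tag for the block; default: the common prefix
#'   of the variable names (before `":"`), else the file name.
#' @return A [feature_block()].
#' @export
read_feature_block <- function(path, platform = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  vars <- header[-1L]
  if (anyDuplicated(vars))
    stop("duplicated variable name(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "),
         call. = FALSE)
  n <- length(lines) - 1L
  ids <- character(n)
  values <- matrix(NA_real_, n, length(vars))
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != length(header))
      stop(sprintf("row %d has %d fields, expected %d", i + 1L,
                   length(f), length(header)), call. = FALSE)
    ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   i + 1L, vars[bad[1L]]), call. = FALSE)
    values[i, ] <- v
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(ids, vars)
  if (is.null(platform)) {
    pre <- unique(sub(":.*$", "", vars))
    platform <- if (length(pre) == 1L && pre != vars[1L]) pre
                else sub("\\.[^.]*$", "", basename(path))
  }
  feature_block(values, platform = platform)
}

#' Write a fused matrix as delimited text
#'
#' Two header rows — the platform of each column, then the variable
#' names — followed by one row per sample. 17 significant digits, so the
#' round trip through [read_fused_matrix()] is exact.
#'
#' @param fused A [concatenate_blocks()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fused_matrix <- function(fused, path) {
  stopifnot(inherits(fused, "fused_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("platform", fused$platform), collapse = "\t"), con)
  writeLines(paste(c("sample_id", fused$variable_names), collapse = "\t"),
             con)
  for (i in seq_len(nrow(fused$values)))
    writeLines(paste(c(fused$sample_ids[i],
                       sprintf("%.17g", fused$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a fused matrix written by [write_fused_matrix()]
#' @param path File path.
#' @return A `fused_matrix` (without scaling parameters; the values are
#'   as written).
#' @export
read_fused_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("no data rows in ", path, call. = FALSE)
  platform <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][-1L]
  blk <- read_feature_block_lines(lines[-1L], path)
  structure(list(values = blk$values, sample_ids = rownames(blk$values),
                 platform = platform,
                 variable_names = colnames(blk$values),
                 scaled = NA, center = NULL, scale = NULL),
            class = "fused_matrix")
}

# shared line parser (header + rows) used by read_fused_matrix
read_feature_block_lines <- function(lines, path) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  read_feature_block(tmp, platform = "fused")
}

#' Run the whole pipeline on synthetic data
#'
#' End-to-end orchestration: generate the synthetic study (metadata plus
#' per-platform blocks), fuse the blocks, run PCA and Ward clustering,
#' run the double cross-validated PLS-DA with permutation test and rank
#' products, and write every result as delimited text (plus a Newick
#' dendrogram and a DCF run manifest) under `outdir`. Given the same
#' configuration and seed the output files are reproducible
#' byte-for-byte.
#'
#' @param config A [sim_config()] describing the simulated study.
#' @param outdir Output directory (created if needed).
#' @param n_permutations Permutations for the significance test.
#' @param a_max Component cap for the cross-validation.
#' @return Invisibly, a named list of the artifact paths plus the main
#'   results (`fused`, `dcv`, `perm`, `rank_products`).
#' @export
run_pipeline <- function(config, outdir, n_permutations = 99L,
                         a_max = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- generate_metadata(config)
  gen <- generate_feature_blocks(config)
  blocks <- align_samples(gen$blocks)
  fused <- concatenate_blocks(blocks, scale = TRUE)

  paths <- list(metadata = file.path(outdir, "metadata.tsv"),
                fused = file.path(outdir, "fused_matrix.tsv"),
                scores = file.path(outdir, "pca_scores.tsv"),
                loadings = file.path(outdir, "pca_loadings.tsv"),
                dendrogram = file.path(outdir, "hca.nwk"),
                predictions = file.path(outdir, "dcv_predictions.tsv"),
                rank_products = file.path(outdir, "rank_products.tsv"),
                permutation = file.path(outdir, "permutation.tsv"),
                manifest = file.path(outdir, "manifest.dcf"))
  write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fused_matrix(fused, paths$fused)

  pca <- pca_fit(fused$values, max_components = min(10L,
                 nrow(fused$values) - 1L, ncol(fused$values)))
  write_result_table(data.frame(sample_id = fused$sample_ids,
                                pca$scores), paths$scores)
  write_result_table(data.frame(variable = rownames(pca$loadings),
                                platform = fused$platform, pca$loadings),
                     paths$loadings)
  hc <- hierarchical_cluster(fused$values)
  writeLines(dendrogram_to_newick(hc), paths$dendrogram)

  labels <- meta$group
  perm <- permutation_test(fused$values, labels,
                           n_permutations = n_permutations,
                           a_max = a_max, seed = config$seed)
  dcv <- perm$observed
  write_result_table(dcv$predictions, paths$predictions)
  rp <- rank_products(dcv)
  write_result_table(data.frame(variable = rownames(rp$log_sum),
                                platform = fused$platform,
                                geo_mean_rank = rp$geo_mean_rank[, 1L],
                                log_rank_sum = rp$log_sum[, 1L]),
                     paths$rank_products)
  write_result_table(data.frame(permutation = seq_along(perm$null_m),
                                null_m = perm$null_m),
                     paths$permutation)
  manifest <- c(seed = config$seed,
                n_samples = nrow(fused$values),
                n_variables = ncol(fused$values),
                n_classes = config$n_classes,
                effect_size = config$effect_size,
                a_max = dcv$a_max,
                n_permutations = n_permutations,
                misclassifications = dcv$misclassifications,
                permutation_p = fmt_num(perm$p_value))
  writeLines(paste0(names(manifest), ": ", manifest), paths$manifest)
  invisible(c(paths, list(fused = fused, dcv = dcv, perm = perm,
                          rank_products = rp)))
}

# delimited result tables at fixed 12-significant-digit precision for
# byte-stable regression comparisons
write_result_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
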