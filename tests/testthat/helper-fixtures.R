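# shared fixtures, built in code

# small single-platform simulated study
tiny_config <- function(n_per_class = 10, p = 50, n_disc = 5,
                        effect_size = 5, seed = 42) {
  sim_config(n_per_class = n_per_class, platform_dims = c(ms = p),
             n_discriminative = c(ms = n_disc), effect_size = effect_size,
             seed = seed)
}

tiny_study <- function(...) {
  cfg <- tiny_config(...)
  gen <- generate_feature_blocks(cfg)
  list(x = gen$blocks$ms$values, labels = generate_metadata(cfg)$group,
       truth = gen$truth, config = cfg)
}

# two tight, well-separated 2-d blobs (deterministic)
two_blob_matrix <- function(n_per = 5, gap = 10, seed = 1) {
  metabofuse:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2, 0, 0.1), n_per, 2),
               matrix(rnorm(n_per * 2, gap, 0.1), n_per, 2))
    rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
    x
  })
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
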