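# brute-force inner LOO oracle: R-level pls_fit per fold, all candidate A
brute_inner_errs <- function(x, labels, a_max) {
  n <- nrow(x)
  y <- dummy_code(labels)
  cls <- attr(y, "class_order")
  errs <- integer(a_max)
  for (j in seq_len(n)) {
    for (a in seq_len(a_max)) {
      fit <- suppressWarnings(pls_fit(x[-j, ], labels[-j], ncomp = a,
                                      class_order = cls))
      pred <- predict(fit, x[j, , drop = FALSE], type = "class")
      errs[a] <- errs[a] + (pred != labels[j])
    }
  }
  errs
}

test_that("inner LOO component selection matches a brute-force oracle", {
  st <- tiny_study(n_per_class = 6, p = 10, n_disc = 3, effect_size = 2,
                   seed = 51)
  sel <- inner_loo_select_ncomp(st$x, st$labels, a_max = 4)
  oracle <- brute_inner_errs(st$x, st$labels, 4)
  expect_identical(attr(sel, "errors"), oracle)
  expect_identical(as.integer(sel),
                   which.min(oracle))  # ties -> smallest A

  # perfectly separable in one component: returns 1 even with a_max = 5
  st2 <- tiny_study(n_per_class = 6, p = 10, n_disc = 5, effect_size = 8,
                    seed = 52)
  expect_equal(as.integer(inner_loo_select_ncomp(log(st2$x), st2$labels,
                                                 a_max = 5)), 1L)
  expect_equal(as.integer(inner_loo_select_ncomp(log(st2$x), st2$labels,
                                                 a_max = 1)), 1L)
  expect_error(inner_loo_select_ncomp(st2$x[1:2, ], st2$labels[1:2]),
               "3 samples")
})

test_that("double CV yields one honest model per sample", {
  # 10 of 50 variables at a 5-SD shift: the separation margin makes
  # error-free classification certain by construction, not by luck
  st <- tiny_study(n_per_class = 10, p = 50, n_disc = 10, effect_size = 5,
                   seed = 53)
  # effects are injected on the log scale; analyse log-intensities
  dcv <- double_cv(log(st$x), st$labels)
  expect_equal(nrow(dcv$predictions), 20)
  expect_equal(dim(dcv$coefficients), c(50, 2, 20))
  expect_equal(dcv$misclassifications,
               sum(dcv$predictions$predicted != dcv$predictions$true))
  # strong effect: error-free classification
  expect_equal(dcv$misclassifications, 0)
})

test_that("leakage guard: the left-out sample cannot influence its model", {
  st <- tiny_study(n_per_class = 5, p = 15, seed = 54)
  dcv1 <- double_cv(st$x, st$labels)
  x2 <- st$x
  x2[4, ] <- x2[4, ] * 1e3 + 77          # corrupt one sample
  dcv2 <- double_cv(x2, st$labels)
  # model fitted without sample 4 is bit-identical
  expect_identical(dcv1$coefficients[, , 4], dcv2$coefficients[, , 4])
  expect_identical(dcv1$predictions$ncomp[4], dcv2$predictions$ncomp[4])
})

test_that("misclassification count is invariant to sample order", {
  st <- tiny_study(n_per_class = 6, p = 20, n_disc = 3, effect_size = 1.5,
                   seed = 55)
  perm <- metabofuse:::with_seed(7, sample(nrow(st$x)))
  d1 <- double_cv(st$x, st$labels)
  d2 <- double_cv(st$x[perm, ], st$labels[perm])
  expect_equal(d1$misclassifications, d2$misclassifications)
})

test_that("shuffled labels classify at chance level", {
  st <- tiny_study(n_per_class = 10, p = 50, n_disc = 5, effect_size = 5,
                   seed = 56)
  shuffled <- metabofuse:::with_seed(8, sample(st$labels))
  dcv <- double_cv(st$x, shuffled)
  # binomial 99% band around 0.5 for n = 20
  band <- qbinom(c(0.005, 0.995), 20, 0.5)
  expect_gte(dcv$misclassifications, band[1])
  expect_lte(dcv$misclassifications, band[2])
})

test_that("double CV rejects degenerate class structures", {
  x <- metabofuse:::with_seed(9, matrix(rnorm(40), 8, 5))
  expect_error(double_cv(x, rep("a", 8)), "2 classes")
  expect_error(double_cv(x, c("a", rep("b", 7))), "at least 2 samples")
})

test_that("permutation p follows the add-one formula and is reproducible", {
  st <- tiny_study(n_per_class = 8, p = 30, n_disc = 5, effect_size = 6,
                   seed = 57)
  pt <- permutation_test(st$x, st$labels, n_permutations = 19, seed = 3)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_m <= pt$observed$misclassifications)) / 20)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  pt2 <- permutation_test(st$x, st$labels, n_permutations = 19, seed = 3)
  expect_identical(pt$null_m, pt2$null_m)
  # observed M = 0 and no null at 0 -> p = 1/20
  if (pt$observed$misclassifications == 0 && all(pt$null_m >= 1))
    expect_equal(pt$p_value, 1 / 20)
  expect_error(permutation_test(st$x, st$labels, n_permutations = 5),
               "19")
})

test_that("rank products: log-sum equals the integer product oracle", {
  # 3 models, 4 variables, 1 class: integer ranks
  B <- array(0, c(4, 1, 3))
  B[, 1, 1] <- c(4, 3, 2, 1)     # ranks 1,2,3,4
  B[, 1, 2] <- c(4, 1, 3, 2)     # ranks 1,4,2,3
  B[, 1, 3] <- c(2, 4, 3, 1)     # ranks 3,1,2,4
  rp <- rank_products(B)
  direct <- c(1 * 1 * 3, 2 * 4 * 1, 3 * 2 * 2, 4 * 3 * 4)
  expect_equal(drop(exp(rp$log_sum)), direct, tolerance = 1e-12)
  expect_equal(drop(rp$geo_mean_rank), direct^(1 / 3), tolerance = 1e-12)

  # a variable ranked 1 everywhere has product 1
  B1 <- array(rep(c(9, 2, 1), 3), c(3, 1, 3))
  expect_equal(rank_products(B1)$geo_mean_rank[1, 1], 1)

  # two models with ranks 2 and 3 -> product 6, geometric mean sqrt(6)
  B2 <- array(c(3, 2, 1, 3, 1, 2), c(3, 1, 2))
  expect_equal(exp(rank_products(B2)$log_sum[2, 1]), 6)
  expect_equal(rank_products(B2)$geo_mean_rank[2, 1], sqrt(6))
})

test_that("rank ties get average ranks; variable order is immaterial", {
  B <- array(c(5, 5, 1), c(3, 1, 1))
  rp <- rank_products(B)
  expect_equal(drop(rp$geo_mean_rank), c(1.5, 1.5, 3))
  st <- tiny_study(n_per_class = 5, p = 12, seed = 58)
  dcv <- double_cv(st$x, st$labels)
  rp1 <- rank_products(dcv)
  perm <- metabofuse:::with_seed(2, sample(12))
  rp2 <- rank_products(dcv$coefficients[perm, , , drop = FALSE])
  expect_equal(rp2$log_sum[rownames(rp1$log_sum), ], rp1$log_sum)
})

test_that("rank products recover injected discriminators", {
  st <- tiny_study(n_per_class = 10, p = 200, n_disc = 5, effect_size = 3,
                   seed = 59)
  dcv <- double_cv(log(st$x), st$labels)
  rp <- rank_products(dcv)
  top10 <- rownames(rp$log_sum)[order(rp$log_sum[, 1])][1:10]
  expect_true(all(st$truth$discriminative$variable %in% top10))
})

test_that("discriminator reports carry per-class statistics and flags", {
  st <- tiny_study(n_per_class = 8, p = 40, n_disc = 5, effect_size = 4,
                   seed = 60)
  dcv <- double_cv(log(st$x), st$labels)
  rp <- rank_products(dcv)
  rep1 <- summarize_discriminators(rp, st$x, st$labels, top_k = 10)
  expect_equal(nrow(rep1), 10)
  expect_true(all(c("mean_A", "sd_A", "level_A", "mean_B", "sd_B",
                    "level_B") %in% names(rep1)))
  v1 <- rep1$variable[1]
  mA <- mean(st$x[st$labels == "A", v1])
  mB <- mean(st$x[st$labels == "B", v1])
  expect_identical(rep1$level_A[1], if (mA > mB) "higher" else "lower")
  expect_equal(rep1$mean_A[1], mA)
  expect_equal(rep1$sd_B[1], sd(st$x[st$labels == "B", v1]))
  rep2 <- summarize_discriminators(rp, st$x, st$labels, top_k = 10)
  expect_identical(rep1, rep2)
})
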