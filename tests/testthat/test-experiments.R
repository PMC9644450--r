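# Experiment protocols: ablation grid, capacity sweep, heatmaps, instance
# selection, reference distances and rank-based method comparison.

test_that("ablation covers the 2x2 grid with shared folds", {
  bags <- small_bags(seed = 81, n = 40)
  tc <- fast_train_config(seed = 14, epochs = 5)
  folds <- kfold_split(vapply(bags, function(b) b$label, integer(1)),
                       k = 4, seed = 14)
  tab <- run_ablation(bags, small_model_config(), tc, folds = folds)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$variant, c("FC", "Skip", "Sparse", "Proposed"))
  grid <- unique(tab[, c("skip_on", "sparse_on")])
  expect_identical(nrow(grid), 4L)
  # the FC row is just a direct cross_validate with the switched config
  direct <- cross_validate(bags, variant_config(small_model_config(), "FC"),
                           tc, folds = folds)
  expect_equal(tab$mean_auc[tab$variant == "FC"], direct$mean_auc,
               tolerance = 1e-12)
})

test_that("variant configs differ only in the two ablation switches", {
  base <- small_model_config()
  for (v in c("FC", "Skip", "Sparse", "Proposed")) {
    cfg <- variant_config(base, v)
    cfg$use_skip <- base$use_skip
    cfg$pooling <- base$pooling
    expect_identical(sparsemil:::config_hash(cfg),
                     sparsemil:::config_hash(base))
  }
})

test_that("m* sweep produces one row per capacity", {
  bags <- small_bags(seed = 82, n = 30)
  tc <- fast_train_config(seed = 15, epochs = 4)
  tab <- mstar_sensitivity(bags, c(5, 10), small_model_config(), tc, k = 3)
  expect_identical(tab$m_star, c(5, 10))
  expect_true(all(is.finite(tab$mean_auc)))
  # degenerate capacity 1: only the first instance of each bag is used
  tab1 <- mstar_sensitivity(bags, 1, small_model_config(), tc, k = 3)
  expect_true(is.finite(tab1$mean_auc))
})

test_that("attention heatmap rows are simplex vectors over valid cells", {
  bags <- small_bags(seed = 83, n = 15)
  model <- random_model(seed = 84, m_star = max(vapply(bags, function(b)
    nrow(b$instances), integer(1))))
  hm <- attention_heatmap(model, bags)
  expect_true(all(abs(rowSums(hm$weights) - 1) < 1e-9))
  expect_true(all(hm$weights[!hm$mask] == 0))
  # rows sorted by bag size
  expect_true(!is.unsorted(rowSums(hm$mask)))
  # sparsemax rows have zeros on some valid cells; softmax rows have none
  soft <- model
  soft$config$pooling <- "softmax"
  hs <- attention_heatmap(soft, bags)
  expect_identical(sum(hs$weights[hs$mask] == 0), 0L)
  expect_gt(sum(hm$weights[hm$mask] == 0), 0L)
})

test_that("feature heatmap is min-max + log1p with constant-column guard", {
  bags <- small_bags(seed = 85, n = 12)
  model <- random_model(seed = 86, m_star = 60)
  fh <- feature_heatmap(model, bags)
  expect_equal(dim(fh), c(12, 8))
  expect_true(all(fh >= 0 & fh <= log(2) + 1e-12))
  # force a constant column via a degenerate single-bag call
  expect_warning(f1 <- feature_heatmap(model, bags[1]), "constant")
  expect_true(all(f1 == 0))
})

test_that("primary-instance labeling follows the attention support", {
  model <- random_model(seed = 87, m_star = 10)
  b <- random_bag(seed = 88, m = 6)
  sel <- label_primary_instances(model, b)
  expect_length(sel, 6)
  a <- bag_attention(model, list(b))$alpha[1, 1:6]
  expect_identical(sel, a > 0)
  # single-instance bag: the whole simplex mass on one instance
  b1 <- random_bag(seed = 89, m = 1)
  expect_identical(label_primary_instances(model, b1), TRUE)
  soft <- model
  soft$config$pooling <- "softmax"
  expect_error(label_primary_instances(soft, b), "unsupported pooling")
})

test_that("reference distances and rank-sum grouping behave sanely", {
  set.seed(90)
  emb <- matrix(rnorm(40 * 3), 40, 3)
  flags <- rep(c(TRUE, FALSE), 20)
  labels <- rep(c(1, 0), each = 20)
  # single zero reference vector: distance = own norm
  rep0 <- reference_distance_report(emb, flags, labels,
                                    matrix(0, 1, 3))
  expect_equal(rep0$distances, sqrt(rowSums(emb^2)))
  # identical groups: no detectable difference (label 0 empty by design)
  same <- suppressWarnings(
    reference_distance_report(rbind(emb[1:10, ], emb[1:10, ]),
                              rep(c(TRUE, FALSE), each = 10),
                              rep(1, 20), matrix(rnorm(15), 5, 3)))
  expect_gte(same$tests$p_value[same$tests$label == 1], 0.99)
  # both the label-0 groups and the label-1 non-primary group are empty
  expect_warning(expect_warning(
    reference_distance_report(emb[1:5, ], rep(TRUE, 5), rep(1, 5),
                              matrix(0, 1, 3)),
    "empty"))
  # primaries shifted away from the reference cloud sit farther from it
  prim <- matrix(rnorm(20 * 3, mean = 5), 20, 3)
  back <- matrix(rnorm(20 * 3), 20, 3)
  shifted <- suppressWarnings(
    reference_distance_report(rbind(prim, back),
                              rep(c(TRUE, FALSE), each = 20),
                              rep(1, 40),
                              matrix(rnorm(30), 10, 3)))
  tab <- shifted$table
  expect_gt(tab$mean_distance[tab$label == 1 & tab$primary],
            tab$mean_distance[tab$label == 1 & !tab$primary])
  expect_error(
    reference_distance_report(emb, flags, labels, matrix(0, 1, 2)),
    "dimension")
})

test_that("method comparison ranks and exact signed-rank test", {
  # A beats B on all 10 datasets
  tab <- rbind(A = seq(0.8, 0.89, by = 0.01),
               B = seq(0.7, 0.79, by = 0.01))
  mc <- compare_methods(tab, "A", "B")
  expect_equal(unname(mc$avg_rank["A"]), 1)
  expect_equal(unname(mc$avg_rank["B"]), 2)
  expect_equal(mc$signed_rank_p, 2 / 1024)

  # identical AUCs: all ranks tie at 1.5
  tied <- rbind(A = rep(0.8, 4), B = rep(0.8, 4))
  mct <- compare_methods(tied, "A", "B")
  expect_true(all(mct$ranks == 1.5))
  expect_equal(mct$signed_rank_p, 1)

  # single dataset: p undefined with warning
  expect_warning(one <- compare_methods(cbind(c(A = 0.9, B = 0.8)),
                                        "A", "B"),
                 "single dataset")
  expect_true(is.na(one$signed_rank_p))
  expect_error(compare_methods(matrix(0.5, 1, 3), 1, 1), ">= 2 methods")
})

test_that("within-dataset ranks agree with a sort-based oracle", {
  set.seed(91)
  m <- matrix(runif(40), 5, 8,
              dimnames = list(paste0("M", 1:5), NULL))
  mc <- compare_methods(m, "M1", "M2")
  for (d in 1:8) {
    expect_equal(sort(mc$ranks[, d]), sort(rank(-m[, d])))
    ord <- order(m[, d], decreasing = TRUE)
    expect_identical(rownames(m)[ord][1],
                     names(which.min(mc$ranks[, d])))
  }
})

test_that("exact signed-rank matches exhaustive sign enumeration", {
  set.seed(92)
  for (rep in 1:5) {
    d <- round(rnorm(8), 2)
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    # brute force over all 2^n sign patterns
    ws <- vapply(0:(2^n - 1), function(code) {
      signs <- bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0
      sum(r[signs])
    }, numeric(1))
    p_brute <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
    expect_equal(exact_signed_rank_test(d), p_brute)
  }
  expect_equal(exact_signed_rank_test(numeric(0)), 1)
})
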