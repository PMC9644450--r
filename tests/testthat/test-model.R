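# Network building blocks and the end-to-end forward pass: weight sharing,
# residual structure, masked attention, pooling, and the symmetry contracts
# (permutation and padding invariance) that make the model a set function.

test_that("local_fc applies one shared affine map per instance", {
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(local_fc_forward(X, diag(5), numeric(5)), X)
  W <- matrix(rnorm(25), 5, 5)
  b <- rnorm(5)
  out <- local_fc_forward(X, W, b)
  for (j in 1:4) expect_equal(out[j, ], drop(W %*% X[j, ]) + b)
  # single instance degenerates to an ordinary dense layer
  expect_equal(local_fc_forward(X[2, , drop = FALSE], W, b),
               out[2, , drop = FALSE])
  # weight sharing: permuting rows permutes outputs identically
  perm <- c(3, 1, 4, 2)
  expect_equal(local_fc_forward(X[perm, ], W, b), out[perm, ])
  expect_error(local_fc_forward(X, matrix(1, 3, 3), numeric(3)), "shape")
})

test_that("residual block reduces to identity / zero when F is zeroed", {
  X <- matrix(rnorm(12), 3, 4)
  Wz <- matrix(0, 4, 4)
  bz <- numeric(4)
  expect_equal(residual_block(X, Wz, bz, use_skip = TRUE), X)
  expect_equal(residual_block(X, Wz, bz, use_skip = FALSE),
               matrix(0, 3, 4))
  # dropout only acts in training mode
  W <- matrix(rnorm(16), 4, 4)
  b <- rnorm(4)
  expect_equal(residual_block(X, W, b, dropout_rate = 0.9,
                              training = FALSE),
               X + pmax(local_fc_forward(X, W, b), 0))
})

test_that("attention scorers behave as documented", {
  Z <- matrix(rnorm(24), 6, 4)
  mask <- rep(TRUE, 6)
  lin <- list(type = "linear", w = c(1, 0, 0, 0), b = 0)
  expect_equal(attention_scores(Z, mask, lin), Z[, 1])
  # identical rows yield identical scores
  Z2 <- Z[rep(2, 6), ]
  gt <- list(type = "gated_tanh", V = matrix(rnorm(12), 3, 4),
             w = rnorm(3))
  expect_equal(diff(range(attention_scores(Z2, mask, gt))), 0)
  # V = 0 gives constant scores, hence uniform sparsemax attention
  gt0 <- list(type = "gated_tanh", V = matrix(0, 3, 4), w = rnorm(3))
  sc <- attention_scores(Z, mask, gt0)
  expect_equal(masked_sparsemax(sc, mask), rep(1 / 6, 6))
  expect_error(attention_scores(Z, rep(FALSE, 6), lin), "empty bag")
})

test_that("attention pooling is the stated convex combination", {
  Z <- matrix(rnorm(15), 5, 3)
  onehot <- c(0, 0, 1, 0, 0)
  expect_equal(attention_pool(Z, onehot), Z[3, ])
  uni <- rep(1 / 5, 5)
  expect_equal(attention_pool(Z, uni), colMeans(Z))
  # garbage in zero-weight rows cannot leak through
  Zg <- Z
  Zg[4, ] <- 1e6
  a <- c(0.5, 0.5, 0, 0, 0)
  expect_equal(attention_pool(Z, a), attention_pool(Zg, a),
               tolerance = 1e-12)
  expect_error(attention_pool(Z, c(1, 0)), "length")
})

test_that("eval-mode forward is a permutation-invariant probability", {
  model <- random_model(seed = 51)
  b <- random_bag(seed = 52, m = 9)
  p1 <- predict(model, list(b))$probability
  expect_gt(p1, 0)
  expect_lt(p1, 1)
  set.seed(53)
  for (rep in 1:5) {
    perm <- sample(9)
    bp <- bag(b$instances[perm, ], b$label, b$bag_id)
    expect_equal(predict(model, list(bp))$probability, p1,
                 tolerance = 1e-6)
  }
})

test_that("eval-mode forward ignores capacity and padded-slot garbage", {
  model50 <- random_model(seed = 54, m_star = 50)
  model100 <- model50
  model100$config$m_star <- 100L
  b <- random_bag(seed = 55, m = 7)
  p50 <- predict(model50, list(b))$probability
  p100 <- predict(model100, list(b))$probability
  expect_equal(p50, p100, tolerance = 1e-6)
  # inject garbage into the padded slots directly
  batch <- pad_bags(list(b), m_star = 50)
  batch$X[!as.vector(t(batch$mask)), ] <- 1e3
  fw <- sparsemil:::minn_forward(model50, batch, training = FALSE)
  expect_equal(fw$prob, p50, tolerance = 1e-6)
})

test_that("forward rejects empty bags and non-finite features", {
  model <- random_model(seed = 56)
  batch <- pad_bags(list(random_bag(57, m = 3)), m_star = 5)
  batch$mask[1, ] <- FALSE
  expect_error(sparsemil:::minn_forward(model, batch), "empty bag")
  batch2 <- pad_bags(list(random_bag(58, m = 3)), m_star = 5)
  batch2$X[1, 1] <- NaN
  expect_error(sparsemil:::minn_forward(model, batch2), "invalid input")
})

test_that("sparsemax pooling yields exact zeros, softmax never does", {
  zeros_sparse <- numeric(20)
  zeros_soft <- numeric(20)
  for (s in 1:20) {
    b <- random_bag(seed = 600 + s, m = 10)
    msp <- random_model(seed = 700 + s, m_star = 10)
    mso <- msp
    mso$config$pooling <- "softmax"
    asp <- bag_attention(msp, list(b))$alpha[1, ]
    aso <- bag_attention(mso, list(b))$alpha[1, ]
    zeros_sparse[s] <- sum(asp == 0)
    zeros_soft[s] <- sum(aso == 0)
  }
  expect_gt(mean(zeros_sparse), 0)
  expect_identical(sum(zeros_soft), 0)
})

test_that("the ablation grid maps onto the two config switches", {
  base <- minn_config()
  fc <- variant_config(base, "FC")
  sk <- variant_config(base, "Skip")
  sp <- variant_config(base, "Sparse")
  pr <- variant_config(base, "Proposed")
  expect_false(fc$use_skip); expect_identical(fc$pooling, "softmax")
  expect_true(sk$use_skip); expect_identical(sk$pooling, "softmax")
  expect_false(sp$use_skip); expect_identical(sp$pooling, "sparsemax")
  expect_true(pr$use_skip); expect_identical(pr$pooling, "sparsemax")
})

test_that("extracted features are deterministic and support-driven", {
  model <- random_model(seed = 61, m_star = 10)
  bags <- lapply(1:6, function(i) random_bag(620 + i, m = 8))
  F1 <- extract_features(model, bags)
  F2 <- extract_features(model, bags)
  expect_equal(dim(F1), c(6, 8))
  expect_identical(F1, F2)
  # perturbing an instance with exactly zero attention leaves the bag's
  # features untouched
  att <- bag_attention(model, bags)
  for (i in 1:6) {
    off <- which(att$alpha[i, 1:8] == 0)
    if (length(off) == 0) next
    b <- bags[[i]]
    b$instances[off[1], ] <- b$instances[off[1], ] + 0.5
    altered <- bags
    altered[[i]] <- b
    Fa <- extract_features(model, altered)
    if (all(bag_attention(model, altered)$alpha[i, off[1]] == 0)) {
      expect_equal(Fa[i, ], F1[i, ], tolerance = 1e-9)
    }
  }
})

test_that("model config validates its invariants", {
  expect_error(minn_config(p = 0), "p >= 1")
  expect_error(minn_config(dropout_rate = 1), "dropout_rate < 1")
  expect_error(minn_config(n_blocks = 0), "n_blocks >= 1")
  expect_error(minn_init(minn_config()), "m_star")
})
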