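#' Model configuration for the sparse-attention MIL network
#'
#' The network applies `n_blocks` locally fully-connected residual blocks to
#' every instance (a shared `p x p` weight matrix per block — full
#' connections within an instance, none across instances), scores each
#' instance, pools instances with masked sparsemax (or softmax) attention,
#' batch-normalizes the pooled feature vector, and classifies it with a
#' single sigmoid unit.
#'
#' The four ablation variants form a 2x2 grid over `use_skip` and `pooling`:
#' `FC` = (no skip, softmax), `Skip` = (skip, softmax),
#' `Sparse` = (no skip, sparsemax), `Proposed` = (skip, sparsemax).
#'
#' @param p Instance feature dimension (30 for TESSA-style TCR embeddings).
#' @param m_star Bag capacity (instances per bag after padding/truncation);
#'   `NULL` defers to the largest bag size seen at training time.
#' @param n_blocks Number of residual blocks (depth).
#' @param use_skip Add the identity skip connection around each block?
#' @param pooling `"sparsemax"` (sparse attention, exact zeros) or
#'   `"softmax"` (dense attention baseline).
#' @param dropout_rate Probability of zeroing each activation during
#'   training (applied after each ReLU; inactive at evaluation).
#' @param scorer Attention score head: `"gated_tanh"`
#'   (`e_j = w . tanh(V z_j)`) or `"linear"` (`e_j = w . z_j + b`).
#' @param scorer_hidden Hidden width of the gated_tanh scorer.
#' @return Object of class `"minn_config"`.
#' @export
minn_config <- function(p = 30L,
                        m_star = NULL,
                        n_blocks = 4L,
                        use_skip = TRUE,
                        pooling = c("sparsemax", "softmax"),
                        dropout_rate = 0.3,
                        scorer = c("gated_tanh", "linear"),
                        scorer_hidden = p) {
  pooling <- match.arg(pooling)
  scorer <- match.arg(scorer)
  stopifnot(p >= 1, is.null(m_star) || m_star >= 1, n_blocks >= 1,
            dropout_rate >= 0, dropout_rate < 1, scorer_hidden >= 1)
  structure(
    list(p = as.integer(p),
         m_star = if (is.null(m_star)) NULL else as.integer(m_star),
         n_blocks = as.integer(n_blocks),
         use_skip = isTRUE(use_skip),
         pooling = pooling,
         dropout_rate = dropout_rate,
         scorer = scorer,
         scorer_hidden = as.integer(scorer_hidden)),
    class = "minn_config")
}

#' Derive an ablation-variant configuration
#'
#' @param config Base [minn_config()]; only the skip and pooling switches
#'   are changed.
#' @param variant One of `"FC"`, `"Skip"`, `"Sparse"`, `"Proposed"`.
#' @return Modified `minn_config`.
#' @export
variant_config <- function(config,
                           variant = c("Proposed", "FC", "Skip", "Sparse")) {
  variant <- match.arg(variant)
  config$use_skip <- variant %in% c("Skip", "Proposed")
  config$pooling <- if (variant %in% c("Sparse", "Proposed"))
    "sparsemax" else "softmax"
  config
}

he_uniform <- function(nrow, ncol = NULL, fan_in) {
  limit <- sqrt(6 / fan_in)
  if (is.null(ncol)) {
    stats::runif(nrow, -limit, limit)
  } else {
    matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
  }
}

#' Initialize an untrained model
#'
#' He-style uniform fan-in initialization for all weight matrices, zero
#' biases, batch-norm scale 1 / shift 0, and unit running variance. Uses
#' the current RNG stream unless `seed` is given.
#'
#' @param config A [minn_config()] with `m_star` resolved (non-NULL).
#' @param seed Optional integer seed for reproducible initialization.
#' @return Object of class `"minn_model"`.
#' @export
minn_init <- function(config, seed = NULL) {
  stopifnot(inherits(config, "minn_config"))
  if (is.null(config$m_star)) {
    stop("config$m_star must be set before initialization", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- config$p
  h <- config$scorer_hidden
  params <- list()
  for (l in seq_len(config$n_blocks)) {
    params[[paste0("W", l)]] <- he_uniform(p, p, fan_in = p)
    params[[paste0("b", l)]] <- numeric(p)
  }
  if (config$scorer == "gated_tanh") {
    params$Va <- he_uniform(h, p, fan_in = p)
    params$wa <- he_uniform(h, fan_in = h)
  } else {
    params$wa <- he_uniform(p, fan_in = p)
    params$ba <- 0
  }
  params$gamma <- rep(1, p)
  params$beta <- numeric(p)
  params$u <- he_uniform(p, fan_in = p)
  params$c0 <- 0
  structure(
    list(config = config,
         params = params,
         bn = list(mean = numeric(p), var = rep(1, p)),
         history = NULL),
    class = "minn_model")
}

#' @export
print.minn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<minn_model> p=%d m*=%d blocks=%d skip=%s pooling=%s scorer=%s%s\n",
    cfg$p, cfg$m_star, cfg$n_blocks, cfg$use_skip, cfg$pooling, cfg$scorer,
    if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Locally fully-connected layer (shared weights across instances)
#'
#' Applies the same affine map `W x + b` to every row (instance) of `X`:
#' full connectivity within an instance, none across instances. Row `j` of
#' the output depends only on row `j` of the input, so permuting rows
#' permutes outputs identically.
#'
#' @param X Instance matrix (`m x p`).
#' @param W Weight matrix (`p x p`).
#' @param b Bias vector (length `p`).
#' @return `m x p` matrix with rows `W X[j, ] + b`.
#' @export
local_fc_forward <- function(X, W, b) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(W) || nrow(W) != length(b)) {
    stop("invalid input: shape mismatch in local_fc_forward", call. = FALSE)
  }
  out <- X %*% t(W)
  out + rep(b, each = nrow(out))
}

#' One residual block of the instance encoder
#'
#' Computes `F(X) = dropout(relu(local_fc(X)))` and returns `X + F(X)` when
#' `use_skip`, else `F(X)`. Dropout draws are taken only when `training`.
#'
#' @inheritParams local_fc_forward
#' @param use_skip Include the identity bypass?
#' @param dropout_rate Zeroing probability during training.
#' @param training Training mode flag.
#' @return `m x p` matrix.
#' @export
residual_block <- function(X, W, b, use_skip = TRUE, dropout_rate = 0,
                           training = FALSE) {
  A <- pmax(local_fc_forward(X, W, b), 0)
  if (training && dropout_rate > 0) {
    keep <- matrix(stats::runif(length(A)) >= dropout_rate,
                   nrow(A), ncol(A))
    A <- A * keep / (1 - dropout_rate)
  }
  if (use_skip) X + A else A
}

#' Per-instance attention scores
#'
#' One scalar score per instance row of `Z`. Scores at masked (padded)
#' slots are computed but never consulted downstream: the pooling step
#' restricts the simplex projection to valid slots.
#'
#' @param Z Instance feature matrix (`m x p`).
#' @param mask Logical validity vector of length `m`; at least one `TRUE`.
#' @param scorer List describing the score head: either
#'   `list(type = "linear", w, b)` or `list(type = "gated_tanh", V, w)`.
#' @return Numeric vector of length `m`.
#' @export
attention_scores <- function(Z, mask, scorer) {
  Z <- as.matrix(Z)
  if (length(mask) != nrow(Z)) {
    stop("invalid input: mask length != instance count", call. = FALSE)
  }
  if (!any(mask)) stop("empty bag: mask has no TRUE entry", call. = FALSE)
  switch(scorer$type,
    linear = drop(Z %*% scorer$w) + scorer$b,
    gated_tanh = drop(tanh(Z %*% t(scorer$V)) %*% scorer$w),
    stop("unknown scorer type: ", scorer$type, call. = FALSE))
}

#' Attention pooling of instance features
#'
#' The convex combination `z_tilde = sum_j alpha[j] * Z[j, ]`. Since
#' padded slots carry weight exactly 0, their (finite) contents cannot
#' leak into the pooled vector.
#'
#' @param Z Instance feature matrix (`m x p`).
#' @param alpha Simplex weight vector of length `m` (zeros on padded slots).
#' @return Numeric vector of length `p`.
#' @export
attention_pool <- function(Z, alpha) {
  Z <- as.matrix(Z)
  if (length(alpha) != nrow(Z)) {
    stop("invalid input: alpha length != instance count", call. = FALSE)
  }
  drop(crossprod(Z, alpha))
}

# Bag-major flattening of the validity mask (n x m -> length n*m, matching
# the row order of batch$X).
mask_flat <- function(mask) as.vector(t(mask))

# Full forward pass over a padded batch.
#
# Returns probabilities, attention weights and pooled features; with
# `keep_cache = TRUE` also every intermediate needed by minn_backward().
# Padded slots carry exactly zero attention weight and zero gradient, so
# the instance encoder runs on the valid (unpadded) rows only — an exact
# optimization, and the reason evaluation output is independent of m*
# beyond the true bag sizes. Dropout masks are likewise drawn only for
# valid rows, in bag-major order, which makes the training RNG stream —
# and hence the whole training trajectory — independent of m* as well.
minn_forward <- function(model, batch, training = FALSE,
                         keep_cache = FALSE) {
  cfg <- model$config
  par <- model$params
  if (!all(is.finite(batch$X))) {
    stop("invalid input: non-finite values in batch features", call. = FALSE)
  }
  n <- batch$n
  m <- batch$m_star
  sizes <- rowSums(batch$mask)
  if (!all(sizes >= 1L)) {
    stop("empty bag: a bag has no valid instance slot", call. = FALSE)
  }
  valid <- which(mask_flat(batch$mask))
  grp <- rep(seq_len(n), sizes)        # bag index of each valid row
  H <- batch$X[valid, , drop = FALSE]
  rate <- cfg$dropout_rate

  block_cache <- if (keep_cache) vector("list", cfg$n_blocks)
  for (l in seq_len(cfg$n_blocks)) {
    W <- par[[paste0("W", l)]]
    b <- par[[paste0("b", l)]]
    Pre <- H %*% t(W)
    Pre <- Pre + rep(b, each = nrow(Pre))
    A <- pmax(Pre, 0)
    Dm <- NULL
    if (training && rate > 0) {
      Dm <- matrix(stats::runif(length(A)) >= rate,
                   nrow(A), ncol(A)) / (1 - rate)
      A <- A * Dm
    }
    Hn <- if (cfg$use_skip) H + A else A
    if (keep_cache) block_cache[[l]] <- list(H_in = H, Pre = Pre, Dm = Dm)
    H <- Hn
  }

  # attention scores
  if (cfg$scorer == "gated_tanh") {
    Tm <- tanh(H %*% t(par$Va))
    e <- drop(Tm %*% par$wa)
  } else {
    Tm <- NULL
    e <- drop(H %*% par$wa) + par$ba
  }

  alpha <- matrix(0, n, m)
  wv <- numeric(length(e))             # attention weight per valid row
  at <- 0L
  for (i in seq_len(n)) {
    rows <- at + seq_len(sizes[i])
    at <- at + sizes[i]
    a <- if (cfg$pooling == "sparsemax") sparsemax(e[rows])
         else masked_softmax(e[rows], rep(TRUE, sizes[i]))
    wv[rows] <- a
    alpha[i, batch$mask[i, ]] <- a
  }

  pooled <- rowsum(H * wv, group = grp, reorder = FALSE)
  dimnames(pooled) <- NULL

  eps <- 1e-5
  if (training) {
    mu <- colMeans(pooled)
    v <- pmax(colMeans(pooled^2) - mu^2, 0)
  } else {
    mu <- model$bn$mean
    v <- model$bn$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (pooled - rep(mu, each = n)) * rep(invstd, each = n)
  bn_out <- xhat * rep(par$gamma, each = n) + rep(par$beta, each = n)

  logit <- unname(drop(bn_out %*% par$u)) + par$c0
  prob <- stats::plogis(logit)

  out <- list(prob = prob, logit = logit, alpha = alpha,
              pooled = pooled, pooled_norm = bn_out,
              batch_mu = if (training) mu, batch_var = if (training) v)
  if (keep_cache) {
    out$cache <- list(H = H, Tm = Tm, e = e, wv = wv, grp = grp,
                      sizes = sizes, xhat = xhat, invstd = invstd,
                      block_cache = block_cache, n = n)
  }
  out
}

# Binary cross-entropy loss and full gradient for one training batch.
# `fw` must come from minn_forward(..., training = TRUE, keep_cache = TRUE).
minn_backward <- function(model, batch, fw, pos_weight = NULL) {
  cfg <- model$config
  par <- model$params
  cc <- fw$cache
  n <- cc$n
  y <- batch$labels
  pr <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  wp <- if (is.null(pos_weight)) 1 else pos_weight
  loss <- -mean(wp * y * log(pr) + (1 - y) * log(1 - pr))

  grads <- list()
  dlogit <- (wp * y * (pr - 1) + (1 - y) * pr) / n

  grads$u <- drop(crossprod(fw$pooled_norm, dlogit))
  grads$c0 <- sum(dlogit)
  dbn <- outer(dlogit, par$u)

  grads$gamma <- colSums(dbn * cc$xhat)
  grads$beta <- colSums(dbn)
  dxhat <- dbn * rep(par$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  dpooled <- (dxhat - rep(s1 / n, each = n) -
              cc$xhat * rep(s2 / n, each = n)) *
             rep(cc$invstd, each = n)

  dpool_exp <- dpooled[cc$grp, , drop = FALSE]
  dalpha_v <- rowSums(cc$H * dpool_exp)
  dZ <- dpool_exp * cc$wv

  de <- numeric(length(dalpha_v))
  at <- 0L
  for (i in seq_len(n)) {
    rows <- at + seq_len(cc$sizes[i])
    at <- at + cc$sizes[i]
    g <- dalpha_v[rows]
    a <- cc$wv[rows]
    if (cfg$pooling == "sparsemax") {
      S <- which(a > 0)
      de[rows[S]] <- g[S] - mean(g[S])
    } else {
      de[rows] <- a * (g - sum(a * g))
    }
  }

  if (cfg$scorer == "gated_tanh") {
    grads$wa <- drop(crossprod(cc$Tm, de))
    dG <- outer(de, par$wa) * (1 - cc$Tm^2)
    grads$Va <- crossprod(dG, cc$H)
    dZ <- dZ + dG %*% par$Va
  } else {
    grads$wa <- drop(crossprod(cc$H, de))
    grads$ba <- sum(de)
    dZ <- dZ + outer(de, par$wa)
  }

  dH <- dZ
  for (l in rev(seq_len(cfg$n_blocks))) {
    bc <- cc$block_cache[[l]]
    dA <- if (is.null(bc$Dm)) dH else dH * bc$Dm
    dPre <- dA * (bc$Pre > 0)
    grads[[paste0("W", l)]] <- crossprod(dPre, bc$H_in)
    grads[[paste0("b", l)]] <- colSums(dPre)
    dH_in <- dPre %*% par[[paste0("W", l)]]
    dH <- if (cfg$use_skip) dH + dH_in else dH_in
  }

  list(loss = loss, grads = grads)
}

#' Predict bag probabilities
#'
#' Evaluation-mode forward pass: dropout off, batch normalization driven by
#' the running statistics accumulated during training, hence deterministic
#' and independent of how bags are grouped into batches, of instance order
#' within a bag, and of padding capacity beyond the true bag sizes.
#'
#' @param object Trained (or initialized) [minn_init()] model.
#' @param newdata List of [bag()] objects or a [pad_bags()] batch.
#' @param type `"response"` for a data frame of probabilities,
#'   `"attention"` for the full attention/pooling detail (see
#'   [bag_attention()]), `"features"` for the batch-normalized pooled
#'   feature matrix.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.minn_model <- function(object, newdata,
                               type = c("response", "attention", "features"),
                               ...) {
  type <- match.arg(type)
  batch <- as_padded_batch(newdata, object$config$m_star)
  fw <- minn_forward(object, batch, training = FALSE)
  switch(type,
    response = data.frame(bag_id = batch$bag_ids,
                          probability = fw$prob,
                          label = batch$labels,
                          stringsAsFactors = FALSE),
    attention = attention_detail(fw, batch),
    features = structure(fw$pooled_norm,
                         dimnames = list(batch$bag_ids, NULL)))
}

as_padded_batch <- function(newdata, m_star) {
  if (inherits(newdata, "padded_batch")) return(newdata)
  if (inherits(newdata, "mil_bag")) newdata <- list(newdata)
  pad_bags(newdata, m_star = m_star)
}

attention_detail <- function(fw, batch) {
  support <- lapply(seq_len(batch$n), function(i) {
    which(fw$alpha[i, ] > 0)
  })
  list(alpha = structure(fw$alpha, dimnames = list(batch$bag_ids, NULL)),
       mask = batch$mask,
       pooled = fw$pooled,
       pooled_norm = fw$pooled_norm,
       support = support,
       bag_ids = batch$bag_ids,
       labels = batch$labels)
}

#' Attention weights, support and pooled features per bag
#'
#' @param model Trained model.
#' @param bags List of bags or padded batch.
#' @return List with `alpha` (`n x m_star`, exact zeros off the attention
#'   support and at padded slots), `mask`, `pooled` (`n x p`),
#'   `pooled_norm`, `support` (list of index vectors), `bag_ids`, `labels`.
#' @export
bag_attention <- function(model, bags) {
  predict(model, bags, type = "attention")
}

#' Extracted bag-level features
#'
#' The batch-normalized pooled feature vector `z_tilde*` of each bag — the
#' input of the final classification layer — in evaluation mode.
#'
#' @param model Trained model.
#' @param bags List of bags or padded batch.
#' @return `n x p` numeric matrix, rownames = bag ids.
#' @export
extract_features <- function(model, bags) {
  predict(model, bags, type = "features")
}
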