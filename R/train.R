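#' Training protocol configuration
#'
#' @param epochs Training epochs (100 by default; the model is selected
#'   among the per-epoch snapshots, not necessarily the last).
#' @param learning_rate Adam step size.
#' @param batch_size Bags per gradient step.
#' @param seed Integer seed controlling initialization, the validation
#'   split, epoch shuffling and dropout. Identical seeds give identical
#'   training trajectories.
#' @param selection `"best_val_auc"`: keep the epoch with the highest AUC
#'   on an internal validation split carved from the training data (never
#'   the test fold); `"last_epoch"`: keep the final weights.
#' @param val_fraction Share of the training bags held out for selection
#'   (ignored under `"last_epoch"`).
#' @param pos_weight Optional loss weight for positive bags (class
#'   imbalance); `NULL` (no reweighting) by default.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L,
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         seed = 1L,
                         selection = c("best_val_auc", "last_epoch"),
                         val_fraction = 0.1,
                         pos_weight = NULL) {
  selection <- match.arg(selection)
  stopifnot(epochs >= 1, learning_rate >= 0, batch_size >= 1,
            val_fraction >= 0, val_fraction < 0.5)
  structure(
    list(epochs = as.integer(epochs),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         seed = as.integer(seed),
         selection = selection,
         val_fraction = val_fraction,
         pos_weight = pos_weight),
    class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stratified index split: held-out validation share per class, >= 1 of each
# class when possible.
split_validation <- function(labels, val_fraction) {
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == 0)
  n_vp <- max(1L, round(length(idx_pos) * val_fraction))
  n_vn <- max(1L, round(length(idx_neg) * val_fraction))
  if (length(idx_pos) <= n_vp || length(idx_neg) <= n_vn) {
    stop("degenerate data: too few bags per class for a validation split",
         call. = FALSE)
  }
  val <- c(sample(idx_pos, n_vp), sample(idx_neg, n_vn))
  sort(val)
}

#' Train the sparse-attention MIL network
#'
#' Minimizes binary cross-entropy between the sigmoid bag probabilities and
#' the bag labels with Adam, for `train_config$epochs` epochs of shuffled
#' mini-batches, and returns the weights of the selected epoch (best
#' internal-validation AUC by default). The whole trajectory is a
#' deterministic function of `train_config$seed`.
#'
#' @param bags Training bags (both classes must be present).
#' @param model_config [minn_config()]; a `NULL` `m_star` is resolved to
#'   the largest training-bag size.
#' @param tc [train_config()].
#' @return A `"minn_model"` whose `history` is a data frame with one row
#'   per epoch (`epoch`, `loss`, `val_auc`) plus attributes
#'   `selected_epoch` and `selection`.
#' @export
train_minn <- function(bags, model_config, tc = train_config()) {
  check_bag_list(bags)
  labels <- bag_labels(bags)
  if (length(unique(labels)) < 2L) {
    stop("degenerate data: training set contains a single class",
         call. = FALSE)
  }
  set.seed(tc$seed)
  cfg <- model_config
  if (is.null(cfg$m_star)) {
    cfg$m_star <- max(vapply(bags, bag_size, integer(1)))
  }

  use_val <- tc$selection == "best_val_auc" && tc$val_fraction > 0
  if (use_val) {
    val_idx <- split_validation(labels, tc$val_fraction)
    val_batch <- pad_bags(bags[val_idx], m_star = cfg$m_star)
    fit_idx <- setdiff(seq_along(bags), val_idx)
    if (length(unique(labels[fit_idx])) < 2L) {
      stop("degenerate data: single class left after validation split",
           call. = FALSE)
    }
  } else {
    val_batch <- NULL
    fit_idx <- seq_along(bags)
  }
  fit_batch <- pad_bags(bags[fit_idx], m_star = cfg$m_star)

  model <- minn_init(cfg)
  opt <- adam_init(model$params)
  n_fit <- fit_batch$n
  momentum <- 0.1

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))
  best <- list(metric = -Inf, params = model$params, bn = model$bn,
               epoch = 0L)

  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n_fit)
    starts <- seq(1L, n_fit, by = tc$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      take <- ord[s:min(s + tc$batch_size - 1L, n_fit)]
      sub <- subset_batch(fit_batch, take)
      fw <- minn_forward(model, sub, training = TRUE, keep_cache = TRUE)
      bw <- minn_backward(model, sub, fw, pos_weight = tc$pos_weight)
      model$bn$mean <- (1 - momentum) * model$bn$mean +
        momentum * fw$batch_mu
      model$bn$var <- (1 - momentum) * model$bn$var +
        momentum * fw$batch_var
      upd <- adam_step(model$params, bw$grads, opt, tc$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + bw$loss * length(take)
    }
    epoch_loss <- epoch_loss / n_fit
    val_auc <- if (use_val) {
      fw_val <- minn_forward(model, val_batch, training = FALSE)
      auc_score(fw_val$prob, val_batch$labels)
    } else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss,
                                val_auc = val_auc))
    metric <- if (use_val) val_auc else -epoch_loss
    if (metric > best$metric) {
      best <- list(metric = metric, params = model$params,
                   bn = model$bn, epoch = epoch)
    }
  }

  if (tc$selection == "best_val_auc" && use_val) {
    model$params <- best$params
    model$bn <- best$bn
    selected <- best$epoch
  } else {
    selected <- tc$epochs
  }
  attr(history, "selected_epoch") <- selected
  attr(history, "selection") <- tc$selection
  model$history <- history
  model
}

subset_batch <- function(batch, idx) {
  m <- batch$m_star
  rows <- as.vector(vapply(idx, function(i) (i - 1L) * m + seq_len(m),
                           integer(m)))
  structure(
    list(X = batch$X[rows, , drop = FALSE],
         mask = batch$mask[idx, , drop = FALSE],
         labels = batch$labels[idx],
         bag_ids = batch$bag_ids[idx],
         m_star = m, p = batch$p, n = length(idx)),
    class = "padded_batch")
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic
#' `P(score+ > score-) + P(tie)/2` via midranks, the standard tie
#' convention.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold split
#'
#' Partitions `n` bags into `k` disjoint folds whose sizes differ by at
#' most one; with `stratified = TRUE` the positive bags are dealt
#' round-robin so each fold's class fraction matches the overall fraction
#' to within one bag.
#'
#' @param labels 0/1 label vector (one per bag).
#' @param k Number of folds.
#' @param stratified Preserve class fractions per fold?
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("too few bags for ", k, " folds", call. = FALSE)
  set.seed(seed)
  if (!stratified) {
    fold_of <- sample(rep(seq_len(k), length.out = n))
    return(split(seq_len(n), fold_of))
  }
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n1 < k || n0 < k) {
    stop("stratification error: need at least ", k,
         " bags of each class", call. = FALSE)
  }
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  pos_per_fold <- rep(n1 %/% k, k)
  extra <- n1 %% k
  if (extra > 0L) {
    pos_per_fold[sample.int(k, extra)] <- pos_per_fold[1L] + 1L
  }
  pos <- sample(which(labels == 1))
  neg <- sample(which(labels == 0))
  folds <- vector("list", k)
  p_at <- 1L
  n_at <- 1L
  for (f in seq_len(k)) {
    np <- pos_per_fold[f]
    nn <- sizes[f] - np
    folds[[f]] <- sort(c(pos[seq.int(p_at, length.out = np)],
                         neg[seq.int(n_at, length.out = nn)]))
    p_at <- p_at + np
    n_at <- n_at + nn
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' For each fold: trains on the remaining bags (with the model-selection
#' validation split carved from those training bags only), scores the
#' held-out fold in evaluation mode, and records its AUC. Test bags never
#' influence training, batch-norm statistics or model selection. Fold `f`
#' is trained with seed `tc$seed * 1000 + f`, so each fold's cycle is
#' reproducible standalone from its training bags alone.
#'
#' @param bags List of bags.
#' @param model_config [minn_config()].
#' @param tc [train_config()].
#' @param k Number of folds.
#' @param folds Optional pre-computed fold index list (e.g. to share folds
#'   across ablation variants); defaults to
#'   `kfold_split(labels, k, seed = tc$seed)`.
#' @return Object of class `"minn_cv"`: list with `fold_aucs`, `mean_auc`,
#'   `sd_auc`, `predictions` (data frame `bag_id`, `fold`, `probability`,
#'   `label`) and `folds`.
#' @export
cross_validate <- function(bags, model_config, tc = train_config(),
                           k = 10L, folds = NULL) {
  check_bag_list(bags)
  labels <- bag_labels(bags)
  if (is.null(folds)) {
    folds <- kfold_split(labels, k = k, stratified = TRUE, seed = tc$seed)
  }
  k <- length(folds)
  preds <- vector("list", k)
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(bags), test_idx)
    tc_f <- tc
    tc_f$seed <- tc$seed * 1000L + f
    model <- train_minn(bags[train_idx], model_config, tc_f)
    pr <- predict(model, bags[test_idx])
    pr$fold <- f
    preds[[f]] <- pr
    fold_aucs[f] <- auc_score(pr$probability, pr$label)
  }
  predictions <- do.call(rbind, preds)
  structure(
    list(fold_aucs = fold_aucs,
         mean_auc = mean(fold_aucs),
         sd_auc = stats::sd(fold_aucs),
         predictions = predictions[, c("bag_id", "fold", "probability",
                                       "label")],
         folds = folds),
    class = "minn_cv")
}

#' @export
print.minn_cv <- function(x, ...) {
  cat(sprintf("<minn_cv> %d folds: mean AUC %.4f (sd %.4f)\n",
              length(x$fold_aucs), x$mean_auc, x$sd_auc))
  invisible(x)
}
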