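#' Ablation over the skip-connection and sparse-pooling switches
#'
#' Cross-validates the four model variants — `FC` (no skip, softmax),
#' `Skip` (skip, softmax), `Sparse` (no skip, sparsemax), `Proposed`
#' (skip, sparsemax) — with identical folds and seeds, so the rows differ
#' only in the two architecture switches.
#'
#' @param bags Dataset.
#' @param base_config [minn_config()] supplying everything except the two
#'   switches.
#' @param tc [train_config()].
#' @param k Folds.
#' @param folds Optional shared fold list; computed once here otherwise.
#' @return Data frame with columns `variant`, `skip_on`, `sparse_on`,
#'   `mean_auc`, `sd_auc`; attribute `"cv"` holds the four
#'   [cross_validate()] results.
#' @export
run_ablation <- function(bags, base_config, tc = train_config(),
                         k = 10L, folds = NULL) {
  if (is.null(folds)) {
    folds <- kfold_split(bag_labels(bags), k = k, stratified = TRUE,
                         seed = tc$seed)
  }
  variants <- c("FC", "Skip", "Sparse", "Proposed")
  cvs <- lapply(variants, function(v) {
    cross_validate(bags, variant_config(base_config, v), tc, folds = folds)
  })
  names(cvs) <- variants
  out <- data.frame(
    variant = variants,
    skip_on = variants %in% c("Skip", "Proposed"),
    sparse_on = variants %in% c("Sparse", "Proposed"),
    mean_auc = vapply(cvs, function(x) x$mean_auc, numeric(1)),
    sd_auc = vapply(cvs, function(x) x$sd_auc, numeric(1)),
    row.names = NULL)
  attr(out, "cv") <- cvs
  out
}

#' Sensitivity of CV performance to the bag capacity m*
#'
#' Re-runs cross-validation over a grid of padding/truncation capacities
#' with identical folds and seeds. When every bag is no larger than the
#' smallest grid value, padding invariance makes all rows identical.
#'
#' @param bags Dataset.
#' @param grid Integer vector of capacities (e.g. `c(30, 60, 90, 120, 150)`).
#' @param model_config Base configuration; its `m_star` is overridden.
#' @param tc [train_config()].
#' @param k Folds.
#' @param folds Optional shared fold list.
#' @return Data frame `m_star`, `mean_auc`, `sd_auc`.
#' @export
mstar_sensitivity <- function(bags, grid, model_config,
                              tc = train_config(), k = 10L, folds = NULL) {
  stopifnot(all(grid >= 1))
  if (is.null(folds)) {
    folds <- kfold_split(bag_labels(bags), k = k, stratified = TRUE,
                         seed = tc$seed)
  }
  rows <- lapply(grid, function(ms) {
    cfg <- model_config
    cfg$m_star <- as.integer(ms)
    cv <- cross_validate(bags, cfg, tc, folds = folds)
    data.frame(m_star = ms, mean_auc = cv$mean_auc, sd_auc = cv$sd_auc)
  })
  do.call(rbind, rows)
}

#' Attention-weight heatmap matrix
#'
#' One row per bag holding its attention weights over the `m_star` instance
#' slots, rows ordered by bag size; padded cells are reported in a parallel
#' mask matrix so renderers can gray them out rather than confuse them with
#' exact-zero attention. Every row sums to 1 over its valid cells.
#'
#' @param model Trained model.
#' @param bags Dataset.
#' @return List with `weights` (`n x m_star`), `mask` (`n x m_star`
#'   logical, `TRUE` = real instance), `bag_ids`, `labels`, `order`
#'   (permutation of the input bags applied to the rows).
#' @export
attention_heatmap <- function(model, bags) {
  att <- bag_attention(model, bags)
  sizes <- rowSums(att$mask)
  ord <- order(sizes)
  list(weights = att$alpha[ord, , drop = FALSE],
       mask = att$mask[ord, , drop = FALSE],
       bag_ids = att$bag_ids[ord],
       labels = att$labels[ord],
       order = ord)
}

#' Extracted-feature heatmap matrix
#'
#' The `n x p` matrix of batch-normalized pooled features, column-wise
#' min-max normalized to \[0, 1\] and then `log1p`-transformed (so entries
#' lie in \[0, log 2\]). A constant column carries no contrast and is set
#' to zero with a warning. Normalization parameters are attached as
#' attributes `"col_min"` and `"col_max"`.
#'
#' @param model Trained model.
#' @param bags Dataset.
#' @return `n x p` matrix.
#' @export
feature_heatmap <- function(model, bags) {
  Z <- extract_features(model, bags)
  lo <- apply(Z, 2, min)
  hi <- apply(Z, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) set to 0")
    rng[const] <- 1
  }
  out <- log1p(sweep(sweep(Z, 2, lo), 2, rng, "/"))
  out[, const] <- 0
  attr(out, "col_min") <- lo
  attr(out, "col_max") <- hi
  out
}

#' Label the primary instances of a bag by attention support
#'
#' Under sparsemax pooling the attention support — the instances with
#' strictly positive weight — is the model's hard selection of the
#' instances explaining the bag label. Softmax pooling has no exact zeros
#' and therefore no support in this sense.
#'
#' @param model Trained sparsemax-pooling model.
#' @param b A single [bag()].
#' @return Logical vector of length `min(m_i, m_star)` (instances beyond
#'   the truncation capacity are never seen by the model): `TRUE` where
#'   attention weight is `> 0`.
#' @export
label_primary_instances <- function(model, b) {
  if (model$config$pooling != "sparsemax") {
    stop("unsupported pooling: instance selection requires sparsemax ",
         "(softmax attention has no exact zeros)", call. = FALSE)
  }
  att <- bag_attention(model, list(b))
  keep <- min(bag_size(b), model$config$m_star %||% bag_size(b))
  unname(att$alpha[1, seq_len(keep)] > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recall of ground-truth primary instances
#'
#' Fraction of true primary instances (within the truncation capacity) of
#' positive bags that the sparsemax attention support recovers, averaged
#' over instances.
#'
#' @param model Trained sparsemax model.
#' @param bags Synthetic bags carrying `primary_flags`.
#' @return Scalar recall in \[0, 1\].
#' @export
selection_recall <- function(model, bags) {
  check_bag_list(bags)
  hits <- 0L
  total <- 0L
  for (b in bags) {
    if (b$label != 1L || is.null(b$primary_flags)) next
    sel <- label_primary_instances(model, b)
    truth <- b$primary_flags[seq_along(sel)]
    hits <- hits + sum(sel & truth)
    total <- total + sum(truth)
  }
  if (total == 0L) stop("no primary instances among positive bags",
                        call. = FALSE)
  hits / total
}

#' Mean distance of instances to a reference embedding set
#'
#' For each instance embedding, the mean Euclidean distance to all rows of
#' `reference_embeddings` (e.g. embeddings of virus-specific TCRs), then
#' summarized by the four groups (bag label) x (primary / non-primary) and
#' compared within each label by a two-sided Wilcoxon rank-sum test of
#' primary vs non-primary distances. Groups with no members are skipped
#' with a warning.
#'
#' @param instance_embeddings `n x d` matrix, one row per instance.
#' @param primary_flags Logical vector of length `n` (model- or
#'   ground-truth-derived primary labels).
#' @param labels 0/1 vector of length `n`: the label of each instance's bag.
#' @param reference_embeddings `r x d` matrix.
#' @return List with `distances` (per-instance mean distance), `table`
#'   (data frame `label`, `primary`, `n`, `mean_distance`) and `tests`
#'   (data frame `label`, `p_value`).
#' @export
reference_distance_report <- function(instance_embeddings, primary_flags,
                                      labels, reference_embeddings) {
  X <- as.matrix(instance_embeddings)
  R <- as.matrix(reference_embeddings)
  if (ncol(X) != ncol(R)) {
    stop("invalid input: instance and reference embeddings differ in ",
         "dimension", call. = FALSE)
  }
  stopifnot(length(primary_flags) == nrow(X), length(labels) == nrow(X))
  d2 <- outer(rowSums(X^2), rep(1, nrow(R))) +
    outer(rep(1, nrow(X)), rowSums(R^2)) - 2 * X %*% t(R)
  dist_mean <- rowMeans(sqrt(pmax(d2, 0)))

  grid <- expand.grid(label = c(0, 1), primary = c(TRUE, FALSE))
  tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- labels == grid$label[i] & primary_flags == grid$primary[i]
    data.frame(label = grid$label[i], primary = grid$primary[i],
               n = sum(sel),
               mean_distance = if (any(sel)) mean(dist_mean[sel])
                               else NA_real_)
  }))

  tests <- do.call(rbind, lapply(c(0, 1), function(lb) {
    a <- dist_mean[labels == lb & primary_flags]
    b <- dist_mean[labels == lb & !primary_flags]
    if (length(a) == 0L || length(b) == 0L) {
      warning("empty primary or non-primary group for label ", lb,
              "; test skipped")
      return(data.frame(label = lb, p_value = NA_real_))
    }
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    data.frame(label = lb, p_value = p)
  }))

  list(distances = dist_mean, table = tab, tests = tests)
}
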