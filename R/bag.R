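#' Construct a bag of instances
#'
#' A bag is one observational unit — in the repertoire setting, one tissue
#' sample — carrying a single binary label and a variable-size set of
#' instance feature vectors (rows of `instances`), e.g. fixed-length numeric
#' embeddings of the TCR sequences observed in that sample.
#'
#' @param instances Numeric matrix, `m_i x p`: one row per instance.
#' @param label Bag label, 0 (negative/normal) or 1 (positive/tumor).
#' @param bag_id Identifier string.
#' @param instance_ids Optional character vector of length `m_i`
#'   (e.g. CDR3 amino-acid sequences).
#' @param primary_flags Optional logical vector of length `m_i`: ground-truth
#'   markers of the signal-carrying (primary) instances. Available for
#'   synthetic data only; a negative bag must have no flagged instance.
#' @return An object of class `"mil_bag"`.
#' @export
bag <- function(instances, label, bag_id = NULL, instance_ids = NULL,
                primary_flags = NULL) {
  instances <- as.matrix(instances)
  storage.mode(instances) <- "double"
  dimnames(instances) <- NULL
  if (nrow(instances) < 1L) {
    stop("invalid bag: needs at least one instance", call. = FALSE)
  }
  if (!all(is.finite(instances))) {
    stop("invalid bag: instance features must be finite", call. = FALSE)
  }
  if (!(length(label) == 1L && label %in% c(0, 1))) {
    stop("invalid bag: label must be 0 or 1", call. = FALSE)
  }
  m <- nrow(instances)
  if (!is.null(instance_ids) && length(instance_ids) != m) {
    stop("invalid bag: instance_ids length != instance count", call. = FALSE)
  }
  if (!is.null(primary_flags)) {
    primary_flags <- as.logical(primary_flags)
    if (length(primary_flags) != m) {
      stop("invalid bag: primary_flags length != instance count",
           call. = FALSE)
    }
    if (label == 0 && any(primary_flags)) {
      stop("invalid bag: negative bag cannot contain primary instances",
           call. = FALSE)
    }
  }
  structure(
    list(bag_id = if (is.null(bag_id)) NA_character_ else as.character(bag_id),
         label = as.integer(label),
         instances = instances,
         instance_ids = instance_ids,
         primary_flags = primary_flags),
    class = "mil_bag")
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag %s> label=%d, %d instance(s) x %d feature(s)\n",
              x$bag_id, x$label, nrow(x$instances), ncol(x$instances)))
  invisible(x)
}

bag_size <- function(b) nrow(b$instances)

bag_labels <- function(bags) vapply(bags, function(b) b$label, integer(1))

check_bag_list <- function(bags) {
  if (length(bags) == 0L) stop("empty bag list", call. = FALSE)
  if (!all(vapply(bags, inherits, logical(1), "mil_bag"))) {
    stop("`bags` must be a list of mil_bag objects", call. = FALSE)
  }
  p <- unique(vapply(bags, function(b) ncol(b$instances), integer(1)))
  if (length(p) != 1L) {
    stop("inconsistent feature dimension across bags: ",
         paste(p, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Pad or truncate one bag to a fixed instance capacity
#'
#' Bags hold variable numbers of instances but the network consumes a fixed
#' `m_star x p` block per bag. A bag with fewer than `m_star` instances has
#' the empty slots padded with zeros and marked invalid in the mask; a bag
#' with more keeps exactly its first `m_star` instances in their original
#' order. Surviving instance values are never altered, and the operation is
#' idempotent at fixed `m_star`.
#'
#' @param b A [bag()].
#' @param m_star Integer capacity, >= 1.
#' @return List with `features` (`m_star x p` matrix) and `mask` (logical
#'   vector of length `m_star`, `TRUE` for real instances).
#' @export
pad_truncate <- function(b, m_star) {
  stopifnot(inherits(b, "mil_bag"), m_star >= 1)
  p <- ncol(b$instances)
  m <- nrow(b$instances)
  keep <- min(m, m_star)
  features <- matrix(0, nrow = m_star, ncol = p)
  features[seq_len(keep), ] <- b$instances[seq_len(keep), , drop = FALSE]
  mask <- c(rep(TRUE, keep), rep(FALSE, m_star - keep))
  list(features = features, mask = mask)
}

#' Tensorize a list of bags into a fixed-capacity padded batch
#'
#' Stacks [pad_truncate()] over bags. The instance features are stored as a
#' single `(n * m_star) x p` matrix in bag-major row order (all slots of bag
#' 1, then bag 2, ...), alongside an `n x m_star` validity mask. Zero-padded
#' slots are all-zero on construction and every bag retains at least one
#' valid slot.
#'
#' @param bags List of [bag()] objects.
#' @param m_star Capacity; default is the largest bag size in `bags`.
#' @return Object of class `"padded_batch"`: list with `X`
#'   (`(n*m_star) x p`), `mask` (`n x m_star` logical), `labels`, `bag_ids`,
#'   `m_star`, `p`, `n`.
#' @export
pad_bags <- function(bags, m_star = NULL) {
  p <- check_bag_list(bags)
  sizes <- vapply(bags, bag_size, integer(1))
  if (is.null(m_star)) m_star <- max(sizes)
  m_star <- as.integer(m_star)
  n <- length(bags)
  X <- matrix(0, nrow = n * m_star, ncol = p)
  mask <- matrix(FALSE, nrow = n, ncol = m_star)
  for (i in seq_len(n)) {
    pt <- pad_truncate(bags[[i]], m_star)
    X[(i - 1L) * m_star + seq_len(m_star), ] <- pt$features
    mask[i, ] <- pt$mask
  }
  structure(
    list(X = X, mask = mask, labels = bag_labels(bags),
         bag_ids = vapply(bags, function(b) b$bag_id, character(1)),
         m_star = m_star, p = p, n = n),
    class = "padded_batch")
}

# Row indices of bag i inside the bag-major feature matrix of a batch.
batch_rows <- function(batch, i) {
  (i - 1L) * batch$m_star + seq_len(batch$m_star)
}
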