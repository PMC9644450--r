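#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Maps a real score vector `z` of length `K` to the point of the
#' `(K-1)`-simplex closest to it in Euclidean distance,
#' \deqn{\mathrm{sparsemax}(z) = \arg\min_{p \in \Delta^{K-1}} \|p - z\|^2.}
#' Unlike softmax, the projection can (and typically does) land on a face of
#' the simplex, so scores below an adaptively determined threshold receive
#' weight exactly zero. In attention pooling this yields a hard selection of
#' the instances that carry the bag signal.
#'
#' The result is invariant under adding a constant to all entries of `z`,
#' and a vector already on the simplex projects to itself.
#'
#' @param z Numeric vector of scores (finite, length >= 1).
#' @return Numeric vector on the simplex: entries >= 0, summing to 1.
#' @seealso [sparsemax_threshold()] for the threshold and support,
#'   [masked_sparsemax()] for padded inputs, [sparsemax_jvp()] for the
#'   Jacobian-vector product used in backpropagation.
#' @examples
#' sparsemax(c(0, 0, 0))      # uniform
#' sparsemax(c(10, 0, 0))     # vertex: gap exceeds 1
#' sparsemax(c(0.6, 0.2))     # c(0.7, 0.3)
#' @export
sparsemax <- function(z) {
  sparsemax_threshold(z)$weights
}

#' Sparsemax with threshold and support set
#'
#' Computes the simplex projection together with the adaptive threshold
#' `tau` satisfying `sum(pmax(z - tau, 0)) == 1` and the support set
#' `{j : z[j] > tau}`. Uses the exact sort-and-scan algorithm
#' (descending sort, cumulative sums, largest k with `1 + k * z_(k) >`
#' cumulative sum), O(K log K). Entries tied with `tau` exactly get weight
#' zero and are excluded from the support.
#'
#' @inheritParams sparsemax
#' @return A list with components `weights` (simplex vector), `tau`
#'   (numeric scalar), and `support` (integer indices with positive weight).
#' @export
sparsemax_threshold <- function(z) {
  z <- check_scores(z)
  zs <- sort(z, decreasing = TRUE)
  k <- seq_along(zs)
  css <- cumsum(zs)
  supp_size <- max(which(1 + k * zs > css))
  tau <- (css[supp_size] - 1) / supp_size
  w <- pmax(z - tau, 0)
  support <- which(z > tau)
  # support found by strict comparison can only shrink by exact float ties;
  # renormalisation is unnecessary because tau comes from the same arithmetic
  list(weights = w, tau = tau, support = support)
}

#' Jacobian-vector product of sparsemax
#'
#' Applies the (sub)gradient Jacobian of [sparsemax()] at `z` to a vector
#' `v`: on the support `S` of the projection, `(Jv)[j] = v[j] - mean(v[S])`;
#' off the support the product is zero. This is the backward rule used to
#' train attention networks through the projection.
#'
#' @inheritParams sparsemax
#' @param v Numeric vector, same length as `z`.
#' @return Numeric vector `J(z) %*% v`.
#' @export
sparsemax_jvp <- function(z, v) {
  v <- as.numeric(v)
  if (length(v) != length(z)) {
    stop("invalid input: `v` must have the same length as `z` (",
         length(z), " vs ", length(v), ")", call. = FALSE)
  }
  s <- sparsemax_threshold(z)$support
  out <- numeric(length(z))
  out[s] <- v[s] - mean(v[s])
  out
}

#' Sparsemax restricted to unmasked entries
#'
#' Projects the subvector of `z` at positions where `mask` is `TRUE` onto
#' the simplex and scatters the result back, leaving exact zeros at masked
#' positions. Padded instance slots of a bag are masked this way so their
#' (arbitrary) scores can never receive attention. Implemented by projecting
#' the subvector rather than by setting masked scores to `-Inf`, which is
#' equivalent but avoids non-finite arithmetic.
#'
#' @inheritParams sparsemax
#' @param mask Logical vector, same length as `z`; at least one `TRUE`.
#' @return Simplex vector of `length(z)` with zeros wherever `mask` is FALSE.
#' @export
masked_sparsemax <- function(z, mask) {
  mask <- as.logical(mask)
  if (length(mask) != length(z)) {
    stop("invalid input: `mask` must match `z` in length", call. = FALSE)
  }
  if (!any(mask)) {
    stop("empty bag: mask has no TRUE entry", call. = FALSE)
  }
  out <- numeric(length(z))
  out[mask] <- sparsemax(z[mask])
  out
}

#' Brute-force simplex projection oracle
#'
#' Independent reference for [sparsemax()]: solves the projection QP by
#' enumerating all `2^K - 1` candidate support sets and checking the
#' Karush-Kuhn-Tucker conditions (primal feasibility on the support, dual
#' feasibility off it). Exponential in `K`, so refused for `K > 12`.
#' Intended for testing only.
#'
#' @inheritParams sparsemax
#' @return Simplex vector, the unique KKT point.
#' @export
simplex_project_oracle <- function(z) {
  z <- check_scores(z)
  K <- length(z)
  if (K > 12L) {
    stop("refusing K > 12: support enumeration is exponential", call. = FALSE)
  }
  best <- NULL
  for (code in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(K) - 1L)) != 0L)
    tau <- (sum(z[S]) - 1) / length(S)
    p <- numeric(K)
    p[S] <- z[S] - tau
    primal_ok <- all(p[S] > -1e-12)
    dual_ok <- length(S) == K || all(z[-S] - tau <= 1e-12)
    if (primal_ok && dual_ok) {
      best <- pmax(p, 0)
      break
    }
  }
  if (is.null(best)) stop("KKT enumeration failed (numerical degeneracy)")
  best
}

check_scores <- function(z) {
  z <- as.numeric(z)
  if (length(z) == 0L) stop("invalid input: empty score vector", call. = FALSE)
  if (!all(is.finite(z))) {
    stop("invalid input: scores must be finite", call. = FALSE)
  }
  z
}

# Softmax restricted to unmasked entries; the dense baseline pooling.
masked_softmax <- function(z, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty bag: mask has no TRUE entry", call. = FALSE)
  out <- numeric(length(z))
  zs <- z[mask]
  e <- exp(zs - max(zs))
  out[mask] <- e / sum(e)
  out
}
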