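#' Specify a synthetic multiple-instance dataset
#'
#' Describes a generator that emulates the primary-instance structure of
#' repertoire classification data: every positive bag hides at least one
#' signal-carrying ("primary") instance among irrelevant background
#' instances, while negative bags contain background only. Bag sizes follow
#' a heavy-tailed law — by default a shifted negative binomial
#' `1 + NB(size = 0.22, mu = 5.5)` capped at 150, under which roughly three
#' quarters of bags have five or fewer instances — mimicking the skewed
#' clone-count distribution of tumor-infiltrating TCR repertoires.
#'
#' @param n_bags Number of bags to generate.
#' @param positive_fraction Fraction of positive (tumor) bags: 0.5 for the
#'   balanced design, 0.1 for the screening-style imbalanced design.
#' @param p Feature dimension per instance (30, matching fixed-length TCR
#'   embeddings).
#' @param bag_size_law List `(size, mu, min, max)` for the shifted negative
#'   binomial instance-count law.
#' @param primary_count_law List `(lambda, min)`: positive bags draw
#'   `min + Poisson(lambda)` primary instances (capped at the bag size).
#' @param signal_shift Mean shift applied to primary instances: scalar
#'   (broadcast over all `p` features) or length-`p` vector. The default 1
#'   with `noise_sd = 1` puts primaries about `sqrt(p)` background standard
#'   deviations from the background mean — a strongly separable signal.
#'   Set to 0 for a null dataset with identically distributed classes.
#' @param noise_sd Standard deviation of the isotropic Gaussian features.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_bags = 400,
                           positive_fraction = 0.5,
                           p = 30,
                           bag_size_law = list(size = 0.22, mu = 5.5,
                                               min = 1, max = 150),
                           primary_count_law = list(lambda = 1, min = 1),
                           signal_shift = 1,
                           noise_sd = 1,
                           seed = 1L) {
  stopifnot(n_bags >= 1, positive_fraction > 0, positive_fraction < 1,
            p >= 1, noise_sd > 0)
  if (round(n_bags * positive_fraction) < 1) {
    stop("invalid spec: positive_fraction * n_bags < 1", call. = FALSE)
  }
  if (!(length(signal_shift) %in% c(1L, p))) {
    stop("invalid spec: signal_shift must be scalar or length p",
         call. = FALSE)
  }
  structure(
    list(n_bags = as.integer(n_bags),
         positive_fraction = positive_fraction,
         p = as.integer(p),
         bag_size_law = bag_size_law,
         primary_count_law = primary_count_law,
         signal_shift = signal_shift,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

draw_bag_sizes <- function(law, n) {
  m <- law$min + stats::rnbinom(n, size = law$size, mu = law$mu)
  pmin(m, law$max)
}

# Theoretical pmf of the bag-size law on min..max (mass at max lumps the
# tail), for goodness-of-fit checking.
bag_size_pmf <- function(law) {
  sizes <- law$min:law$max
  x <- sizes - law$min
  pr <- stats::dnbinom(x, size = law$size, mu = law$mu)
  pr[length(pr)] <- 1 - stats::pnbinom(x[length(x)] - 1,
                                       size = law$size, mu = law$mu)
  data.frame(size = sizes, prob = pr)
}

#' Generate synthetic bags under the primary-instance assumption
#'
#' Background instances are drawn from `N(0, noise_sd^2 I)` in `R^p`;
#' primary instances from `N(signal_shift, noise_sd^2 I)`. Each positive bag
#' receives `primary_count >= 1` primaries placed at random positions among
#' its background instances; negative bags are pure background. The exact
#' positive-bag count is `round(n_bags * positive_fraction)` and labels are
#' shuffled across bag positions. Ground truth is recorded in each bag's
#' `primary_flags`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [bag()] objects with `primary_flags` set.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_bags
  p <- spec$p
  shift <- rep(spec$signal_shift, length.out = p)
  n_pos <- round(n * spec$positive_fraction)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  sizes <- draw_bag_sizes(spec$bag_size_law, n)
  lapply(seq_len(n), function(i) {
    m <- sizes[i]
    feat <- matrix(stats::rnorm(m * p, sd = spec$noise_sd),
                   nrow = m, ncol = p)
    flags <- rep(FALSE, m)
    if (labels[i] == 1L) {
      k <- min(m, spec$primary_count_law$min +
                 stats::rpois(1, spec$primary_count_law$lambda))
      at <- sample.int(m, k)
      feat[at, ] <- feat[at, , drop = FALSE] +
        matrix(shift, nrow = k, ncol = p, byrow = TRUE)
      flags[at] <- TRUE
    }
    bag(instances = feat, label = labels[i],
        bag_id = sprintf("bag_%04d", i),
        primary_flags = flags)
  })
}

#' Write the ground-truth primary flags of synthetic bags
#'
#' Companion file to [write_bags()] for generated data: one row per
#' instance with `bag_id`, `instance` (1-based position) and `primary`
#' (0/1 ground truth).
#'
#' @param bags Synthetic bags carrying `primary_flags`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(bags, path) {
  check_bag_list(bags)
  rows <- lapply(bags, function(b) {
    if (is.null(b$primary_flags)) {
      stop("bag ", b$bag_id, " has no primary_flags", call. = FALSE)
    }
    data.frame(bag_id = b$bag_id,
               instance = seq_len(bag_size(b)),
               primary = as.integer(b$primary_flags))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
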