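# Synthetic classification datasets with controllable error geometry.
# Boundary-overlap data concentrate mistakes on the same ambiguous samples
# near the class midplane (high consistency); label-noise data attach
# mistakes to randomly flipped labels. Isotropic unit-variance Gaussian
# classes give a closed-form Bayes accuracy to anchor tests analytically.

#' Specify a synthetic dataset
#'
#' @param n_samples number of samples (>= 20).
#' @param n_features number of features (>= 1).
#' @param class_balance proportion of samples in the positive class, in
#'   (0, 1).
#' @param class_separation Euclidean distance between the two class centroids
#'   in feature units (class variance is isotropic and 1).
#' @param label_noise_rate fraction of labels flipped after generation, in
#'   \[0, 1\].
#' @param seed integer seed; generation is a deterministic function of the
#'   spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_features = 2L, class_balance = 0.5,
                           class_separation = 2, label_noise_rate = 0,
                           seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  if (is.na(n_samples) || n_samples < 20)
    stop_invalid("n_samples must be at least 20")
  if (is.na(n_features) || n_features < 1)
    stop_invalid("n_features must be at least 1")
  if (class_balance <= 0 || class_balance >= 1)
    stop_invalid("class_balance must lie strictly between 0 and 1")
  if (class_separation < 0) stop_invalid("class_separation must be non-negative")
  if (label_noise_rate < 0 || label_noise_rate > 1)
    stop_invalid("label_noise_rate must lie in [0, 1]")
  structure(list(n_samples = n_samples, n_features = n_features,
                 class_balance = class_balance,
                 class_separation = class_separation,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Two isotropic unit-variance Gaussian classes separated along the first
# feature axis; centroids at -sep/2 and +sep/2.
gaussian_pair <- function(spec) {
  n1 <- round(spec$class_balance * spec$n_samples)
  n0 <- spec$n_samples - n1
  if (n0 < 1 || n1 < 1) stop_invalid("class_balance leaves a class empty")
  f <- spec$n_features
  X <- matrix(stats::rnorm(spec$n_samples * f), spec$n_samples, f)
  half <- spec$class_separation / 2
  X[seq_len(n0), 1] <- X[seq_len(n0), 1] - half
  X[n0 + seq_len(n1), 1] <- X[n0 + seq_len(n1), 1] + half
  labels <- factor(rep(c("neg", "pos"), c(n0, n1)), levels = c("neg", "pos"))
  list(X = X, labels = labels)
}

#' Generate a boundary-overlap dataset
#'
#' Two isotropic unit-variance Gaussian classes whose centroids sit
#' `class_separation` apart along the first feature axis. Samples near the
#' midplane are intrinsically ambiguous, so a well-trained classifier's
#' errors concentrate on the same ids across repetitions — the
#' high-consistency regime. The Bayes-optimal accuracy is available in
#' closed form via [boundary_bayes_accuracy()].
#'
#' @param spec a [synthetic_spec()] with `label_noise_rate = 0`.
#' @return an [ec_dataset()]; the spec is attached as attribute
#'   `"synthetic_spec"`.
#' @export
generate_boundary_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$label_noise_rate != 0)
    stop_invalid("boundary datasets require label_noise_rate = 0; use generate_label_noise_dataset")
  set.seed(spec$seed)
  g <- gaussian_pair(spec)
  ds <- ec_dataset(g$X, g$labels)
  attr(ds, "synthetic_spec") <- spec
  ds
}

#' Generate a label-noise dataset
#'
#' Starts from the same two-Gaussian geometry and then flips exactly
#' `round(label_noise_rate * n_samples)` labels, chosen uniformly at random.
#' A model that fits the underlying structure keeps erring on the flipped
#' samples, while the noise injects training-set randomness that lowers
#' consistency. The flipped ids are recorded as ground-truth metadata
#' (attribute `"flipped_ids"`), never shown to classifiers.
#'
#' @param spec a [synthetic_spec()] with `label_noise_rate > 0`.
#' @return an [ec_dataset()] with attributes `"synthetic_spec"` and
#'   `"flipped_ids"`.
#' @export
generate_label_noise_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$label_noise_rate <= 0)
    stop_invalid("label-noise datasets require label_noise_rate > 0")
  set.seed(spec$seed)
  g <- gaussian_pair(spec)
  n_flip <- round(spec$label_noise_rate * spec$n_samples)
  flip_idx <- sort(sample.int(spec$n_samples, n_flip))
  labels <- g$labels
  labels[flip_idx] <- next_level(labels[flip_idx], levels(labels))
  ds <- ec_dataset(g$X, labels)
  attr(ds, "synthetic_spec") <- spec
  attr(ds, "flipped_ids") <- ds$ids[flip_idx]
  ds
}

#' Closed-form Bayes accuracy of the two-Gaussian geometry
#'
#' For two isotropic unit-variance Gaussian classes whose centroids are
#' `separation` apart, the optimal decision rule thresholds the first feature
#' at `log(p0/p1) / separation` (the likelihood-ratio point), giving accuracy
#' `p0 * pnorm(t + s/2) + p1 * (1 - pnorm(t - s/2))`. With balanced classes
#' this reduces to `pnorm(separation / 2)`; at zero separation the classes
#' are indistinguishable and the best rule predicts the majority class.
#'
#' @param separation centroid distance (non-negative).
#' @param class_balance proportion of the positive class.
#' @return the Bayes-optimal accuracy.
#' @export
boundary_bayes_accuracy <- function(separation, class_balance = 0.5) {
  if (separation < 0) stop_invalid("separation must be non-negative")
  p1 <- class_balance; p0 <- 1 - p1
  if (separation == 0) return(max(p0, p1))
  t <- log(p0 / p1) / separation
  p0 * stats::pnorm(t + separation / 2) + p1 * (1 - stats::pnorm(t - separation / 2))
}
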