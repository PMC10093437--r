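# Independent oracles and fixture builders shared across tests. The oracles
# deliberately use literal enumeration, never the package's own code paths.

# Brute-force Jaccard: enumerate the union and count shared elements.
jaccard_oracle <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(NA_real_)
  inter <- 0L
  for (x in u) if ((x %in% a) && (x %in% b)) inter <- inter + 1L
  inter / length(u)
}

# Small balanced two-class dataset with ids 0..n-1.
tiny_dataset <- function(n = 100, f = 2, seed = 1) {
  set.seed(seed)
  ec_dataset(matrix(rnorm(n * f), n, f),
             rep(c("a", "b"), length.out = n))
}

# A classifier whose decision rule ignores the training data entirely:
# predicts by the sign of the first feature.
midplane_classifier <- function() {
  classifier_adapter(
    fit = function(features, labels, ids) list(levels = levels(labels)),
    predict = function(model, features, ids)
      factor(ifelse(features[, 1] > 0, model$levels[2], model$levels[1]),
             levels = model$levels),
    descriptor = "midplane")
}

# Majority-class rule: always predicts the most frequent training label.
majority_classifier <- function() {
  classifier_adapter(
    fit = function(features, labels, ids)
      list(top = names(which.max(table(labels))), levels = levels(labels)),
    predict = function(model, features, ids)
      factor(rep(model$top, nrow(features)), levels = model$levels),
    descriptor = "majority")
}
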