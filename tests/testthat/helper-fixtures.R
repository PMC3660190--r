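# Small in-code fixtures shared across test files.

# tiny labeled dataset: n_genes x (2 * n_per_class), first `n_informative`
# genes shifted by `effect` SD units between classes
toy_dataset <- function(n_genes = 20, n_per_class = 10, n_informative = 1,
                        effect = 3, seed = 1) {
  gen <- generate_dataset(synthetic_spec(
    n_genes = n_genes, n_informative = n_informative,
    n_samples_per_class = n_per_class, effect_size = effect, seed = seed))
  gen
}

# population-standardized vector, as the MI bandwidth default expects
zstd <- function(v) {
  c <- v - mean(v)
  c / sqrt(mean(c^2))
}

# trapezoidal area under an roc_result curve, computed independently
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# brute-force pair-counting AUC (ties count one half)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}
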