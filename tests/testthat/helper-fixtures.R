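# shared fixture builders; everything is generated in code, no stored data

# a labelled wrist training set where labels come from a known cut set
# applied to noise-free linked counts; avoids boundary ties by construction
make_linked_training <- function(n = 5000, seed = 1) {
  st <- simulate_states(sticky_state_model(), n, seed = seed)
  em <- well_separated_emission(dispersion = 0)
  cts <- emit_counts(st, em, seed = seed + 1)
  hip_cpm <- to_cpm(cts$hip, 15)
  wrist_cpm <- to_cpm(cts$wrist, 15)
  list(states = st, hip_cpm = hip_cpm, wrist_cpm = wrist_cpm,
       hip_label = classify(hip_cpm, butte_hip()))
}

# brute-force ROC scan used as the independent oracle
brute_roc <- function(values, positive) {
  cand <- sort(unique(values))
  best <- Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(values[positive] > t)
    spec <- mean(values[!positive] <= t)
    if (abs(sens - spec) < best - 1e-12) {
      best <- abs(sens - spec); best_t <- t
    }
  }
  best_t
}

# exhaustive search over contiguous partitions of sorted values (oracle for
# the k-means dynamic programme; valid because optimal 1-D clusters are
# contiguous)
brute_kmeans_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf; best_b <- NULL
  for (j in seq_len(ncol(splits))) {
    cutix <- c(0, splits[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + sse(x[(cutix[i] + 1):cutix[i + 1]])
    if (tot < best - 1e-9) { best <- tot; best_b <- splits[, j] }
  }
  list(wcss = best, boundaries = x[best_b])
}

# kappa straight from the definition, as an independent check
brute_kappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

random_confusion <- function(k = 4) {
  matrix(sample(0:60, k * k, replace = TRUE), k, k,
         dimnames = list(reference = intensity_levels()[1:k],
                         comparison = intensity_levels()[1:k]))
}
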