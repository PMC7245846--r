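# independent from-definition oracle for every densitometric feature,
# written directly from the definitions (loops, no shared code paths)
oracle_features <- function(sample, bin_width = 10, lo = 0, hi = 4100) {
  n <- length(sample)
  mu <- sum(sample) / n
  med <- {
    s <- sort(sample)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  edges <- seq(lo, hi, by = bin_width)
  counts <- integer(length(edges) - 1)
  for (v in sample) {
    i <- min(max(1, floor((v - lo) / bin_width) + 1), length(counts))
    counts[i] <- counts[i] + 1
  }
  mode_bin <- which(counts == max(counts))[1]
  m2 <- sum((sample - mu)^2) / n
  m3 <- sum((sample - mu)^3) / n
  m4 <- sum((sample - mu)^4) / n
  auc_n <- sum(sample >= 1000 & sample <= 1500) / n
  auc_f <- sum(sample >= 2000 & sample <= 2500) / n
  list(mean = mu, median = med,
       mode = lo + (mode_bin - 0.5) * bin_width,
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3,
       auc_normal = auc_n, auc_fibrotic = auc_f,
       auc_ratio = if (auc_f == 0) Inf else auc_n / auc_f)
}

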