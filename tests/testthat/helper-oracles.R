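# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# closed-form OLS slope (Sigma formula)
ols_slope_oracle <- function(x, y, intercept = TRUE) {
  if (intercept) {
    xm <- mean(x); ym <- mean(y)
    sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  } else {
    sum(x * y) / sum(x^2)
  }
}

# one-sided (greater) hypergeometric tail by direct enumeration:
# P(X >= k) for X ~ Hyper(K successes, N total, n drawn)
hyper_tail_oracle <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# naive average-linkage agglomeration over a distance matrix; returns the
# partition (list of index vectors) at exactly k clusters
brute_average_linkage <- function(d, k) {
  d <- as.matrix(d)
  groups <- as.list(seq_len(nrow(d)))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      avg <- mean(d[groups[[i]], groups[[j]]])
      if (avg < best[1]) best <- c(avg, j, i)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  groups
}

# canonical form of a partition given as labels, for comparing clusterings
# that may use different label ids
partition_signature <- function(labels) {
  sets <- split(names(labels), labels)
  sets <- lapply(sets, sort)
  paste(sort(vapply(sets, paste, "", collapse = ",")), collapse = ";")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
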