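# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws:
# mark the first K items, enumerate every n-subset, count overlaps >= k.
enum_hyper_tail <- function(k, N, K, n) {
  if (n == 0 || k == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Monte-Carlo permutation estimate of the same tail (for N too big to
# enumerate): draw n of N items uniformly without replacement.
mc_hyper_tail <- function(k, N, K, n, n_draws = 1e5) {
  hits <- vapply(seq_len(n_draws),
                 function(i) sum(sample.int(N, n) <= K), numeric(1))
  mean(hits >= k)
}

# Literal Benjamini-Hochberg step-up: sort, q_i = p_(i) * m / i, enforce
# monotonicity from the largest rank down, cap at 1, unsort.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  q[order(o)]
}

# Brute-force UPGMA: keeps explicit member lists and recomputes every
# cluster-cluster distance as the mean over all member pairs of the
# ORIGINAL distance matrix (no Lance-Williams update). Same tie-break rule:
# lowest pair of current cluster positions.
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))   # member leaf indices
  codes <- -seq_len(n)              # hclust coding
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dist_ij < best) { best <- dist_ij; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- sort(c(codes[bi], codes[bj]))
    height[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    codes[bi] <- step
    clusters[[bj]] <- NULL
    codes <- codes[-bj]
  }
  list(merge = merge, height = height)
}

# Double-loop prevalence oracles, straight from the definitions.
prevalence_intra_oracle <- function(values, gene, k) {
  v <- values[gene, ]
  pos <- 0; n <- 0
  for (s in seq_len(ncol(values))) {
    if (is.na(v[s])) next
    n <- n + 1
    med <- stats::median(values[, s], na.rm = TRUE)
    if (v[s] > k * med) pos <- pos + 1
  }
  100 * pos / n
}

prevalence_cross_oracle <- function(values, gene, k) {
  v <- values[gene, ]
  v <- v[!is.na(v)]
  med <- stats::median(v)
  100 * sum(v > k * med) / length(v)
}

# Random linear-scale matrix with dimnames, optionally with missing values.
random_matrix <- function(n_genes, n_samples, na_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(2^rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  if (na_frac > 0) {
    v[sample(length(v), round(na_frac * length(v)))] <- NA
  }
  v
}
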