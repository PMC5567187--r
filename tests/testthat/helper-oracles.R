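# Independent oracles: deliberately naive implementations, kept free of any
# package internals, used to cross-check the fast implementations.

# step-up BH from its definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

# hypergeometric upper tail by direct enumeration of the pmf
oracle_hyper_upper <- function(M, K, N, x) {
  if (x == 0) {
    return(1)
  }
  ks <- x:min(K, N)
  sum(choose(K, ks) * choose(M - K, N - ks)) / choose(M, N)
}

# Davies-Bouldin from the textbook formula, two explicit loops
oracle_db <- function(x, labels) {
  levs <- unique(labels)
  k <- length(levs)
  cent <- lapply(levs, function(l) colMeans(x[labels == l, , drop = FALSE]))
  scat <- sapply(seq_len(k), function(i) {
    xi <- x[labels == levs[i], , drop = FALSE]
    mean(apply(xi, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  })
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (scat[i] + scat[j]) / d)
    }
    total <- total + best
  }
  total / k
}

# KNN imputation by brute-force all-pairs distances (same metric definition:
# RMS difference over co-observed samples, neighbours observed at the target)
oracle_knn <- function(x, k = 3) {
  out <- x
  for (p in seq_len(nrow(x))) {
    miss <- which(is.na(x[p, ]))
    if (!length(miss)) next
    d <- rep(Inf, nrow(x))
    for (q in seq_len(nrow(x))) {
      if (q == p) next
      shared <- which(!is.na(x[p, ]) & !is.na(x[q, ]))
      if (!length(shared)) next
      d[q] <- sqrt(sum((x[p, shared] - x[q, shared])^2) / length(shared))
    }
    for (s in miss) {
      cand <- order(d)
      cand <- cand[is.finite(d[cand]) & !is.na(x[cand, s])]
      out[p, s] <- if (!length(cand)) {
        mean(x[p, ], na.rm = TRUE)
      } else {
        mean(x[cand[seq_len(min(k, length(cand)))], s])
      }
    }
  }
  out
}

# Spearman rho by explicit rank-then-Pearson
oracle_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# two-sided Fisher exact p for a 2x2 table by enumerating hypergeometric
# tables: sum of probabilities of tables no more probable than the observed
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pooled two-sample t via stats::t.test, var.equal
oracle_pooled_t <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
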