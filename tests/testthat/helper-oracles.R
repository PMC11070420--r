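# Independent oracles and small fixtures shared across tests. These stay
# deliberately naive (double loops, pairwise enumeration) so they are
# independent of the implementation paths they check.

# Brute-force Euclidean distance transform: per pixel, min distance over all
# vessel pixels. O(N^2 * V).
bf_edt <- function(mask) {
  vp <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((vp[, 1] - i)^2 + (vp[, 2] - j)^2))
    }
  }
  out
}

# Pairwise-enumeration AUROC: mean over all positive-negative pairs of
# 1 (positive outscores), 1/2 (tie), 0 otherwise.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Population moments computed directly (oracle for distribution_features).
bf_moments <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  m4 <- sum((x - m)^4) / length(x)
  c(maximum = max(x), mean = m, standard_deviation = sqrt(m2),
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# Random binary mask with at least one vessel pixel.
random_mask <- function(seed, nr = 32, nc = nr, p = 0.15) {
  set.seed(seed)
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

# Dice overlap of two binary masks.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Canonical partition signature of a labelled matrix: the list of pixel-index
# sets, sorted, so two labelings can be compared up to label renumbering.
partition_signature <- function(labels) {
  grp <- split(which(labels > 0), labels[labels > 0])
  unname(grp[order(vapply(grp, min, integer(1)))])
}

# Small-image generator parameters to keep unit tests fast; the generator
# defaults (512 px) are exercised in the acceptance tests.
small_params <- function(seed, ...) {
  synth_params(image_size = 128, seed = seed, ...)
}

# Whether a vessel graph is connected (BFS over the edge list).
graph_connected <- function(g) {
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
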