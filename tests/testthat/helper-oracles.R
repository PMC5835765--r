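# Independent oracles used to cross-check the package implementation.
# Deliberately written as plain brute force, sharing no code with R/.

# entropy in bits, direct formula
oracle_entropy <- function(p) {
  h <- 0
  for (q in c(p, 1 - p)) if (q > 0) h <- h - q * log(q) / log(2)
  h
}

# exhaustive cutpoint search: loop over every midpoint between consecutive
# distinct sorted volumes, recompute the weighted-gain from scratch
oracle_find_threshold <- function(v, lab) {
  sv <- sort(unique(v))
  best_t <- NA_real_; best_g <- -Inf
  parent <- oracle_entropy(mean(lab))
  for (i in seq_len(length(sv) - 1)) {
    t <- (sv[i] + sv[i + 1]) / 2
    d1 <- lab[v < t]; d2 <- lab[v >= t]
    g <- parent - (length(d1) / length(lab) * oracle_entropy(mean(d1)) +
                     length(d2) / length(lab) * oracle_entropy(mean(d2)))
    if (g > best_g + 1e-12) { best_g <- g; best_t <- t }
  }
  list(threshold = best_t, gain = best_g)
}

# two-sided Fisher p by full enumeration of tables with the observed
# margins, summing hypergeometric point probabilities <= observed
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random 2x2 table with all margins positive
random_table_2x2 <- function(n_max = 40) {
  repeat {
    n <- sample(4:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    m <- matrix(cells, 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# labeled-volume instance with both classes present and >= 2 distinct volumes
random_instance <- function(n_max = 50) {
  repeat {
    n <- sample(4:n_max, 1)
    v <- round(10^runif(n, 2, 4.5), 2)
    lab <- runif(n) < plogis(3 * (log10(v) - runif(1, 2.5, 4)))
    if (any(lab) && !all(lab) && length(unique(v)) >= 2) {
      return(list(v = v, lab = lab))
    }
  }
}

# tiny synthetic label image: array of labels plus an affine
make_label_image <- function(labels, dim = c(4, 4, 4), affine = diag(4)) {
  arr <- array(0L, dim = dim)
  arr[seq_along(labels)] <- as.integer(labels)
  list(data = arr, affine = affine)
}

# 3D rotation matrix about z by angle theta
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
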