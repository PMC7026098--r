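# Independent brute-force oracles used to cross-check the implementation.
# These recompute everything from first principles and share no code with
# the package internals.

# Ward2 agglomeration from scratch: at every step the merge cost of two
# clusters A, B is computed directly from the ORIGINAL dissimilarities via
# the ESS identity  D^2(A,B) = 2 [ ESS(A u B) - ESS(A) - ESS(B) ],
# ESS(S) = (1/|S|) sum_{i<j in S} d_ij^2, with no Lance-Williams update.
# Returns merge heights and the partition at each k.
brute_ward2 <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  ess <- function(members) {
    if (length(members) < 2) return(0)
    sum(D2[members, members][upper.tri(matrix(0, length(members), length(members)))]) /
      length(members)
  }
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cost <- 2 * (ess(c(clusters[[i]], clusters[[j]])) -
                     ess(clusters[[i]]) - ess(clusters[[j]]))
      if (cost < best[1] - 1e-12) best <- c(cost, i, j)
    }
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters <- clusters[-j]
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[n - step]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# n-subsets of an N-element population with K marked elements.
brute_hyper_upper <- function(k, K, N, n) {
  pop <- seq_len(N)
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Two-sided Fisher p for a 2x2 table by full enumeration of the
# hypergeometric support with fixed margins (probability ordering, with
# the conventional 1e-7 relative tolerance).
brute_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)),
    numeric(1))
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Ancestor closure (including the term itself) by recursive walk over a
# child -> parents edge list.
brute_ancestors <- function(term, edges) {
  out <- term
  frontier <- term
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    frontier <- setdiff(parents, out)
    out <- union(out, frontier)
  }
  sort(out)
}

# All-pairs interval overlap scan (0-based half-open).
brute_gene_hits <- function(cnvs, genes) {
  out <- list()
  for (i in seq_len(nrow(cnvs))) for (j in seq_len(nrow(genes))) {
    if (cnvs$chrom[i] != genes$chrom[j]) next
    if (!genes$brain_expressed[j]) next
    if (min(cnvs$end[i], genes$end[j]) > max(cnvs$start[i], genes$start[j]))
      out[[length(out) + 1]] <- data.frame(
        individual_id = cnvs$individual_id[i], gene_id = genes$gene_id[j],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(individual_id = character(), gene_id = character()))
  unique(do.call(rbind, out))
}

# random symmetric Gower-like dissimilarity matrix in [0, 1]
random_gower_matrix <- function(n, seed) {
  set.seed(seed)
  D <- matrix(runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

partition_agrees <- function(a, b) {
  # label-invariant equality of two partitions
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}
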