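#' Phenotype clustering: weighted Gower distance, Ward2 agglomeration,
#' silhouette pruning, bootstrap stability, feature contribution
#'
#' @name cluster
NULL

#' Specification of the clustering features and their encodings
#'
#' Seven features: ADI-R verbal status and gender are nominal; the ADOS
#' severity category (Non-spectrum < ASD < Autism) and the IQ category
#' (severe_ID < mild_ID < normal) are ordinal; the three VABS subscales
#' enter as their binary dysfunctional/normal categories by default, or as
#' raw scores (`vabs_mode = "raw"`) for users who prefer the numeric scale.
#'
#' @param vabs_mode `"category"` (default) or `"raw"`.
#' @return data.frame with columns `feature`, `type` and a `levels`
#'   list-column giving the ordered category levels for non-numeric
#'   features.
#' @export
clustering_feature_spec <- function(vabs_mode = c("category", "raw")) {
  vabs_mode <- match.arg(vabs_mode)
  vabs <- c("communication", "daily_living", "socialization")
  if (vabs_mode == "category") {
    vabs_feats <- data.frame(feature = paste0("vabs_", vabs, "_category"),
                             type = "nominal", stringsAsFactors = FALSE)
    vabs_levels <- rep(list(c("dysfunctional", "normal")), 3)
  } else {
    vabs_feats <- data.frame(feature = paste0("vabs_", vabs),
                             type = "numeric", stringsAsFactors = FALSE)
    vabs_levels <- rep(list(NULL), 3)
  }
  spec <- rbind(
    data.frame(feature = "adi_verbal", type = "nominal", stringsAsFactors = FALSE),
    data.frame(feature = "ados_category", type = "ordinal", stringsAsFactors = FALSE),
    vabs_feats,
    data.frame(feature = "iq_category", type = "ordinal", stringsAsFactors = FALSE),
    data.frame(feature = "gender", type = "nominal", stringsAsFactors = FALSE))
  spec$levels <- c(list(c("verbal", "nonverbal")),
                   list(c("Non-spectrum", "ASD", "Autism")),
                   vabs_levels,
                   list(c("severe_ID", "mild_ID", "normal")),
                   list(c("male", "female")))
  spec
}

# numeric encoding of one feature column for distance / correlation work:
# nominal -> integer codes, ordinal -> rank index, numeric -> as-is
encode_feature <- function(x, type, levels = NULL) {
  if (type == "numeric") return(as.numeric(x))
  if (is.null(levels)) levels <- sort(unique(as.character(x)))
  m <- match(as.character(x), levels)
  if (anyNA(m) && !anyNA(x)) stop("value outside declared levels")
  as.numeric(m)
}

#' Screen features for high pairwise correlation
#'
#' Pearson correlation on numeric/rank encodings; features joined by any
#' correlation strictly above `threshold` form groups (connected components
#' of the threshold graph).  Constant features have no defined correlation
#' and are reported and excluded from the screen.
#'
#' @param table data.frame holding the features.
#' @param features Character vector of feature columns to screen (default:
#'   all columns of `table`).
#' @param threshold Correlation threshold (strict `>`), default 0.75.
#' @param spec Optional [clustering_feature_spec()]-style data.frame
#'   supplying encodings; columns not in it are encoded automatically.
#' @return List with `groups` (list of character vectors, each of size
#'   >= 2), `correlation` (matrix) and `constant` (excluded features).
#' @export
correlation_screen <- function(table, features = names(table),
                               threshold = 0.75, spec = NULL) {
  enc <- sapply(features, function(f) {
    type <- "numeric"; levels <- NULL
    if (!is.null(spec) && f %in% spec$feature) {
      i <- match(f, spec$feature)
      type <- spec$type[i]; levels <- spec$levels[[i]]
    } else if (!is.numeric(table[[f]])) {
      type <- "nominal"
    }
    encode_feature(table[[f]], type, levels)
  })
  sds <- apply(enc, 2, stats::sd, na.rm = TRUE)
  constant <- features[is.na(sds) | sds == 0]
  use <- setdiff(features, constant)
  if (length(constant))
    warning("constant feature(s) excluded from correlation screen: ",
            paste(constant, collapse = ", "))
  cm <- stats::cor(enc[, use, drop = FALSE], use = "pairwise.complete.obs",
                   method = "pearson")
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(use, comp$membership)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2])
  list(groups = groups, correlation = cm, constant = constant)
}

#' Down-weight correlated features
#'
#' Every feature belonging to any correlated group receives
#' `reduced_weight` (default half); all others keep `base_weight`.
#' Membership in several overlapping groups still yields a single
#' halving (idempotent).
#'
#' @param features Character vector of all clustering features.
#' @param groups Groups from [correlation_screen()].
#' @param base_weight,reduced_weight Weights, defaults 1 and 0.5.
#' @return Named numeric vector of weights.
#' @export
apply_correlation_weights <- function(features, groups,
                                      base_weight = 1, reduced_weight = 0.5) {
  w <- stats::setNames(rep(base_weight, length(features)), features)
  inside <- intersect(unique(unlist(groups)), features)
  w[inside] <- reduced_weight
  w
}

#' Weighted Gower distance matrix for mixed-type features
#'
#' d(i,j) = sum_f w_f d_f(i,j) / sum_f w_f, with per-feature contributions:
#' nominal/binary 0 if equal else 1; ordinal |rank_i - rank_j| / (R - 1)
#' on the category ranks; numeric |x_i - x_j| / range.  A zero-range
#' numeric feature contributes 0 with a warning.  Entries lie in [0, 1]
#' and halving all weights leaves the matrix unchanged.
#'
#' @param table Complete (no NA) data.frame holding the features.
#' @param weights Named weights per feature (default all 1).
#' @param spec Feature specification, default [clustering_feature_spec()].
#' @return Symmetric n x n matrix, zero diagonal, dimnames =
#'   individual ids when present.
#' @export
gower_distance <- function(table, weights = NULL,
                           spec = clustering_feature_spec()) {
  feats <- spec$feature
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    stop("features absent from table: ", paste(missing_cols, collapse = ", "))
  if (anyNA(table[feats])) stop("table has missing values; impute first")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(feats)), feats)
  if (any(weights[feats] <= 0) || anyNA(weights[feats]))
    stop("all features need positive weights")
  n <- nrow(table)
  D <- matrix(0, n, n)
  wsum <- 0
  for (i in seq_along(feats)) {
    f <- feats[i]; type <- spec$type[i]
    x <- encode_feature(table[[f]], type, spec$levels[[i]])
    if (type == "nominal") {
      contrib <- outer(x, x, `!=`) * 1
    } else {
      denom <- if (type == "ordinal") length(spec$levels[[i]]) - 1
               else diff(range(x))
      if (denom == 0) {
        warning("zero-range feature '", f, "' contributes 0 to all distances")
        contrib <- matrix(0, n, n)
      } else {
        contrib <- abs(outer(x, x, `-`)) / denom
      }
    }
    D <- D + weights[[f]] * contrib
    wsum <- wsum + weights[[f]]
  }
  D <- D / wsum
  ids <- if ("individual_id" %in% names(table)) table$individual_id else NULL
  dimnames(D) <- list(ids, ids)
  D
}

#' Agglomerative hierarchical clustering with the Ward2 criterion
#'
#' Lance-Williams agglomeration on squared dissimilarities with merge
#' heights reported as square roots (the ward.D2 convention), cut to `k`
#' clusters.
#'
#' @param D Distance matrix (square symmetric) or `dist`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return List with `labels` (integer 1..k, named by individual), `k`,
#'   and `tree` (the `hclust` object; `$height` is nondecreasing).
#' @export
ahc_ward2 <- function(D, k) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must lie in 1..n")
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, k = k, tree = tree)
}

#' Silhouette widths for a clustering
#'
#' s_i = (b_i - a_i) / max(a_i, b_i), with a_i the mean distance to the
#' individual's own cluster (excluding itself) and b_i the smallest mean
#' distance to another cluster.  Members of singleton clusters score 0.
#' The overall value is the cluster-size-weighted mean of the per-cluster
#' means.
#'
#' @param D Distance matrix.
#' @param labels Cluster labels (>= 2 distinct, all clusters nonempty).
#' @return List with `s` (per-individual widths), `cluster_means`,
#'   `sizes`, and `overall`.
#' @export
silhouette_report <- function(D, labels) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labels <- as.vector(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters")
  n <- nrow(D)
  sizes <- table(factor(labels, levels = cl))
  # k x n matrix of summed distances from each individual to each cluster
  sums <- rowsum(D, group = labels)            # rows ordered by sort(unique)
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], cl)
    own_size <- sizes[[g]]
    a[i] <- if (own_size > 1) sums[g, i] / (own_size - 1) else 0
    other <- setdiff(seq_along(cl), g)
    b[i] <- min(sums[other, i] / as.numeric(sizes[other]))
  }
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  singleton <- sizes[match(labels, cl)] == 1
  s[singleton] <- 0
  cluster_means <- vapply(cl, function(g) mean(s[labels == g]), numeric(1))
  names(cluster_means) <- cl
  overall <- sum(as.numeric(sizes) * cluster_means) / sum(sizes)
  names(s) <- rownames(D)
  list(s = s, cluster_means = cluster_means,
       sizes = stats::setNames(as.integer(sizes), cl), overall = overall)
}

#' Remove weakly clustered individuals and recluster
#'
#' Clusters the cohort, removes every individual with silhouette width
#' below `s_threshold`, recomputes the distance matrix on the remainder
#' and reclusters at the same `k`.  Single pass by default; `iterate`
#' repeats until no individual falls below the threshold.
#'
#' @param table Complete clinical data.frame (with category columns).
#' @param weights Feature weights for [gower_distance()].
#' @param k Number of clusters.
#' @param s_threshold Silhouette threshold (strict `<` removal), default
#'   0.300.
#' @param spec Feature specification.
#' @param iterate Repeat to fixpoint (default FALSE).
#' @return List with `table` (pruned), `assignment`, `silhouette`
#'   (after), `silhouette_before`, `removed_ids`.
#' @export
prune_weak <- function(table, weights = NULL, k = 2, s_threshold = 0.300,
                       spec = clustering_feature_spec(), iterate = FALSE) {
  D <- gower_distance(table, weights, spec)
  asg <- ahc_ward2(D, k)
  sil_before <- silhouette_report(D, asg$labels)
  removed <- character(0)
  repeat {
    weak <- sil_before$s < s_threshold
    if (!any(weak)) { sil <- sil_before; break }
    if (all(weak))
      stop("silhouette threshold ", s_threshold, " removes every individual (n = ",
           nrow(table), ", min s = ", round(min(sil_before$s), 3), ")")
    removed <- c(removed, table$individual_id[weak])
    table <- table[!weak, , drop = FALSE]
    D <- gower_distance(table, weights, spec)
    asg <- ahc_ward2(D, k)
    sil <- silhouette_report(D, asg$labels)
    if (!iterate) break
    sil_before <- sil
  }
  list(table = table, assignment = asg, silhouette = sil,
       silhouette_before = sil_before, removed_ids = removed)
}

# best-matching Jaccard of each reference cluster against a bootstrap
# clustering, over the ids present in the resample
max_jaccard <- function(ref_labels, boot_labels, ids) {
  ref_sets <- split(ids, ref_labels[ids])
  boot_sets <- split(ids, boot_labels[ids])
  vapply(ref_sets, function(rs)
    max(vapply(boot_sets, function(bs) jaccard(rs, bs), numeric(1))),
    numeric(1))
}

#' Bootstrap cluster stability (Jaccard boot means)
#'
#' For each of `B` bootstrap resamples (n with replacement), the distinct
#' resampled individuals are reclustered with the same pipeline (the
#' reference dissimilarity matrix restricted to them, Ward2 at the same
#' `k`), and each reference cluster records its maximal Jaccard overlap
#' with the bootstrap clusters, computed on the distinct individuals in
#' the resample.  Boot means above 0.85 are conventionally read as stable
#' clusters.
#'
#' @param table Complete clinical data.frame.
#' @param weights Feature weights.
#' @param k Number of clusters.
#' @param B Bootstrap iterations, default 1000.
#' @param seed Integer seed.
#' @param spec Feature specification.
#' @return List with `boot_mean` (per reference cluster), `B`, and
#'   `reference` (the reference assignment).
#' @export
bootstrap_stability <- function(table, weights = NULL, k = 2, B = 1000L,
                                seed = 1L, spec = clustering_feature_spec()) {
  if (B < 1) stop("B must be at least 1")
  D <- gower_distance(table, weights, spec)
  ref <- ahc_ward2(D, k)
  n <- nrow(table)
  ids <- table$individual_id
  ref_labels <- stats::setNames(ref$labels, ids)
  acc <- matrix(NA_real_, B, k)
  with_seed(seed, {
    for (b in seq_len(B)) {
      take <- sort(unique(sample.int(n, n, replace = TRUE)))
      if (length(take) <= k) { acc[b, ] <- NA; next }
      sub <- D[take, take]
      bl <- stats::setNames(ahc_ward2(sub, k)$labels, ids[take])
      acc[b, ] <- max_jaccard(ref_labels, bl, ids[take])
    }
  })
  boot_mean <- colMeans(acc, na.rm = TRUE)
  names(boot_mean) <- sort(unique(ref$labels))
  list(boot_mean = boot_mean, B = as.integer(B), reference = ref)
}

# greedy maximal-overlap matching of new cluster labels onto reference
# labels; ties broken toward larger reference clusters
match_clusters <- function(ref, new) {
  rl <- sort(unique(ref)); nl <- sort(unique(new))
  conf <- table(factor(ref, rl), factor(new, nl))
  mapping <- stats::setNames(rep(NA_integer_, length(nl)), nl)
  ref_sizes <- table(factor(ref, rl))
  free_r <- rl; free_n <- nl
  while (length(free_r) && length(free_n)) {
    sub <- conf[as.character(free_r), as.character(free_n), drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    if (nrow(best) > 1) {
      sz <- ref_sizes[as.character(free_r)[best[, 1]]]
      best <- best[order(-as.numeric(sz), best[, 1], best[, 2]), , drop = FALSE]
    }
    r <- free_r[best[1, 1]]; nn <- free_n[best[1, 2]]
    mapping[as.character(nn)] <- r
    free_r <- setdiff(free_r, r); free_n <- setdiff(free_n, nn)
  }
  mapping[as.character(new)]
}

#' Contribution of each feature to cluster cohesion
#'
#' One feature at a time is removed (weights renormalised implicitly by
#' the Gower denominator), the cohort reclustered at the same `k`, new
#' clusters matched to the reference clusters by greedy maximal overlap,
#' and the change in per-cluster mean silhouette recorded as
#' reference minus reduced.  A positive change means the feature supports
#' that cluster's cohesion.
#'
#' @param table Complete clinical data.frame.
#' @param weights Feature weights.
#' @param ref_labels Reference cluster labels (vector aligned with rows).
#' @param spec Feature specification.
#' @return data.frame with one row per (feature, cluster): `feature`,
#'   `cluster`, `delta_silhouette`.
#' @export
feature_contribution <- function(table, weights = NULL, ref_labels,
                                 spec = clustering_feature_spec()) {
  feats <- spec$feature
  if (length(feats) < 2) stop("need at least two features")
  k <- length(unique(ref_labels))
  D_full <- gower_distance(table, weights, spec)
  sil_full <- silhouette_report(D_full, ref_labels)
  out <- list()
  for (f in feats) {
    sub_spec <- spec[spec$feature != f, , drop = FALSE]
    D <- gower_distance(table, weights, sub_spec)
    new <- ahc_ward2(D, k)$labels
    mapped <- match_clusters(ref_labels, new)
    sil <- silhouette_report(D, mapped)
    cl <- names(sil_full$cluster_means)
    out[[f]] <- data.frame(
      feature = f, cluster = cl,
      delta_silhouette = sil_full$cluster_means[cl] - sil$cluster_means[cl],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
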