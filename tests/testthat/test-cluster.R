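two_feature_spec <- function() {
  spec <- data.frame(feature = c("b", "o"), type = c("nominal", "ordinal"),
                     stringsAsFactors = FALSE)
  spec$levels <- list(c("x", "y"), c("l1", "l2", "l3"))
  spec
}

test_that("correlation screen groups connected high-correlation features", {
  set.seed(11)
  n <- 500
  lat <- rnorm(n)
  tab <- data.frame(v1 = lat + rnorm(n, 0, 0.35),
                    v2 = lat + rnorm(n, 0, 0.35),
                    v3 = lat + rnorm(n, 0, 0.35),
                    dup = NA, ind1 = rnorm(n), ind2 = rnorm(n),
                    const = 1)
  tab$dup <- tab$ind1
  expect_warning(scr <- correlation_screen(tab), "constant")
  expect_equal(scr$constant, "const")
  groups <- lapply(scr$groups, sort)
  expect_true(list(c("v1", "v2", "v3")) %in% groups ||
                any(vapply(groups, function(g)
                  setequal(g, c("v1", "v2", "v3")), logical(1))))
  expect_true(any(vapply(groups, function(g)
    setequal(g, c("dup", "ind1")), logical(1))))

  # independent features are (almost) never grouped: 20 replicates
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    t2 <- data.frame(a = rnorm(500), b = rnorm(500))
    length(correlation_screen(t2)$groups) > 0
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("correlated features are down-weighted to half, idempotently", {
  feats <- c("f1", "f2", "f3", "f4")
  expect_equal(unname(apply_correlation_weights(feats, list())),
               rep(1, 4))
  w <- apply_correlation_weights(feats, list(c("f1", "f2")))
  expect_equal(unname(w), c(0.5, 0.5, 1, 1))
  # membership in two overlapping groups still halves once
  w2 <- apply_correlation_weights(feats, list(c("f1", "f2"), c("f2", "f3")))
  expect_equal(unname(w2), c(0.5, 0.5, 0.5, 1))
})

test_that("weighted Gower distances match hand computation and stay in [0,1]", {
  spec <- two_feature_spec()
  tab <- data.frame(b = c("x", "y"), o = c("l1", "l3"),
                    stringsAsFactors = FALSE)
  D <- gower_distance(tab, c(b = 1, o = 0.5), spec)
  expect_equal(D[1, 2], 1)           # (1*1 + 0.5*1) / 1.5
  tab2 <- data.frame(b = c("x", "y"), o = c("l1", "l2"))
  D2 <- gower_distance(tab2, c(b = 1, o = 0.5), spec)
  expect_equal(D2[1, 2], (1 + 0.5 * 0.5) / 1.5)   # 0.8333

  same <- data.frame(b = c("x", "x"), o = c("l2", "l2"))
  expect_equal(gower_distance(same, spec = spec)[1, 2], 0)
  alldiff <- data.frame(b = c("x", "y"), o = c("l1", "l3"))
  expect_equal(gower_distance(alldiff, spec = spec)[1, 2], 1)

  # scale invariance: halving all weights changes nothing
  cohort <- derive_categories(generate_clinical(
    cohort_config(60, module4_rate = 0, seed = 2))$table)
  w <- setNames(rep(1, 7), clustering_feature_spec()$feature)
  Da <- gower_distance(cohort, w)
  Db <- gower_distance(cohort, w / 2)
  expect_equal(Da, Db)
  expect_true(all(Da >= 0 & Da <= 1))
  expect_true(isSymmetric(Da))
  expect_equal(diag(Da), setNames(rep(0, 60), cohort$individual_id))
})

test_that("zero-range numeric features contribute zero with a warning", {
  spec <- data.frame(feature = c("n1", "n2"), type = "numeric",
                     stringsAsFactors = FALSE)
  spec$levels <- list(NULL, NULL)
  tab <- data.frame(n1 = c(5, 5, 5), n2 = c(0, 1, 2))
  expect_warning(D <- gower_distance(tab, spec = spec), "zero-range")
  expect_equal(D[1, 3], (0 + 1) / 2)
})

test_that("Ward2 agglomeration matches hclust conventions and edge cases", {
  D <- random_gower_matrix(8, seed = 1)
  expect_error(ahc_ward2(D, 9), "k must lie")
  singletons <- ahc_ward2(D, 8)
  expect_equal(length(unique(singletons$labels)), 8)
  expect_true(all(diff(singletons$tree$height) >= -1e-12))

  # two tight groups, large separation: k = 2 recovers ground truth
  truth <- rep(1:2, each = 5)
  D2 <- matrix(0.9, 10, 10)
  D2[1:5, 1:5] <- 0.05; D2[6:10, 6:10] <- 0.05
  set.seed(2)
  jit <- matrix(runif(100, 0, 0.01), 10)
  D2 <- D2 + (jit + t(jit)) / 2
  diag(D2) <- 0
  got <- ahc_ward2(D2, 2)$labels
  expect_true(partition_agrees(got, truth))
})

test_that("Ward2 equals the from-scratch ESS agglomerator on random matrices", {
  for (s in 1:10) {
    n <- sample(5:10, 1)
    D <- random_gower_matrix(n, seed = 1000 + s)
    oracle <- brute_ward2(D)
    tree <- ahc_ward2(D, 2)$tree
    expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-8)
    for (k in 2:(n - 1))
      expect_true(partition_agrees(stats::cutree(tree, k), oracle$partitions[[k]]))
  }
})

test_that("silhouette widths match hand computation and the weighted identity", {
  D <- as.matrix(dist(c(0, 1, 10, 11), method = "manhattan"))
  rep1 <- silhouette_report(D, c(1, 1, 2, 2))
  expect_equal(rep1$s[[1]], (10.5 - 1) / 10.5, tolerance = 1e-12)
  expect_true(all(rep1$s >= -1 & rep1$s <= 1))

  # duplicated points in two clusters: a_i = 0, all s_i = 1
  Dd <- matrix(1, 6, 6); Dd[1:3, 1:3] <- 0; Dd[4:6, 4:6] <- 0; diag(Dd) <- 0
  repd <- silhouette_report(Dd, rep(1:2, each = 3))
  expect_equal(unname(repd$s), rep(1, 6))

  expect_error(silhouette_report(D, rep(1, 4)), "2 clusters")

  # overall equals size-weighted per-cluster means on a real cohort
  cohort <- derive_categories(generate_clinical(
    cohort_config(80, module4_rate = 0, seed = 5))$table)
  Dg <- gower_distance(cohort)
  lab <- ahc_ward2(Dg, 2)$labels
  sr <- silhouette_report(Dg, lab)
  expect_equal(sr$overall,
               sum(sr$sizes * sr$cluster_means) / sum(sr$sizes))
  # cross-check against the classic silhouette implementation
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(lab, stats::as.dist(Dg))
  expect_equal(unname(sr$s), unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette pruning removes planted in-between individuals", {
  cohort <- generate_clinical(cohort_config(200, module4_rate = 0, seed = 3))
  clin <- derive_categories(cohort$table)

  res_keep <- prune_weak(clin, s_threshold = -1)
  expect_equal(nrow(res_keep$table), 200)
  expect_length(res_keep$removed_ids, 0)

  # plant 10% "in-between" rows (features drawn half from each group) in
  # a cleanly separated base cohort; removals should concentrate on them
  clean_params <- default_group_params()
  clean_params$milder$verbal_rate <- 1
  clean_params$severe$verbal_rate <- 0
  clean_params$milder$iq_mean <- 100; clean_params$milder$iq_sd <- 8
  clean_params$severe$iq_mean <- 45; clean_params$severe$iq_sd <- 8
  clean_params$milder$vabs_mean[] <- 85
  clean_params$severe$vabs_mean[] <- 40
  planted_removed <- vapply(1:10, function(s) {
    coh <- generate_clinical(cohort_config(
      180, module4_rate = 0, group_params = clean_params,
      vabs_latent_sd = 6, vabs_noise_sd = 3, seed = s))
    tab <- derive_categories(coh$table)
    n_plant <- 20
    donors_m <- which(coh$latent == "milder")[1:n_plant]
    donors_s <- which(coh$latent == "severe")[1:n_plant]
    mix <- tab[donors_m, ]
    # each planted row draws every feature from a random group's donor
    set.seed(1000 + s)
    feat_cols <- clustering_feature_spec()$feature
    for (j in seq_len(n_plant)) {
      from_sev <- sample(feat_cols, ceiling(length(feat_cols) / 2))
      mix[j, from_sev] <- tab[donors_s[j], from_sev]
    }
    mix$individual_id <- paste0("mix", 1:n_plant)
    aug <- rbind(tab, mix)
    pruned <- prune_weak(aug, k = 2, s_threshold = 0.300)
    sum(grepl("^mix", pruned$removed_ids)) /
      max(1, length(pruned$removed_ids))
  }, numeric(1))
  expect_gte(mean(planted_removed >= 0.8), 0.8)
})

test_that("bootstrap stability is high for separated groups, seeded, validated", {
  cohort <- derive_categories(generate_clinical(
    cohort_config(120, module4_rate = 0, seed = 8))$table)
  st <- bootstrap_stability(cohort, k = 2, B = 50, seed = 4)
  expect_equal(st$B, 50L)
  expect_true(all(st$boot_mean >= 0 & st$boot_mean <= 1))
  st2 <- bootstrap_stability(cohort, k = 2, B = 50, seed = 4)
  expect_identical(st$boot_mean, st2$boot_mean)
  expect_error(bootstrap_stability(cohort, k = 2, B = 0), "B must")

  # strongly separated duplicated-point groups are perfectly stable
  dup <- cohort[rep(1:2, each = 30), ]
  dup$individual_id <- paste0("d", 1:60)
  expect_equal(unname(bootstrap_stability(dup, k = 2, B = 30,
                                          seed = 1)$boot_mean),
               c(1, 1))
})

test_that("forcing k=2 on a single homogeneous group is unstable", {
  # numeric-feature cohort drawn from one 10-dimensional blob
  spec <- data.frame(feature = paste0("n", 1:10), type = "numeric",
                     stringsAsFactors = FALSE)
  spec$levels <- rep(list(NULL), 10)
  boot_means <- vapply(1:12, function(s) {
    set.seed(s)
    tab <- data.frame(individual_id = paste0("i", 1:100))
    for (j in 1:10) tab[[paste0("n", j)]] <- rnorm(100)
    mean(bootstrap_stability(tab, k = 2, B = 100, seed = s,
                             spec = spec)$boot_mean)
  }, numeric(1))
  expect_lt(mean(boot_means), 0.6)
})

test_that("feature contribution isolates separating, redundant and noise features", {
  # redundancy: a duplicated feature among many informative ones barely
  # moves the per-cluster silhouettes when removed
  set.seed(41)
  n <- 120
  grp <- rep(c("a", "b"), each = n / 2)
  nf <- 9
  spec <- data.frame(feature = c(paste0("f", 1:nf), "dup", "noise"),
                     type = "nominal", stringsAsFactors = FALSE)
  spec$levels <- c(rep(list(c("a", "b")), nf + 1), list(c("u", "v")))
  tab <- data.frame(individual_id = paste0("i", 1:n),
                    stringsAsFactors = FALSE)
  for (f in paste0("f", 1:nf)) {
    v <- grp
    flip <- sample(n, 6)
    v[flip] <- ifelse(v[flip] == "a", "b", "a")
    tab[[f]] <- v
  }
  tab$dup <- tab$f1
  tab$noise <- sample(c("u", "v"), n, TRUE)
  ref <- ahc_ward2(gower_distance(tab, spec = spec), 2)$labels
  fc <- feature_contribution(tab, ref_labels = ref, spec = spec)
  expect_setequal(unique(fc$feature), spec$feature)
  expect_lt(max(abs(fc$delta_silhouette[fc$feature == "dup"])), 0.05)
  # removing the noise feature does not hurt cohesion
  expect_true(all(fc$delta_silhouette[fc$feature == "noise"] <= 1e-9))

  # a feature that alone separates the groups dominates when removed
  spec2 <- data.frame(feature = c("sep", "n1", "n2"),
                      type = c("nominal", "numeric", "numeric"),
                      stringsAsFactors = FALSE)
  spec2$levels <- list(c("a", "b"), NULL, NULL)
  tab2 <- data.frame(individual_id = paste0("i", 1:n), sep = grp,
                     n1 = rnorm(n), n2 = rnorm(n), stringsAsFactors = FALSE)
  ref2 <- ahc_ward2(gower_distance(tab2, spec = spec2), 2)$labels
  fc2 <- feature_contribution(tab2, ref_labels = ref2, spec = spec2)
  agg <- tapply(fc2$delta_silhouette, fc2$feature, mean)
  expect_equal(names(which.max(agg)), "sep")
  expect_gt(max(agg), 0)
})
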