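#' Reproducible validation experiments on synthetic cohorts
#'
#' Each experiment regenerates its synthetic inputs from a seed, runs the
#' relevant pipeline stages, and returns the measured quantities.  The
#' defaults are the study conditions under which the pipeline is validated;
#' see the methods vignette for the rationale behind each size.
#'
#' @name experiments
NULL

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjustment of the Rand index, computed from the
#' contingency table of the two labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

# correlation screen on the raw clinical scores, mapped onto the
# categorical clustering features, then half-weighting of the correlated
# group (the VABS trio under the default generator)
pheno_cluster_weights <- function(clin, threshold = 0.75,
                                  spec = clustering_feature_spec(),
                                  reduced_weight = 0.5) {
  raw <- intersect(c("vabs_communication", "vabs_daily_living",
                     "vabs_socialization", "performance_iq", "ados_severity"),
                   names(clin))
  scr <- correlation_screen(clin, features = raw, threshold = threshold)
  group_map <- lapply(scr$groups, function(g)
    intersect(sub("^(vabs_[a-z_]+)$", "\\1_category", g), spec$feature))
  apply_correlation_weights(spec$feature, group_map,
                            reduced_weight = reduced_weight)
}

# shared clustering front-end: filter, categorise, weight, prune
cluster_synthetic_cohort <- function(cohort, k = 2, s_threshold = 0.300) {
  filt <- filter_cohort(cohort$table)
  clin <- derive_categories(filt$table)
  latent <- stats::setNames(cohort$latent, cohort$table$individual_id)
  weights <- pheno_cluster_weights(clin)
  pruned <- prune_weak(clin, weights, k = k, s_threshold = s_threshold)
  labels <- stats::setNames(pruned$assignment$labels,
                            pruned$table$individual_id)
  list(pruned = pruned, labels = labels, weights = weights,
       latent = latent[names(labels)], clin = clin)
}

#' Latent-group recovery and bootstrap stability of the clustering stage
#'
#' For each seed: generate a complete two-group cohort, run the clustering
#' stage (correlation-weighted Gower, Ward2 at k = 2, silhouette pruning at
#' 0.300), and measure the adjusted Rand index between the recovered
#' clusters and the latent groups, plus the per-cluster bootstrap Jaccard
#' means.
#'
#' @param n_individuals Cohort size per replicate, default 1000.
#' @param n_seeds Number of replicates, default 20.
#' @param B Bootstrap iterations per replicate, default 100.
#' @param seed Master seed.
#' @return data.frame with `seed`, `ari`, `boot_min` (smaller of the two
#'   cluster boot means), `n_clustered`.
#' @export
experiment_parameter_recovery <- function(n_individuals = 1000L,
                                          n_seeds = 20L, B = 100L,
                                          seed = 1L) {
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    si <- stage_seed(seed, paste0("recovery", i))
    cohort <- generate_clinical(cohort_config(n_individuals, seed = si))
    run <- cluster_synthetic_cohort(cohort)
    ari <- adjusted_rand_index(run$labels, run$latent)
    stab <- bootstrap_stability(run$pruned$table, run$weights, k = 2, B = B,
                                seed = stage_seed(si, "boot"))
    out[[i]] <- data.frame(seed = i, ari = ari,
                           boot_min = min(stab$boot_mean),
                           n_clustered = length(run$labels))
  }
  do.call(rbind, out)
}

# pick designated signal processes: specific enough to be informative,
# annotated to enough genes to be detectable by the enrichment test, and
# mutually distant in the DAG (pairwise SimRel below `max_sim`) so the
# redundancy-reduction step cannot collapse the two groups' signals onto
# a shared representative
designate_signal_terms <- function(annmap, onto, n_per_group = 3L,
                                   min_genes = 5L, max_genes = 60L,
                                   max_sim = 0.5) {
  cand <- names(annmap$ic)[is.finite(annmap$ic) &
                             annmap$n_genes >= min_genes &
                             annmap$n_genes <= max_genes]
  cand <- cand[order(-annmap$ic[cand])]
  kept <- character(0)
  for (t in cand) {
    if (length(kept) == 2 * n_per_group) break
    if (all(vapply(kept, function(r) simrel(t, r, annmap, onto),
                   numeric(1)) <= max_sim))
      kept <- c(kept, t)
  }
  if (length(kept) < 2 * n_per_group)
    stop("ontology too small to designate separated signal terms")
  # the severe group takes the most specific processes, mirroring the
  # design where the positive class is carried by high-IC disruptions
  odd <- seq(1, 2 * n_per_group, by = 2)
  list(milder = kept[odd + 1], severe = kept[odd])
}

#' Classifier precision contrast between high-IC and all individuals
#'
#' For each seed: generate a cohort, genome and ontology; plant the
#' CNV-to-process signal only in an `informative_fraction` of each latent
#' group (those individuals' CNVs preferentially hit genes of their
#' group's designated specific processes, so they end up with both high
#' information content and group-informative profiles); run the full
#' pipeline (clustering, CNV filtering, enrichment, redundancy reduction,
#' IC stratification) and record the Naive Bayes precision on the first IC
#' quantile versus the whole cohort.
#'
#' @param n_individuals Cohort size, default 1200.
#' @param n_seeds Replicates, default 20.
#' @param informative_fraction Fraction of signal carriers per group,
#'   default 0.3.
#' @param odds_multiplier Target-rate multiplier for carriers, default 75
#'   (a strong planted signal: carriers aim 75% of their CNVs at their
#'   group's designated specific processes, everyone else 1%).
#' @param base_target_rate Baseline designated-gene targeting rate,
#'   default 0.01.
#' @param common_target_rate Per-CNV rate of hitting a generic shared
#'   process (group-independent), default 0.15; keeps noise-profile
#'   individuals in the feature matrix, where they dilute whole-cohort
#'   precision exactly as shallow annotations do in real cohorts.
#' @param seed Master seed.
#' @return data.frame with `seed`, `q1_precision`, `all_precision`,
#'   `n_matrix`.
#' @export
experiment_ic_signal <- function(n_individuals = 1200L, n_seeds = 20L,
                                 informative_fraction = 0.3,
                                 odds_multiplier = 75,
                                 base_target_rate = 0.01,
                                 common_target_rate = 0.15, seed = 1L) {
  # genome sized for the cohort so the hit-gene set stays well below the
  # background and the enrichment test keeps its power
  gcfg <- genome_config(chrom_lengths = c(chr1 = 4.5e8, chr2 = 3.6e8),
                        n_genes = 600L, n_terms = 80L)
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    si <- stage_seed(seed, paste0("icsignal", i))
    genes <- generate_genes(gcfg, seed = stage_seed(si, "genes"))
    onto_out <- generate_ontology(gcfg, genes, seed = stage_seed(si, "onto"))
    annmap <- build_annotation_map(onto_out$annotations, onto_out$ontology)
    enrichment <- designate_signal_terms(annmap, onto_out$ontology,
                                         min_genes = 8L, max_genes = 25L)
    generic <- names(annmap$ic)[annmap$n_genes >= 60 & annmap$n_genes <= 180]
    generic <- generic[order(-annmap$n_genes[generic])][seq_len(min(3, length(generic)))]
    cohort <- generate_clinical(cohort_config(n_individuals,
                                              seed = stage_seed(si, "cohort")))
    vcfg <- cnv_sim_config(enrichment = enrichment,
                           odds_multiplier = odds_multiplier,
                           base_target_rate = base_target_rate,
                           informative_fraction = informative_fraction,
                           common_terms = generic,
                           common_target_rate = common_target_rate)
    cnvs <- generate_cnvs(cohort, genes, annmap, vcfg, gcfg$chrom_lengths,
                          seed = stage_seed(si, "cnvs"))
    run <- cluster_synthetic_cohort(cohort)
    hc <- high_confidence_filter(cnvs$case)
    rare <- rare_filter(hc, cnvs$control, vcfg$n_controls)
    mapped <- map_to_brain_genes(rare, genes)
    ids <- intersect(names(mapped$gene_sets), names(run$labels))
    query <- unique(unlist(mapped$gene_sets[ids]))
    enr <- hypergeom_enrich(query, annmap,
                            background = genes$gene_id[genes$brain_expressed])
    sig <- enr$results[enr$results$significant, , drop = FALSE]
    groups <- reduce_redundancy(sig, annmap, onto_out$ontology)
    reps <- unique(groups$representative)
    ind <- individual_ic(mapped$gene_sets[ids], reps, annmap)
    nonverbal <- tapply(run$pruned$table$adi_verbal == "nonverbal",
                        run$labels, mean)
    severe_cluster <- as.integer(names(which.max(nonverbal)))
    mat <- build_matrix(ind$profile, run$labels, ind$ic_sum,
                        positive = severe_cluster,
                        term_order = sig$term[sig$term %in% reps])
    strat <- ic_stratified_evaluation(mat$x, mat$y, mat$ic,
                                      seed = stage_seed(si, "strat"))
    out[[i]] <- data.frame(
      seed = i,
      q1_precision = strat$precision[strat$subset == "Q1"],
      all_precision = strat$precision[strat$subset == "all"],
      n_matrix = nrow(mat$x))
  }
  do.call(rbind, out)
}

#' Null calibration of the classifier and the importance measure
#'
#' Features are drawn independently of the labels; the cross-validated
#' Naive Bayes recall should sit near chance (0.5 on balanced classes)
#' and every random-forest permutation importance should be statistically
#' indistinguishable from zero.
#'
#' @param n_nb Rows for the Naive Bayes null, default 500.
#' @param n_rf Rows for the importance null, default 400.
#' @param n_features Feature count, default 10.
#' @param n_seeds Replicates, default 20.
#' @param n_trees Trees per forest, default 100.
#' @param seed Master seed.
#' @return List with `recall` (per-seed mean CV recall) and `importance`
#'   (seeds x features matrix of mean decreases in accuracy).
#' @export
experiment_null_calibration <- function(n_nb = 500L, n_rf = 400L,
                                        n_features = 10L, n_seeds = 20L,
                                        n_trees = 100L, seed = 1L) {
  recall <- numeric(n_seeds)
  importance <- matrix(NA_real_, n_seeds, n_features)
  for (i in seq_len(n_seeds)) {
    si <- stage_seed(seed, paste0("null", i))
    dat <- with_seed(si, {
      list(x_nb = matrix(rbinom(n_nb * n_features, 1, 0.3), n_nb,
                         dimnames = list(NULL, paste0("p", seq_len(n_features)))),
           y_nb = factor(rep(c("negative", "positive"), length.out = n_nb)[
             sample(n_nb)], levels = c("negative", "positive")),
           x_rf = matrix(rbinom(n_rf * n_features, 1, 0.3), n_rf,
                         dimnames = list(NULL, paste0("p", seq_len(n_features)))),
           y_rf = factor(rep(c("negative", "positive"), length.out = n_rf)[
             sample(n_rf)], levels = c("negative", "positive")))
    })
    cv <- nb_cv_evaluate(dat$x_nb, dat$y_nb, seed = stage_seed(si, "nb"))
    recall[i] <- cv$mean[["recall"]]
    imp <- rf_importance(dat$x_rf, dat$y_rf, n_trees = n_trees,
                         seed = stage_seed(si, "rf"))
    importance[i, ] <- imp$importance[match(colnames(dat$x_rf), imp$feature)]
  }
  colnames(importance) <- paste0("p", seq_len(n_features))
  list(recall = recall, importance = importance)
}
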