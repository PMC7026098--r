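#' Cluster characterisation statistics and pipeline orchestration
#'
#' @name report
NULL

#' Pearson chi-square test of independence
#'
#' No continuity correction (the convention that reproduces standard
#' contingency-table results on large counts); df = (r-1)(c-1), p from
#' the upper tail of the chi-square distribution.
#'
#' @param tab Matrix (or table) of non-negative integer counts, at least
#'   2 x 2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total; expected counts undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-ordering convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `p_value`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("Fisher's exact test needs a 2x2 table")
  list(p_value = stats::fisher.test(tab)$p.value)
}

profile_measures <- function() {
  list(adi_verbal = c("verbal", "nonverbal"),
       ados_category = c("Autism", "ASD", "Non-spectrum"),
       vabs_communication_category = c("dysfunctional", "normal"),
       vabs_daily_living_category = c("dysfunctional", "normal"),
       vabs_socialization_category = c("dysfunctional", "normal"),
       iq_category = c("severe_ID", "mild_ID", "normal"),
       gender = c("male", "female"))
}

#' Per-cluster clinical profile with association tests
#'
#' For each clinical measure: per-cluster category counts and percentages
#' (per-cluster percentages over a measure's categories sum to 100), and
#' an association test between category and cluster -- Pearson chi-square
#' when every expected count is at least 5, otherwise Fisher's exact test
#' for 2x2 tables (the choice is recorded).  Measures collapsing to a
#' single category are reported without a test.
#'
#' @param table Clinical data.frame with derived category columns.
#' @param labels Cluster labels aligned with rows (NA rows excluded and
#'   counted).
#' @param measures Named list measure -> category levels, default
#'   [profile_measures()] restricted to available columns.
#' @return List with `profile` (data.frame measure, category, cluster,
#'   n, pct), `tests` (data.frame measure, test, statistic, df, p_value)
#'   and `n_unlabelled`.
#' @export
cluster_profile <- function(table, labels, measures = NULL) {
  if (is.null(measures))
    measures <- profile_measures()[intersect(names(profile_measures()),
                                             names(table))]
  keep <- !is.na(labels)
  n_unlab <- sum(!keep)
  table <- table[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  prof <- list(); tests <- list()
  for (m in names(measures)) {
    x <- factor(table[[m]], levels = measures[[m]])
    tab <- table(x, factor(labels, levels = cl))
    used <- rowSums(tab) > 0
    tab <- tab[used, , drop = FALSE]
    sizes <- colSums(tab)
    for (g in seq_along(cl)) {
      prof[[paste(m, g)]] <- data.frame(
        measure = m, category = rownames(tab), cluster = cl[g],
        n = as.integer(tab[, g]),
        pct = round(100 * tab[, g] / sizes[g], 2),
        stringsAsFactors = FALSE)
    }
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      tests[[m]] <- data.frame(measure = m, test = "none",
                               statistic = NA_real_, df = NA_real_,
                               p_value = NA_real_, stringsAsFactors = FALSE)
      next
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5) || any(dim(tab) != c(2, 2))) {
      ct <- chi_square(tab)
      tests[[m]] <- data.frame(measure = m, test = "chi_square",
                               statistic = ct$statistic, df = ct$df,
                               p_value = ct$p_value, stringsAsFactors = FALSE)
    } else {
      ft <- fisher_exact(tab)
      tests[[m]] <- data.frame(measure = m, test = "fisher_exact",
                               statistic = NA_real_, df = NA_real_,
                               p_value = ft$p_value, stringsAsFactors = FALSE)
    }
  }
  profile <- do.call(rbind, prof); rownames(profile) <- NULL
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  list(profile = profile, tests = tests, n_unlabelled = n_unlab)
}

#' Default end-to-end pipeline configuration
#'
#' All thresholds of the analysis in one place: completeness retention
#' (> 0.70), feature correlation (> 0.75) with half-weighting, silhouette
#' pruning (< 0.300 removed), bootstrap iterations, caller support
#' (>= 2), CNV size (> 30 kb), control frequency (< 1%), reciprocal
#' overlap (0.5), enrichment FDR (< 0.05), SimRel grouping (> 0.7),
#' CV fold counts and IC quantiles.  Simulation block sizes the synthetic
#' cohort.
#'
#' @param seed Master seed; fans out to per-stage seeds.
#' @return Nested list of parameters.
#' @export
pipeline_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_individuals = 400L, missing_rate = 0.05,
                    n_genes = 300L, n_terms = 40L, n_controls = 300L,
                    odds_multiplier = 4, mean_cnvs = 3),
    clinical = list(completeness_threshold = 0.70, max_missing_features = 2L,
                    n_trees = 100L, max_iter = 10L),
    cluster = list(k = 2L, correlation_threshold = 0.75,
                   reduced_weight = 0.5, s_threshold = 0.300,
                   bootstrap_B = 100L),
    cnv = list(min_callers = 2L, min_size_bp = 30000, max_freq = 0.01,
               reciprocal_overlap = 0.5),
    ontology = list(fdr_threshold = 0.05, sim_threshold = 0.7),
    classify = list(n_folds = 5L, rf_folds = 10L, quantiles = 4L,
                    alpha = 1, rf_trees = 200L))
}

#' Run the full genotype-phenotype pipeline on synthetic data
#'
#' Executes clinical preprocessing, phenotype clustering, CNV filtering,
#' functional enrichment, IC stratification and classifier evaluation on
#' a self-generated synthetic cohort, writing every intermediate artifact,
#' a provenance record (parameters and per-stage seeds) and a summary to
#' `out_dir`.  Reruns with the same configuration are deterministic.
#'
#' @param config Configuration list, see [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_json <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  seed <- config$seed
  sim <- config$simulate

  # --- synthetic inputs -------------------------------------------------
  gcfg <- genome_config(n_genes = sim$n_genes, n_terms = sim$n_terms)
  genes <- generate_genes(gcfg, seed = stage_seed(seed, "genes"))
  onto_out <- generate_ontology(gcfg, genes, seed = stage_seed(seed, "ontology"))
  annmap <- build_annotation_map(onto_out$annotations, onto_out$ontology)
  enrichment <- designate_signal_terms(annmap, onto_out$ontology)
  ccfg <- cohort_config(n_individuals = sim$n_individuals,
                        missing_rate = sim$missing_rate,
                        seed = stage_seed(seed, "cohort"))
  cohort <- generate_clinical(ccfg)
  vcfg <- cnv_sim_config(mean_cnvs = sim$mean_cnvs, n_controls = sim$n_controls,
                         enrichment = enrichment,
                         odds_multiplier = sim$odds_multiplier)
  cnvs <- generate_cnvs(cohort, genes, annmap, vcfg, gcfg$chrom_lengths,
                        seed = stage_seed(seed, "cnvs"))
  write_synthetic_inputs(file.path(out_dir, "inputs"), cohort, genes,
                         onto_out, cnvs)

  stage <- "clinical"
  result <- tryCatch({
    # --- clinical -------------------------------------------------------
    filt <- filter_cohort(cohort$table,
                          config$clinical$completeness_threshold,
                          config$clinical$max_missing_features)
    imp <- impute_missforest(filt$table, n_trees = config$clinical$n_trees,
                             max_iter = config$clinical$max_iter,
                             seed = stage_seed(seed, "impute"))
    clin <- derive_categories(imp$table)
    write_tsv(clin, "clinical_completed.tsv")
    write_json(imp$report, "imputation_report.json")

    # --- clustering -----------------------------------------------------
    stage <- "cluster"
    ccl <- config$cluster
    spec <- clustering_feature_spec()
    weights <- pheno_cluster_weights(clin, threshold = ccl$correlation_threshold,
                                     spec = spec,
                                     reduced_weight = ccl$reduced_weight)
    pruned <- prune_weak(clin, weights, k = ccl$k,
                         s_threshold = ccl$s_threshold, spec = spec)
    stab <- bootstrap_stability(pruned$table, weights, k = ccl$k,
                                B = ccl$bootstrap_B,
                                seed = stage_seed(seed, "bootstrap"),
                                spec = spec)
    contrib <- feature_contribution(pruned$table, weights,
                                    pruned$assignment$labels, spec = spec)
    labels <- stats::setNames(pruned$assignment$labels,
                              pruned$table$individual_id)
    write_tsv(data.frame(individual_id = names(labels), cluster = labels),
              "cluster_assignments.tsv")
    # positive class = more severe cluster: higher nonverbal fraction
    nonverbal <- tapply(pruned$table$adi_verbal == "nonverbal", labels, mean)
    severe_cluster <- as.integer(names(which.max(nonverbal)))
    profile_stats <- cluster_profile(pruned$table, labels)
    write_tsv(profile_stats$profile, "cluster_profile.tsv")
    write_tsv(profile_stats$tests, "cluster_tests.tsv")

    # --- CNV filtering --------------------------------------------------
    stage <- "cnv"
    hc <- high_confidence_filter(cnvs$case, config$cnv$min_callers,
                                 config$cnv$min_size_bp)
    rare <- rare_filter(hc, cnvs$control, sim$n_controls,
                        config$cnv$max_freq, config$cnv$reciprocal_overlap)
    mapped <- map_to_brain_genes(rare, genes)
    write_tsv(rare, "retained_cnvs.tsv")
    write_tsv(mapped$hits, "gene_hits.tsv")

    # --- enrichment -----------------------------------------------------
    stage <- "ontology"
    clustered_ids <- intersect(names(mapped$gene_sets), names(labels))
    if (!length(clustered_ids)) stop("no individuals with both cluster and CNV data")
    query <- unique(unlist(mapped$gene_sets[clustered_ids]))
    background <- genes$gene_id[genes$brain_expressed]
    enr <- hypergeom_enrich(query, annmap, background,
                            config$ontology$fdr_threshold)
    sig <- enr$results[enr$results$significant, , drop = FALSE]
    if (!nrow(sig)) stop("no significant processes at the configured FDR")
    groups <- reduce_redundancy(sig, annmap, onto_out$ontology,
                                config$ontology$sim_threshold)
    reps <- unique(groups$representative)
    write_tsv(enr$results, "enrichment.tsv")
    write_json(groups, "term_groups.json")
    ind <- individual_ic(mapped$gene_sets[clustered_ids], reps, annmap)

    # --- classification -------------------------------------------------
    stage <- "classify"
    ord <- sig$term[sig$term %in% reps]
    mat <- build_matrix(ind$profile, labels, ind$ic_sum,
                        positive = severe_cluster, term_order = ord)
    imp_rf <- rf_importance(mat$x, mat$y, n_folds = config$classify$rf_folds,
                            n_trees = config$classify$rf_trees,
                            seed = stage_seed(seed, "rfimp"))
    cv <- nb_cv_evaluate(mat$x, mat$y, n_folds = config$classify$n_folds,
                         alpha = config$classify$alpha,
                         seed = stage_seed(seed, "nbcv"))
    strat <- ic_stratified_evaluation(mat$x, mat$y, mat$ic,
                                      q = config$classify$quantiles,
                                      n_folds = config$classify$n_folds,
                                      alpha = config$classify$alpha,
                                      seed = stage_seed(seed, "icstrat"))
    write_tsv(imp_rf, "rf_importance.tsv")
    write_tsv(strat, "ic_stratified_metrics.tsv")

    # --- summary (Tables 1-5 analogues) ---------------------------------
    stage <- "report"
    summary <- list(
      validation = list(sizes = as.list(pruned$silhouette$sizes),
                        cluster_silhouette = as.list(pruned$silhouette$cluster_means),
                        overall_silhouette = pruned$silhouette$overall,
                        stability = as.list(stab$boot_mean),
                        n_removed = length(pruned$removed_ids)),
      profile_tests = profile_stats$tests,
      enrichment = list(n_significant = nrow(sig),
                        n_after_reduction = length(reps)),
      importance = imp_rf,
      metrics = strat,
      feature_contribution = contrib,
      severe_cluster = severe_cluster)
    write_json(summary, "summary.json")
    provenance <- list(package_version = as.character(utils::packageVersion("cnvpheno")),
                       config = config,
                       stage_seeds = sapply(
                         c("genes", "ontology", "cohort", "cnvs", "impute",
                           "bootstrap", "rfimp", "nbcv", "icstrat"),
                         function(s) stage_seed(seed, s)))
    write_json(provenance, "provenance.json")
    summary
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
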