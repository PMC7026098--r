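#' Synthetic cohort, genome, ontology and CNV generators
#'
#' The generators emulate the statistical structure the downstream analysis
#' assumes: a two-latent-group clinical cohort with mixed-type measures and
#' MCAR missingness, a toy genome with non-overlapping genes and a
#' brain-expressed flag, a single-rooted GO-like DAG with gene annotations,
#' and case/control CNV calls whose gene content is enriched for designated
#' ontology terms in a targeted latent group.  The latent group drives both
#' the clinical feature distributions and the CNV term enrichment, so the
#' end-to-end genotype-phenotype classifier has recoverable signal.
#'
#' @name synth
NULL

#' Default per-group clinical distributions
#'
#' Two latent groups: a larger "milder" group (verbal, mostly normal-range
#' IQ and adaptive behaviour) and a smaller "severe" group (nonverbal, low
#' VABS and IQ).  Means and rates are loosely calibrated to the category
#' margins a severity-split ASD cohort exhibits; they are configuration,
#' not constants baked into the pipeline.
#'
#' @return Named list of per-group parameter lists.
#' @export
default_group_params <- function() {
  list(
    milder = list(
      verbal_rate = 0.97,
      ados_cat_probs = c(nonspectrum = 0.14, asd = 0.07, autism = 0.79),
      vabs_mean = c(communication = 76, daily_living = 71, socialization = 70),
      iq_mean = 95, iq_sd = 14,
      male_rate = 0.92
    ),
    severe = list(
      verbal_rate = 0.03,
      ados_cat_probs = c(nonspectrum = 0.01, asd = 0.20, autism = 0.79),
      vabs_mean = c(communication = 42, daily_living = 44, socialization = 42),
      iq_mean = 55, iq_sd = 16,
      male_rate = 0.85
    )
  )
}

#' Cohort generator configuration
#'
#' @param n_individuals Cohort size (>= 0).
#' @param group_props Two latent-group proportions summing to 1.
#' @param group_params Per-group clinical distributions, see
#'   [default_group_params()].
#' @param module4_rate Fraction of individuals assessed with ADOS module 4
#'   (these carry no severity score and are dropped by the clinical filter).
#' @param vabs_latent_sd,vabs_noise_sd Shared-latent and idiosyncratic SDs
#'   of the three VABS subscale scores; the shared latent makes the
#'   subscales strongly correlated (r ~ latent^2/(latent^2+noise^2)).
#' @param missing_rate MCAR cell-missingness fraction in [0, 1).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_individuals = 1000L,
                          group_props = c(milder = 0.65, severe = 0.35),
                          group_params = default_group_params(),
                          module4_rate = 0.06,
                          vabs_latent_sd = 12, vabs_noise_sd = 5,
                          missing_rate = 0, seed = 1L) {
  if (n_individuals < 0) stop("n_individuals must be non-negative")
  if (length(group_props) != 2 || abs(sum(group_props) - 1) > 1e-12)
    stop("group_props must be two proportions summing to 1")
  if (any(group_props < 0) || any(group_props > 1))
    stop("group_props must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(names(group_props))) names(group_props) <- names(group_params)
  structure(list(n_individuals = as.integer(n_individuals),
                 group_props = group_props, group_params = group_params,
                 module4_rate = module4_rate,
                 vabs_latent_sd = vabs_latent_sd, vabs_noise_sd = vabs_noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

empty_clinical_table <- function() {
  data.frame(individual_id = character(), adi_verbal = character(),
             ados_module = integer(), ados_severity = integer(),
             vabs_communication = integer(), vabs_daily_living = integer(),
             vabs_socialization = integer(), performance_iq = integer(),
             gender = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic clinical cohort
#'
#' Draws a latent group per individual, then the seven clinical fields plus
#' gender from the group-conditional distributions.  ADOS severity is drawn
#' uniformly within the category band (Non-spectrum 1-3, ASD 4-5, Autism
#' 6-10) and is absent for module-4 individuals.  VABS subscale scores share
#' a per-individual latent so they are mutually correlated.  Missingness, if
#' requested, is injected MCAR via [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return List with `table` (clinical data.frame), `latent` (character
#'   latent-group label per individual) and, when `missing_rate > 0`,
#'   `mask` (logical matrix of masked cells).
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_individuals
  if (n == 0L)
    return(list(table = empty_clinical_table(), latent = character(0)))
  groups <- names(config$group_props)
  res <- with_seed(config$seed, {
    latent <- sample(groups, n, replace = TRUE, prob = config$group_props)
    tab <- empty_clinical_table()[rep(1L, 0L), ]
    verbal <- character(n); module <- integer(n); severity <- rep(NA_integer_, n)
    vabs <- matrix(NA_integer_, n, 3,
                   dimnames = list(NULL, c("communication", "daily_living", "socialization")))
    iq <- integer(n); gender <- character(n)
    sev_band <- list(nonspectrum = 1:3, asd = 4:5, autism = 6:10)
    for (g in groups) {
      idx <- which(latent == g)
      if (!length(idx)) next
      p <- config$group_params[[g]]
      verbal[idx] <- ifelse(stats::runif(length(idx)) < p$verbal_rate,
                            "verbal", "nonverbal")
      module[idx] <- ifelse(stats::runif(length(idx)) < config$module4_rate,
                            4L, sample(1:3, length(idx), replace = TRUE))
      cat_draw <- sample(names(p$ados_cat_probs), length(idx), replace = TRUE,
                         prob = p$ados_cat_probs)
      sev <- vapply(cat_draw, function(cc) sample(sev_band[[cc]], 1L), integer(1))
      severity[idx] <- ifelse(module[idx] == 4L, NA_integer_, sev)
      shared <- stats::rnorm(length(idx), 0, config$vabs_latent_sd)
      for (s in colnames(vabs)) {
        raw <- p$vabs_mean[[s]] + shared +
          stats::rnorm(length(idx), 0, config$vabs_noise_sd)
        vabs[idx, s] <- as.integer(pmax(0, round(raw)))
      }
      iq[idx] <- as.integer(pmax(0, round(stats::rnorm(length(idx), p$iq_mean, p$iq_sd))))
      gender[idx] <- ifelse(stats::runif(length(idx)) < p$male_rate, "male", "female")
    }
    tab <- data.frame(
      individual_id = sprintf("ind%05d", seq_len(n)),
      adi_verbal = verbal, ados_module = module, ados_severity = severity,
      vabs_communication = vabs[, "communication"],
      vabs_daily_living = vabs[, "daily_living"],
      vabs_socialization = vabs[, "socialization"],
      performance_iq = iq, gender = gender, stringsAsFactors = FALSE)
    list(table = tab, latent = latent)
  })
  if (config$missing_rate > 0) {
    m <- inject_missingness(res$table, config$missing_rate,
                            seed = stage_seed(config$seed, "missingness"))
    res$table <- m$table
    res$mask <- m$mask
  }
  res
}

#' Clinical feature columns subject to analysis and missingness
#' @return Character vector of column names.
#' @export
clinical_feature_columns <- function() {
  c("adi_verbal", "ados_severity", "vabs_communication", "vabs_daily_living",
    "vabs_socialization", "performance_iq", "gender")
}

#' Inject missing-completely-at-random cells
#'
#' Each clinical cell (columns from [clinical_feature_columns()]) is masked
#' independently with probability `rate`.  Cells already missing (e.g. the
#' severity score of module-4 individuals) are left out of the mask.
#'
#' @param table Clinical data.frame.
#' @param rate Masking probability in [0, 1).
#' @param seed Integer seed.
#' @return List with `table` (NA-injected copy) and `mask` (logical matrix,
#'   rows = individuals, columns = clinical features; TRUE = masked here).
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  cols <- intersect(clinical_feature_columns(), names(table))
  mask <- matrix(FALSE, nrow(table), length(cols),
                 dimnames = list(table$individual_id, cols))
  if (rate > 0 && nrow(table) > 0) {
    with_seed(seed, {
      draw <- matrix(stats::runif(nrow(table) * length(cols)),
                     nrow(table), length(cols))
      mask[] <- draw < rate & !is.na(as.matrix(table[cols]))
    })
    for (j in seq_along(cols)) table[[cols[j]]][mask[, j]] <- NA
  }
  list(table = table, mask = mask)
}

#' Genome and ontology generator configuration
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bp.
#' @param n_genes Total genes, placed without overlap.
#' @param brain_expressed_fraction Fraction of genes flagged brain-expressed.
#' @param gene_length_range Uniform range of gene lengths (bp).
#' @param n_terms Ontology size (>= 1), single root.
#' @param max_parents Maximum is_a parents per non-root term.
#' @param annotations_per_gene Mean number of direct annotations per gene
#'   (each gene gets at least one).
#' @return A `genome_config` list.
#' @export
genome_config <- function(n_chromosomes = 2L,
                          chrom_lengths = c(chr1 = 3e8, chr2 = 2.4e8),
                          n_genes = 400L, brain_expressed_fraction = 0.8,
                          gene_length_range = c(5e3, 3e4),
                          n_terms = 60L, max_parents = 2L,
                          annotations_per_gene = 2) {
  if (length(chrom_lengths) != n_chromosomes)
    stop("chrom_lengths must have one entry per chromosome")
  if (brain_expressed_fraction < 0 || brain_expressed_fraction > 1)
    stop("brain_expressed_fraction must lie in [0, 1]")
  if (n_terms < 1) stop("n_terms must be at least 1")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_len(n_chromosomes))
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
                 brain_expressed_fraction = brain_expressed_fraction,
                 gene_length_range = gene_length_range,
                 n_terms = as.integer(n_terms), max_parents = as.integer(max_parents),
                 annotations_per_gene = annotations_per_gene),
            class = "genome_config")
}

#' Generate non-overlapping gene intervals
#'
#' Genes are laid out left to right per chromosome with random gaps, so
#' intervals never overlap and fixtures stay hand-countable.  Coordinates
#' are 0-based half-open (BED convention).
#'
#' @param config A [genome_config()].
#' @param seed Integer seed.
#' @return data.frame with gene_id, chrom, start, end, brain_expressed.
#' @export
generate_genes <- function(config, seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    per_chrom <- table(sample(names(config$chrom_lengths), config$n_genes,
                              replace = TRUE,
                              prob = config$chrom_lengths / sum(config$chrom_lengths)))
    rows <- list()
    gi <- 0L
    for (ch in names(config$chrom_lengths)) {
      ng <- if (ch %in% names(per_chrom)) per_chrom[[ch]] else 0L
      if (ng == 0L) next
      len <- stats::runif(ng, config$gene_length_range[1], config$gene_length_range[2])
      len <- round(len)
      slack <- config$chrom_lengths[[ch]] - sum(len)
      if (slack <= ng) stop("chromosome too short for requested genes")
      gaps <- diff(c(0, sort(stats::runif(ng, 0, slack))))
      start <- cumsum(gaps) + c(0, cumsum(len)[-ng])
      start <- round(start)
      rows[[ch]] <- data.frame(
        gene_id = sprintf("g%04d", gi + seq_len(ng)), chrom = ch,
        start = start, end = start + len, stringsAsFactors = FALSE)
      gi <- gi + ng
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    n_brain <- round(config$brain_expressed_fraction * nrow(genes))
    genes$brain_expressed <- FALSE
    genes$brain_expressed[sample(nrow(genes), n_brain)] <- TRUE
    genes
  })
}

#' Generate a single-rooted ontology DAG with gene annotations
#'
#' Terms are created in index order; each non-root term draws 1 to
#' `max_parents` parents among already-created terms, which guarantees
#' acyclicity by construction.  Each gene receives at least one direct
#' annotation; annotation targets are biased toward high-index (more
#' specific) terms.
#'
#' @param config A [genome_config()].
#' @param genes Gene table from [generate_genes()].
#' @param seed Integer seed.
#' @return List with `edges` (data.frame child, parent), `annotations`
#'   (data.frame gene_id, term_id) and `ontology` (validated
#'   [load_ontology()] object).
#' @export
generate_ontology <- function(config, genes, seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  nt <- config$n_terms
  terms <- sprintf("T%04d", seq_len(nt))
  out <- with_seed(seed, {
    edges <- NULL
    if (nt > 1) {
      child <- parent <- character(0)
      for (i in 2:nt) {
        np <- sample(seq_len(config$max_parents), 1L)
        par <- sample(seq_len(i - 1L), min(np, i - 1L))
        child <- c(child, rep(terms[i], length(par)))
        parent <- c(parent, terms[par])
      }
      edges <- data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(child = character(0), parent = character(0))
    }
    n_ann <- pmax(1L, stats::rpois(nrow(genes), config$annotations_per_gene))
    n_ann <- pmin(n_ann, nt)
    # bias toward specific (late) terms so IC spreads out
    w <- seq_len(nt)
    ann <- data.frame(
      gene_id = rep(genes$gene_id, n_ann),
      term_id = terms[unlist(lapply(n_ann, function(k)
        sample.int(nt, k, prob = w)))],
      stringsAsFactors = FALSE)
    ann <- unique(ann)
    list(edges = edges, annotations = ann)
  })
  out$ontology <- load_ontology(out$edges, terms = terms)
  out
}

#' CNV simulator configuration
#'
#' @param mean_cnvs Mean CNVs per individual (Poisson).
#' @param size_meanlog,size_sdlog Log-normal CNV size parameters (bp).
#' @param caller_probs Probabilities of 1, 2 or 3 supporting callers.
#' @param dup_rate Probability a CNV is a duplication (else deletion).
#' @param n_controls Control cohort size for frequency estimation.
#' @param enrichment Named list mapping latent group -> character vector of
#'   ontology terms whose annotated genes that group's CNVs preferentially
#'   hit.
#' @param base_target_rate Baseline probability that a CNV is aimed at a
#'   designated-term gene in a non-targeted group.
#' @param odds_multiplier Multiplier (>= 1) applied to the baseline rate in
#'   the targeted group; 1 means no enrichment.
#' @param informative_fraction Fraction of each group's individuals that
#'   carry the targeted signal at all (the rest receive background CNVs
#'   only), letting signal be confined to a high-information subset.
#' @param common_terms Ontology terms whose genes every case individual's
#'   CNVs aim at (group-independently) at `common_target_rate`; emulates
#'   the shared functional load of CNV-prone regions and keeps
#'   noise-profile individuals in the analysis.
#' @param common_target_rate Per-CNV probability of aiming at a
#'   common-term gene, default 0.
#' @param common_region_rate Fraction of control individuals carrying each
#'   of two recurrent polymorphic regions (gives the rare-variant filter
#'   something to remove); cases carry them at `common_case_rate`.
#' @param common_case_rate See above.
#' @return A `cnv_sim_config` list.
#' @export
cnv_sim_config <- function(mean_cnvs = 3, size_meanlog = log(8e4),
                           size_sdlog = 0.5,
                           caller_probs = c(`1` = 0.25, `2` = 0.5, `3` = 0.25),
                           dup_rate = 0.45, n_controls = 500L,
                           enrichment = list(), base_target_rate = 0.08,
                           odds_multiplier = 1, informative_fraction = 1,
                           common_terms = character(0),
                           common_target_rate = 0,
                           common_region_rate = 0.03, common_case_rate = 0.05) {
  if (odds_multiplier < 1) stop("odds_multiplier must be >= 1")
  if (base_target_rate < 0 || base_target_rate * odds_multiplier > 1)
    stop("base_target_rate * odds_multiplier must lie in [0, 1]")
  if (informative_fraction < 0 || informative_fraction > 1)
    stop("informative_fraction must lie in [0, 1]")
  structure(list(mean_cnvs = mean_cnvs, size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog, caller_probs = caller_probs,
                 dup_rate = dup_rate, n_controls = as.integer(n_controls),
                 enrichment = enrichment, base_target_rate = base_target_rate,
                 odds_multiplier = odds_multiplier,
                 informative_fraction = informative_fraction,
                 common_terms = common_terms,
                 common_target_rate = common_target_rate,
                 common_region_rate = common_region_rate,
                 common_case_rate = common_case_rate),
            class = "cnv_sim_config")
}

empty_cnv_table <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             type = character(), individual_id = character(),
             callers = character(), stringsAsFactors = FALSE)
}

# draw one CNV interval; targeted CNVs are centred on a gene so they
# always overlap it; sizes exceeding the chromosome are resampled
draw_cnv <- function(chrom_lengths, genes, config, target_gene = NULL) {
  repeat {
    size <- round(stats::rlnorm(1, config$size_meanlog, config$size_sdlog))
    if (!is.null(target_gene)) {
      chrom <- target_gene$chrom
      if (size > chrom_lengths[[chrom]]) next
      lo <- max(0, target_gene$end - size)
      hi <- min(chrom_lengths[[chrom]] - size, target_gene$start)
      if (hi < lo) { start <- max(0, min(target_gene$start, chrom_lengths[[chrom]] - size)) }
      else start <- round(stats::runif(1, lo, hi))
    } else {
      chrom <- sample(names(chrom_lengths), 1L,
                      prob = chrom_lengths / sum(chrom_lengths))
      if (size > chrom_lengths[[chrom]]) next
      start <- round(stats::runif(1, 0, chrom_lengths[[chrom]] - size))
    }
    return(list(chrom = chrom, start = start, end = start + size))
  }
}

#' Simulate case and control CNV calls
#'
#' Per individual, a Poisson number of CNVs is drawn.  In latent groups with
#' designated enrichment terms, each CNV of an "informative" individual is,
#' with probability `base_target_rate * odds_multiplier`, centred on a gene
#' annotated (after propagation) to one of the designated terms; other
#' groups aim at the same designated-term genes at the baseline rate, and
#' everything else is placed uniformly at random.  Controls carry only
#' background CNVs plus the recurrent polymorphic regions.
#'
#' @param cohort Output of [generate_clinical()] (uses `latent` and the
#'   table's individual ids).
#' @param genes Gene table from [generate_genes()].
#' @param annmap Propagated [build_annotation_map()] for the toy ontology.
#' @param config A [cnv_sim_config()].
#' @param chrom_lengths Named chromosome lengths.
#' @param seed Integer seed.
#' @return List with `case` and `control` CNV data.frames (BED-like,
#'   0-based half-open) and `informative` (ids of signal carriers).
#' @export
generate_cnvs <- function(cohort, genes, annmap, config, chrom_lengths,
                          seed = 1L) {
  stopifnot(inherits(config, "cnv_sim_config"))
  ids <- cohort$table$individual_id
  if (length(ids) == 0L)
    return(list(case = empty_cnv_table(), control = empty_cnv_table(),
                informative = character(0)))
  latent <- cohort$latent
  # per-set, per-term gene pools; targeting picks a term uniformly and
  # then a gene within it, so every designated term is hit at the same
  # rate regardless of its gene count
  targeting <- config$enrichment
  if (length(config$common_terms))
    targeting <- c(targeting, list(.common = config$common_terms))
  term_pools <- lapply(targeting, function(ts) {
    pools <- lapply(annmap$term_genes[ts], intersect, genes$gene_id)
    pools[lengths(pools) > 0]
  })
  gene_rows <- genes; rownames(gene_rows) <- gene_rows$gene_id
  with_seed(seed, {
    informative <- character(0)
    for (g in names(config$enrichment)) {
      memb <- ids[latent == g]
      informative <- c(informative,
                       memb[stats::runif(length(memb)) < config$informative_fraction])
    }
    sample_callers <- function(n) {
      k <- sample(as.integer(names(config$caller_probs)), n, replace = TRUE,
                  prob = config$caller_probs)
      vapply(k, function(kk)
        paste(sample(c("callerA", "callerB", "callerC"), kk), collapse = ";"),
        character(1))
    }
    make_cnvs <- function(owner_ids, owner_groups, is_case) {
      rows <- vector("list", length(owner_ids))
      sets <- names(targeting)
      for (i in seq_along(owner_ids)) {
        n_cnv <- stats::rpois(1, config$mean_cnvs)
        if (n_cnv == 0) next
        grp <- owner_groups[i]
        # every designated term set is aimed at with the baseline rate and
        # the common set (if any) at its own rate; an informative
        # individual's own set gets the multiplied rate, so a multiplier
        # of 1 leaves all groups exchangeable
        rates <- numeric(0)
        if (is_case && length(sets)) {
          rates <- stats::setNames(rep(config$base_target_rate, length(sets)),
                                   sets)
          if (".common" %in% sets) rates[".common"] <- config$common_target_rate
          if (!is.na(grp) && grp %in% sets && owner_ids[i] %in% informative)
            rates[grp] <- config$base_target_rate * config$odds_multiplier
          if (sum(rates) > 1)
            stop("targeting rates sum above 1; lower base_target_rate or odds_multiplier")
        }
        cnv <- vector("list", n_cnv)
        for (j in seq_len(n_cnv)) {
          tgt <- NULL
          if (length(rates)) {
            u <- stats::runif(1)
            pick <- which(u < cumsum(rates))
            if (length(pick)) {
              pools <- term_pools[[sets[pick[1]]]]
              if (length(pools)) {
                pool <- pools[[sample.int(length(pools), 1L)]]
                tgt <- gene_rows[pool[sample.int(length(pool), 1L)], ]
              }
            }
          }
          cnv[[j]] <- draw_cnv(chrom_lengths, genes, config, tgt)
        }
        rows[[i]] <- data.frame(
          chrom = vapply(cnv, `[[`, character(1), "chrom"),
          start = vapply(cnv, `[[`, numeric(1), "start"),
          end = vapply(cnv, `[[`, numeric(1), "end"),
          type = ifelse(stats::runif(n_cnv) < config$dup_rate, "dup", "del"),
          individual_id = owner_ids[i],
          callers = sample_callers(n_cnv), stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (is.null(out)) empty_cnv_table() else out
    }
    case <- make_cnvs(ids, latent, TRUE)
    control_ids <- sprintf("ctl%05d", seq_len(config$n_controls))
    control <- make_cnvs(control_ids, rep(NA_character_, config$n_controls), FALSE)
    # recurrent polymorphic regions, present in both cohorts above the
    # rarity threshold so the rare-variant filter has work to do
    common <- data.frame(
      chrom = names(chrom_lengths)[seq_len(min(2, length(chrom_lengths)))],
      start = round(0.4 * unlist(chrom_lengths)[seq_len(min(2, length(chrom_lengths)))]))
    common$end <- common$start + 6e4
    add_common <- function(tab, owner_ids, rate) {
      for (r in seq_len(nrow(common))) {
        carriers <- owner_ids[stats::runif(length(owner_ids)) < rate]
        if (!length(carriers)) next
        tab <- rbind(tab, data.frame(
          chrom = common$chrom[r], start = common$start[r], end = common$end[r],
          type = "dup", individual_id = carriers,
          callers = sample_callers(length(carriers)), stringsAsFactors = FALSE))
      }
      tab
    }
    case <- add_common(case, ids, config$common_case_rate)
    control <- add_common(control, control_ids, config$common_region_rate)
    rownames(case) <- rownames(control) <- NULL
    list(case = case, control = control, informative = sort(unique(informative)))
  })
}

#' Write the full set of synthetic inputs as plain-text files
#'
#' Emits the clinical TSV, case/control CNV TSVs (BED-like, 0-based
#' half-open), gene BED with a brain_expressed column, the ontology as both
#' an is_a edge-list TSV and a minimal OBO file, and the annotation TSV.
#'
#' @param dir Output directory (created if absent).
#' @param cohort,genes,onto,cnvs Outputs of the respective generators.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_inputs <- function(dir, cohort, genes, onto, cnvs) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             genes = file.path(dir, "genes.bed"),
             edges = file.path(dir, "ontology_edges.tsv"),
             obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             case_cnvs = file.path(dir, "case_cnvs.tsv"),
             control_cnvs = file.path(dir, "control_cnvs.tsv"))
  write_tsv <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(cohort$table, paths["clinical"])
  write_tsv(genes, paths["genes"])
  write_tsv(onto$edges, paths["edges"])
  write_obo(onto$ontology, paths["obo"])
  write_tsv(onto$annotations, paths["annotations"])
  write_tsv(cnvs$case, paths["case_cnvs"])
  write_tsv(cnvs$control, paths["control_cnvs"])
  invisible(paths)
}
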