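# shared synthetic "world" for CNV-related tests: toy genome, ontology,
# cohort and CNV calls with optional enrichment targeting

make_cnv_world <- function(n = 300, multiplier = 1, seed = 1,
                           informative_fraction = 1) {
  gcfg <- genome_config(n_genes = 120, n_terms = 25,
                        chrom_lengths = c(chr1 = 4e7, chr2 = 3e7))
  genes <- generate_genes(gcfg, seed = seed)
  onto <- generate_ontology(gcfg, genes, seed = seed)
  annmap <- build_annotation_map(onto$annotations, onto$ontology)
  enrichment <- cnvpheno:::designate_signal_terms(
    annmap, onto$ontology, min_genes = 3, max_genes = 40)
  cohort <- generate_clinical(cohort_config(n, seed = seed))
  cfg <- cnv_sim_config(enrichment = enrichment, odds_multiplier = multiplier,
                        base_target_rate = 0.04, n_controls = 50,
                        informative_fraction = informative_fraction)
  cnvs <- generate_cnvs(cohort, genes, annmap, cfg, gcfg$chrom_lengths,
                        seed = seed)
  list(cnvs = cnvs, genes = genes, annmap = annmap, cohort = cohort,
       enrichment = enrichment, chrom_lengths = gcfg$chrom_lengths)
}

term_hit_rate <- function(world, group, terms) {
  hits <- map_to_brain_genes(world$cnvs$case, world$genes)$gene_sets
  tg <- unique(unlist(world$annmap$term_genes[terms]))
  ids <- world$cohort$table$individual_id[world$cohort$latent == group]
  mean(vapply(ids, function(i)
    length(intersect(hits[[i]], tg)) > 0, logical(1)))
}
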