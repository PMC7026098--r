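# six-term fixture with hand-assignable counts:
#   root <- a <- b ; root <- c ; a <- d ; c <- e
toy_ontology <- function() {
  load_ontology(data.frame(
    child  = c("a", "b", "c", "d", "e"),
    parent = c("root", "a", "root", "a", "c"),
    stringsAsFactors = FALSE))
}

toy_annmap <- function() {
  # 10 genes; direct annotation pattern gives propagated counts
  # root 10, a 7, b 2, c 3, d 2, e 1 (g07 annotated under both branches)
  ann <- data.frame(
    gene_id = c("g01", "g02", "g03", "g04", "g05", "g06",
                "g07", "g07", "g08", "g09", "g10"),
    term_id = c("b", "b", "d", "d", "a", "a",
                "a", "e", "c", "c", "root"),
    stringsAsFactors = FALSE)
  build_annotation_map(ann, toy_ontology())
}

test_that("ontology loading validates structure", {
  single <- load_ontology(data.frame(child = character(),
                                     parent = character()),
                          terms = "solo")
  expect_equal(single$root, "solo")

  expect_error(load_ontology(data.frame(child = c("a", "b", "c"),
                                        parent = c("b", "c", "a"))),
               "cycle")
  expect_error(load_ontology(data.frame(child = c("a", "b"),
                                        parent = c("r1", "r2"))),
               "multiple roots")
  onto <- toy_ontology()
  expect_setequal(onto$ancestors[["b"]], c("b", "a", "root"))
  expect_setequal(onto$ancestors[["e"]], c("e", "c", "root"))
})

test_that("minimal OBO stanzas load to the same graph as the edge list", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root process", "",
               "[Term]", "id: GO:2", "name: child one",
               "is_a: GO:1 ! root process", "",
               "[Term]", "id: GO:3", "name: child two", "is_a: GO:1", "",
               "[Term]", "id: GO:4", "is_a: GO:2", "is_a: GO:3", "",
               "[Term]", "id: GO:5", "is_a: GO:4",
               "", "[Typedef]", "id: part_of"), path)
  ob <- load_ontology(path)
  ref <- load_ontology(data.frame(
    child = c("GO:2", "GO:3", "GO:4", "GO:4", "GO:5"),
    parent = c("GO:1", "GO:1", "GO:2", "GO:3", "GO:4")))
  expect_setequal(ob$terms, ref$terms)
  expect_equal(ob$root, "GO:1")
  expect_equal(ob$names[["GO:2"]], "child one")
  for (t in ob$terms)
    expect_setequal(ob$ancestors[[t]], ref$ancestors[[t]])
})

test_that("annotation propagation obeys the true-path rule and IC identities", {
  am <- toy_annmap()
  expect_setequal(am$propagated[["g01"]], c("b", "a", "root"))
  expect_setequal(am$propagated[["g10"]], "root")
  expect_equal(am$n_genes[["root"]], 10)
  expect_equal(am$n_genes[["a"]], 7)
  expect_equal(am$p[["root"]], 1)
  expect_equal(am$ic[["root"]], 0)
  # IC never decreases child -> parent
  onto <- toy_ontology()
  el <- igraph::as_edgelist(onto$graph)
  for (r in seq_len(nrow(el)))
    expect_gte(am$ic[[el[r, 1]]], am$ic[[el[r, 2]]])

  expect_error(build_annotation_map(
    data.frame(gene_id = "g1", term_id = "nope"), onto), "nope")
})

test_that("propagation equals the brute-force ancestor closure on random DAGs", {
  gcfg <- genome_config(n_terms = 50, n_genes = 40,
                        chrom_lengths = c(chr1 = 4e6, chr2 = 4e6))
  genes <- generate_genes(gcfg, seed = 1)
  for (s in 1:5) {
    oo <- generate_ontology(gcfg, genes, seed = s)
    am <- build_annotation_map(oo$annotations, oo$ontology)
    direct <- split(oo$annotations$term_id, oo$annotations$gene_id)
    for (g in sample(names(direct), 10)) {
      want <- sort(unique(unlist(lapply(direct[[g]], brute_ancestors,
                                        edges = oo$edges))))
      expect_equal(am$propagated[[g]], want)
    }
  }
})

test_that("hypergeometric enrichment matches urn arithmetic and BH hand values", {
  am <- toy_annmap()
  # query = both genes of term b; background all 10 annotated genes
  res <- hypergeom_enrich(c("g01", "g02"), am)$results
  row_b <- res[res$term == "b", ]
  expect_equal(row_b$p_value, 1 / choose(10, 2))   # both draws marked
  expect_equal(row_b$k, 2)
  # k = 0 never significant: P(X >= 0) = 1
  row_e <- res[res$term == "e", ]
  expect_equal(row_e$p_value, 1)
  expect_false(row_e$significant)
  # root term: k = n, K = N -> p = 1
  expect_equal(res$p_value[res$term == "root"], 1)

  # unannotated query genes dropped and counted
  enr <- hypergeom_enrich(c("g01", "g02", "mystery"), am)
  expect_equal(enr$n_dropped, 1)
  expect_error(hypergeom_enrich("mystery", am), "no annotated")

  # BH on (0.01, 0.02, 0.03) -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  # fdr column reproduces the independent step-up definition
  m <- nrow(res)
  ord <- order(res$p_value)
  stepup <- rev(cummin(rev(res$p_value[ord] * m / seq_len(m))))
  expect_equal(res$fdr[ord], pmin(1, stepup))
})

test_that("hypergeometric p-values equal exhaustive enumeration (small urns)", {
  for (N in c(6, 9, 12)) for (K in c(2, floor(N / 2))) for (n in c(2, 4)) {
    am_p <- stats::phyper(seq(0, n) - 1, K, N - K, n, lower.tail = FALSE)
    for (k in 0:min(K, n))
      expect_equal(am_p[k + 1], brute_hyper_upper(k, K, N, n),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("SimRel matches hand-computed MICA arithmetic", {
  am <- toy_annmap()
  onto <- toy_ontology()
  # identity: simrel(t, t) = 1 - p(t)
  expect_equal(simrel("b", "b", am, onto), 1 - 0.2)
  # root against anything: IC(MICA) = 0
  expect_equal(simrel("root", "b", am, onto), 0)
  expect_equal(simrel("root", "root", am, onto), 0)
  # siblings under a: MICA = a, p(a) = 0.7
  ic <- am$ic
  expect_equal(simrel("b", "d", am, onto),
               2 * ic[["a"]] / (ic[["b"]] + ic[["d"]]) * (1 - 0.7))
  # cross-branch: MICA = root -> 0
  expect_equal(simrel("b", "e", am, onto), 0)
  # symmetry and range over all pairs
  for (t1 in onto$terms) for (t2 in onto$terms) {
    s12 <- simrel(t1, t2, am, onto)
    expect_equal(s12, simrel(t2, t1, am, onto))
    expect_gte(s12, 0); expect_lt(s12, 1)
  }
  expect_error(simrel("b", "zzz", am, onto), "unknown")
})

test_that("redundancy grouping is greedy by p-value with a strict threshold", {
  # chain root <- a <- b <- f plus an unrelated branch c; 20 genes make
  # the chain specific enough that b and f merge: simrel(b, f) = 0.782,
  # simrel(a, b) = 0.768, simrel(a, f) = 0.659, c against the chain 0
  onto <- load_ontology(data.frame(child = c("a", "b", "f", "c"),
                                   parent = c("root", "a", "b", "root")))
  am <- build_annotation_map(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", paste0("g", 6:20)),
    term_id = c("f", "b", "a", "c", "c", rep("root", 15)),
    stringsAsFactors = FALSE), onto)
  s_bf <- simrel("b", "f", am, onto)
  expect_equal(s_bf,
               2 * am$ic[["b"]] / (am$ic[["b"]] + am$ic[["f"]]) *
                 (1 - am$p[["b"]]))
  expect_gt(s_bf, 0.7)

  # all pairwise similarities <= threshold: every term its own group
  res_far <- reduce_redundancy(
    data.frame(term = c("b", "c"), p_value = c(0.01, 0.02)),
    am, onto, sim_threshold = 0.7)
  expect_equal(attr(res_far, "n_groups"), 2)
  expect_equal(res_far$representative, c("b", "c"))

  # f joins b's group; the lower-p term is the representative
  res_near <- reduce_redundancy(
    data.frame(term = c("f", "b"), p_value = c(0.03, 0.005)),
    am, onto, sim_threshold = 0.7)
  expect_equal(res_near$representative[res_near$term == "f"], "b")
  expect_equal(res_near$similarity[res_near$term == "f"], s_bf)

  # 4 terms, exactly one pair above a 0.775 threshold -> 3 groups
  res4 <- reduce_redundancy(
    data.frame(term = c("b", "f", "a", "c"),
               p_value = c(0.001, 0.002, 0.003, 0.004)),
    am, onto, sim_threshold = 0.775)
  expect_equal(attr(res4, "n_groups"), 3)
  # audit: merged terms always exceed the threshold against their rep
  merged <- res4[res4$term != res4$representative, ]
  for (r in seq_len(nrow(merged)))
    expect_gt(simrel(merged$term[r], merged$representative[r], am, onto),
              0.775)
  expect_error(reduce_redundancy(data.frame(term = character(),
                                            p_value = numeric()), am, onto),
               "no terms")
})

test_that("per-individual profiles, IC sums and exclusion flags are exact", {
  am <- toy_annmap()
  gene_sets <- list(i1 = c("g01", "g08"),   # hits b (and a, root), c
                    i2 = "g10",             # root only
                    i3 = character(0))
  res <- individual_ic(gene_sets, c("b", "c"), am)
  expect_equal(res$profile["i1", ], c(b = 1L, c = 1L))
  expect_equal(res$profile["i2", ], c(b = 0L, c = 0L))
  expect_equal(res$ic_sum[["i1"]], am$ic[["b"]] + am$ic[["c"]])
  expect_equal(res$ic_sum[["i2"]], 0)
  expect_setequal(res$excluded, c("i2", "i3"))

  # additivity with stated IC values
  am2 <- am
  res2 <- individual_ic(list(x = c("g01")), c("b"), am)
  expect_equal(res2$ic_sum[["x"]], am$ic[["b"]])
})

test_that("IC quantiles are near-equal with earlier quantiles taking extras", {
  ic1300 <- setNames(seq(1300, 1, -1), paste0("i", 1:1300))
  q <- ic_quantiles(ic1300, 4)
  expect_equal(as.integer(table(q)), rep(325L, 4))
  # the highest-IC individuals land in quantile 1
  expect_true(all(q[1:325] == 1))

  q2 <- ic_quantiles(setNames(runif(1301), paste0("i", 1:1301)), 4)
  expect_equal(as.integer(table(q2)), c(326L, 325L, 325L, 325L))

  # all-equal ICs: stable order decides, sizes unchanged
  q3 <- ic_quantiles(setNames(rep(1, 8), paste0("i", 1:8)), 4)
  expect_equal(unname(q3), rep(1:4, each = 2))
  expect_error(ic_quantiles(setNames(1, "a"), 0), "q must")
  expect_error(ic_quantiles(setNames(c(1, 2), c("a", "b")), 3), "at least q")
})
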