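#' Ontology handling: DAG validation, annotation propagation,
#' hypergeometric enrichment, SimRel similarity, redundancy reduction,
#' per-individual information content
#'
#' @name ontology
NULL

#' Load and validate an ontology DAG
#'
#' Accepts an is_a edge list (data.frame with `child`, `parent` columns or
#' a two-column TSV path) or a minimal OBO file ([Term] stanzas with id,
#' name, is_a).  The graph must be acyclic with every term reaching a
#' single root.
#'
#' @param x Edge data.frame or file path (`.obo` parsed as OBO, otherwise
#'   TSV).
#' @param terms Optional full term vector (covers isolated terms absent
#'   from the edge list; a single isolated term is the root of a trivial
#'   ontology, several are an error).
#' @return An `ontology` object: list with `terms`, `root`, `graph`
#'   (igraph, edges child -> parent), `ancestors` (list incl. self) and
#'   `names` (term labels when provided by OBO input).
#' @export
load_ontology <- function(x, terms = NULL) {
  term_names <- NULL
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.obo$", x)) {
      ob <- parse_obo(x)
      edges <- ob$edges; terms <- union(terms, ob$terms)
      term_names <- ob$names
    } else {
      edges <- utils::read.delim(x, header = TRUE, stringsAsFactors = FALSE)
      names(edges)[1:2] <- c("child", "parent")
    }
  } else edges <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(edges) && !all(c("child", "parent") %in% names(edges)))
    stop("edge list needs 'child' and 'parent' columns")
  all_terms <- union(terms, unique(c(edges$child, edges$parent)))
  if (!length(all_terms)) stop("empty ontology")
  g <- igraph::graph_from_data_frame(
    edges[c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = all_terms))
  if (!igraph::is_dag(g)) {
    # name one offending strongly connected component for the error
    sc <- igraph::components(g, mode = "strong")
    bad <- names(sc$membership)[sc$membership == which(sc$csize > 1)[1]]
    stop("ontology contains a cycle involving: ", paste(bad, collapse = ", "))
  }
  roots <- all_terms[igraph::degree(g, mode = "out") == 0]
  if (length(roots) > 1)
    stop("multiple roots: ", paste(roots, collapse = ", "))
  # every term must reach the root
  anc <- igraph::ego(g, order = igraph::vcount(g), mode = "out")
  anc <- lapply(anc, function(v) v$name)
  names(anc) <- all_terms
  unreachable <- all_terms[!vapply(anc, function(a) roots %in% a, logical(1))]
  if (length(unreachable))
    stop("terms not connected to the root: ",
         paste(unreachable, collapse = ", "))
  structure(list(terms = all_terms, root = roots, graph = g,
                 ancestors = anc, names = term_names),
            class = "ontology")
}

#' Parse a minimal OBO file
#'
#' Reads `[Term]` stanzas, keeping `id:`, `name:` and `is_a:` lines only.
#'
#' @param path OBO file path.
#' @return List with `terms`, `edges` (child, parent) and `names`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0); nm <- character(0)
  child <- parent <- character(0)
  cur <- NULL; in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (grepl("^id:", ln)) {
      cur <- sub("^id:\\s*", "", ln)
      terms <- c(terms, cur)
    } else if (grepl("^name:", ln) && !is.null(cur)) {
      nm[cur] <- sub("^name:\\s*", "", ln)
    } else if (grepl("^is_a:", ln) && !is.null(cur)) {
      p <- sub("^is_a:\\s*", "", ln)
      p <- sub("\\s*!.*$", "", p)
      child <- c(child, cur); parent <- c(parent, p)
    }
  }
  list(terms = terms,
       edges = data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE),
       names = nm)
}

#' Write an ontology as a minimal OBO file
#' @param onto An `ontology` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  el <- igraph::as_edgelist(onto$graph)
  for (t in onto$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    if (!is.null(onto$names) && t %in% names(onto$names))
      writeLines(paste0("name: ", onto$names[[t]]), con)
    for (p in el[el[, 1] == t, 2]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Propagate annotations and compute term probabilities and IC
#'
#' Applies the true-path rule: a gene annotated to a term is annotated to
#' all of its ancestors.  Term probability is p(t) = |genes(t)| /
#' |genes(root)| over propagated sets; information content is
#' IC(t) = -ln p(t), so IC(root) = 0 and IC never decreases along
#' child edges.
#'
#' @param annotations data.frame with `gene_id`, `term_id` (direct
#'   annotations).
#' @param onto An `ontology` object.
#' @return An `annotation_map`: list with `direct`, `propagated` (gene ->
#'   terms), `term_genes` (term -> genes, propagated), `n_genes`, `p`,
#'   `ic` (named per term), `genes`, `root`.
#' @export
build_annotation_map <- function(annotations, onto) {
  unknown <- setdiff(unique(annotations$term_id), onto$terms)
  if (length(unknown))
    stop("annotation(s) to unknown term(s): ", paste(unknown, collapse = ", "))
  direct <- lapply(split(annotations$term_id, annotations$gene_id), unique)
  propagated <- lapply(direct, function(ts)
    sort(unique(unlist(onto$ancestors[ts]))))
  term_genes <- lapply(stats::setNames(onto$terms, onto$terms),
                       function(t) character(0))
  inv <- split(rep(names(propagated), lengths(propagated)),
               unlist(propagated))
  term_genes[names(inv)] <- lapply(inv, function(g) sort(unique(g)))
  n_genes <- vapply(term_genes, length, integer(1))
  n_root <- n_genes[[onto$root]]
  if (n_root == 0) stop("no gene reaches the root; empty annotation set")
  p <- n_genes / n_root
  ic <- -log(p)
  ic[p == 0] <- Inf
  structure(list(direct = direct, propagated = propagated,
                 term_genes = term_genes, n_genes = n_genes, p = p, ic = ic,
                 genes = sort(names(direct)), root = onto$root),
            class = "annotation_map")
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each term with at least one annotated background gene, tests
#' overrepresentation of the term's genes in the query with the upper-tail
#' hypergeometric probability P(X >= k) (population N = annotated
#' background genes, K = term genes in background, n = annotated query
#' genes), followed by Benjamini-Hochberg adjustment over all tested
#' terms.  Query genes without any annotation are dropped and counted.
#'
#' @param query Character vector of query gene ids.
#' @param annmap An `annotation_map`.
#' @param background Background gene ids (default: all annotated genes in
#'   the map).
#' @param fdr_threshold Significance threshold on the adjusted p,
#'   default 0.05.
#' @return List with `results` (data.frame term, k, K, n, N, p_value,
#'   fdr, significant; ordered by p), `n_dropped` (unannotated query
#'   genes), `query_used`.
#' @export
hypergeom_enrich <- function(query, annmap, background = NULL,
                             fdr_threshold = 0.05) {
  if (is.null(background)) background <- annmap$genes
  background <- intersect(background, annmap$genes)
  dropped <- setdiff(query, background)
  query <- intersect(unique(query), background)
  if (!length(query)) stop("no annotated query genes")
  N <- length(background)
  n <- length(query)
  term_in_bg <- lapply(annmap$term_genes, intersect, background)
  K <- vapply(term_in_bg, length, integer(1))
  test <- names(K)[K > 0]
  k <- vapply(term_in_bg[test], function(g) length(intersect(g, query)),
              integer(1))
  p <- stats::phyper(k - 1, K[test], N - K[test], n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(term = test, k = k, K = K[test], n = n, N = N,
                    p_value = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  list(results = res, n_dropped = length(dropped), query_used = query)
}

#' SimRel semantic similarity between two terms
#'
#' simrel(t1, t2) = [2 IC(MICA) / (IC(t1) + IC(t2))] * (1 - p(MICA)),
#' where the MICA is the common ancestor (ancestor sets include the terms
#' themselves) with maximal IC.  When both terms are the root
#' (IC(t1) + IC(t2) = 0) the similarity is 0; simrel(t, t) = 1 - p(t).
#'
#' @param t1,t2 Term ids.
#' @param annmap An `annotation_map` (both terms must have p > 0).
#' @param onto An `ontology` object.
#' @return Similarity in [0, 1).
#' @export
simrel <- function(t1, t2, annmap, onto) {
  for (t in c(t1, t2)) {
    if (!t %in% onto$terms) stop("unknown term: ", t)
    if (annmap$p[[t]] == 0) stop("term without annotations: ", t)
  }
  common <- intersect(onto$ancestors[[t1]], onto$ancestors[[t2]])
  ic12 <- annmap$ic[[t1]] + annmap$ic[[t2]]
  if (ic12 == 0) return(0)
  mica <- common[which.max(annmap$ic[common])]
  2 * annmap$ic[[mica]] / ic12 * (1 - annmap$p[[mica]])
}

#' Group redundant enriched terms by semantic similarity
#'
#' Terms are processed in increasing p-value order; each term joins the
#' first existing group whose representative it resembles with SimRel
#' strictly above `sim_threshold`, otherwise it founds a new group.  The
#' representative is the group's lowest-p term (its founder).
#'
#' @param results Enrichment results data.frame (needs `term`,
#'   `p_value`); typically the significant subset.
#' @param annmap An `annotation_map`.
#' @param onto An `ontology` object.
#' @param sim_threshold Grouping threshold (strict `>`), default 0.7.
#' @return data.frame with `term`, `representative`, `similarity` (to the
#'   representative; NA for founders), plus an `n_groups` attribute.
#' @export
reduce_redundancy <- function(results, annmap, onto, sim_threshold = 0.7) {
  if (!nrow(results)) stop("no terms to group")
  ord <- order(results$p_value, results$term)
  terms <- results$term[ord]
  reps <- character(0)
  out <- data.frame(term = terms, representative = NA_character_,
                    similarity = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    t <- terms[i]
    joined <- FALSE
    for (r in reps) {
      s <- simrel(t, r, annmap, onto)
      if (s > sim_threshold) {
        out$representative[i] <- r
        out$similarity[i] <- s
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, t)
      out$representative[i] <- t
    }
  }
  attr(out, "n_groups") <- length(reps)
  out
}

#' Per-individual disrupted-process profile and information content
#'
#' A process is disrupted in an individual iff at least one of the
#' individual's hit genes is annotated (after propagation) to it.  The
#' individual's IC is the sum of the IC values of all disrupted
#' processes; individuals disrupting no process are flagged for
#' exclusion.
#'
#' @param gene_sets Named list individual -> hit gene ids (from
#'   [map_to_brain_genes()]).
#' @param sig_terms Character vector of significant process terms.
#' @param annmap An `annotation_map`.
#' @return List with `profile` (binary matrix individuals x terms),
#'   `ic_sum` (named numeric) and `excluded` (ids with all-zero
#'   profiles).
#' @export
individual_ic <- function(gene_sets, sig_terms, annmap) {
  ids <- names(gene_sets)
  profile <- matrix(0L, length(ids), length(sig_terms),
                    dimnames = list(ids, sig_terms))
  for (t in sig_terms) {
    tg <- annmap$term_genes[[t]]
    profile[, t] <- vapply(gene_sets, function(g)
      as.integer(length(intersect(g, tg)) > 0), integer(1))
  }
  ic_sum <- as.numeric(profile %*% annmap$ic[sig_terms])
  names(ic_sum) <- ids
  excluded <- ids[rowSums(profile) == 0]
  list(profile = profile, ic_sum = ic_sum, excluded = excluded)
}

#' Quantile labels for per-individual IC
#'
#' Individuals are ranked by IC descending and split into `q` groups of
#' near-equal size; when n is not divisible by q, earlier (higher-IC)
#' quantiles take the extra individual.  Ties are broken by the stable
#' input order.
#'
#' @param ic Named numeric vector of IC sums.
#' @param q Number of quantiles, default 4.
#' @return Integer vector of quantile labels (1 = highest IC), named as
#'   `ic`.
#' @export
ic_quantiles <- function(ic, q = 4L) {
  if (q < 1) stop("q must be at least 1")
  n <- length(ic)
  if (n < q) stop("need at least q individuals")
  ord <- order(-ic)                      # stable for ties
  sizes <- rep(n %/% q, q) + c(rep(1L, n %% q), rep(0L, q - n %% q))
  lab <- integer(n)
  lab[ord] <- rep(seq_len(q), sizes)
  names(lab) <- names(ic)
  lab
}
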