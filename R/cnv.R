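#' CNV filtering and gene mapping
#'
#' Coordinates are 0-based half-open (BED convention) throughout.
#'
#' @name cnv
NULL

validate_cnvs <- function(cnvs) {
  req <- c("chrom", "start", "end", "type", "individual_id", "callers")
  miss <- setdiff(req, names(cnvs))
  if (length(miss)) stop("CNV table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(cnvs) && any(cnvs$end <= cnvs$start)) stop("CNV with end <= start")
  invisible(cnvs)
}

#' Convert 1-based inclusive intervals to 0-based half-open
#' @param tab data.frame with `start`, `end` columns, 1-based inclusive.
#' @return Same table in BED convention.
#' @export
to_bed_coords <- function(tab) {
  tab$start <- tab$start - 1
  tab
}

n_callers <- function(callers) {
  lengths(strsplit(as.character(callers), ";", fixed = TRUE))
}

#' Retain high-confidence CNVs
#'
#' A call is retained iff it is supported by at least `min_callers`
#' independent callers and is strictly larger than `min_size_bp`
#' ("above 30 kb": a 30,000 bp call is removed).
#'
#' @param cnvs CNV data.frame (`callers` is a semicolon-joined list).
#' @param min_callers Minimum caller support, default 2.
#' @param min_size_bp Strict size threshold in bp, default 30000.
#' @return Filtered CNV data.frame.
#' @export
high_confidence_filter <- function(cnvs, min_callers = 2L, min_size_bp = 30000) {
  validate_cnvs(cnvs)
  keep <- n_callers(cnvs$callers) >= min_callers &
    (cnvs$end - cnvs$start) > min_size_bp
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# reciprocal-overlap indicator between one case interval and control rows
# (same chromosome assumed filtered by caller)
reciprocal_hits <- function(start, end, c_start, c_end, threshold) {
  ov <- pmin(end, c_end) - pmax(start, c_start)
  len_a <- end - start
  len_b <- c_end - c_start
  ov > 0 & ov / len_a >= threshold & ov / len_b >= threshold
}

#' Control-population frequency of a CNV
#'
#' The frequency is the number of distinct control individuals carrying a
#' same-type control CNV with reciprocal overlap of at least
#' `reciprocal_overlap` (overlap length divided by each interval's own
#' length, both), divided by the control cohort size.
#'
#' @param cnv One-row CNV data.frame (or list with chrom/start/end/type).
#' @param control_cnvs Control CNV data.frame.
#' @param n_controls Control cohort size (> 0).
#' @param reciprocal_overlap Threshold, default 0.5.
#' @return Frequency in [0, 1].
#' @export
control_frequency <- function(cnv, control_cnvs, n_controls,
                              reciprocal_overlap = 0.5) {
  if (n_controls <= 0) stop("n_controls must be positive")
  same <- control_cnvs$chrom == cnv$chrom & control_cnvs$type == cnv$type
  if (!any(same)) return(0)
  cc <- control_cnvs[same, , drop = FALSE]
  hit <- reciprocal_hits(cnv$start, cnv$end, cc$start, cc$end,
                         reciprocal_overlap)
  length(unique(cc$individual_id[hit])) / n_controls
}

#' Retain rare CNVs
#'
#' A call is retained iff its control-population frequency is strictly
#' below `max_freq` ("<1% in controls": exactly 1% is removed).
#'
#' @param cnvs Case CNV data.frame.
#' @param control_cnvs Control CNV data.frame.
#' @param n_controls Control cohort size.
#' @param max_freq Strict frequency threshold, default 0.01.
#' @param reciprocal_overlap Matching threshold, default 0.5.
#' @return Filtered CNV data.frame with a `control_freq` column appended.
#' @export
rare_filter <- function(cnvs, control_cnvs, n_controls, max_freq = 0.01,
                        reciprocal_overlap = 0.5) {
  validate_cnvs(cnvs)
  if (nrow(cnvs) == 0) { cnvs$control_freq <- numeric(0); return(cnvs) }
  freq <- vapply(seq_len(nrow(cnvs)), function(i)
    control_frequency(cnvs[i, ], control_cnvs, n_controls, reciprocal_overlap),
    numeric(1))
  out <- cnvs[freq < max_freq, , drop = FALSE]
  out$control_freq <- freq[freq < max_freq]
  rownames(out) <- NULL
  out
}

#' Map retained CNVs to brain-expressed genes
#'
#' A gene is hit by a CNV iff their intervals overlap by at least one base
#' (complete or partial gene coverage both count; an abutting half-open
#' interval does not) and the gene is flagged brain-expressed.  Hits are
#' unioned per individual.
#'
#' @param cnvs Retained CNV data.frame.
#' @param genes Gene data.frame (gene_id, chrom, start, end,
#'   brain_expressed).
#' @return List with `hits` (audit data.frame: individual_id, gene_id,
#'   cnv_row) and `gene_sets` (named list individual -> character vector
#'   of genes).
#' @export
map_to_brain_genes <- function(cnvs, genes) {
  validate_cnvs(cnvs)
  bad <- setdiff(unique(cnvs$chrom), unique(genes$chrom))
  if (length(bad))
    stop("CNV chromosome(s) absent from gene table: ",
         paste(bad, collapse = ", "))
  brain <- genes[genes$brain_expressed, , drop = FALSE]
  hits <- list()
  for (ch in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == ch)
    gi <- which(brain$chrom == ch)
    if (!length(ci) || !length(gi)) next
    # half-open intervals: use closed IRanges on [start, end-1]
    ir_c <- IRanges::IRanges(start = cnvs$start[ci] + 1, end = cnvs$end[ci])
    ir_g <- IRanges::IRanges(start = brain$start[gi] + 1, end = brain$end[gi])
    ov <- IRanges::findOverlaps(ir_c, ir_g, minoverlap = 1L)
    if (!length(ov)) next
    hits[[ch]] <- data.frame(
      individual_id = cnvs$individual_id[ci[S4Vectors::queryHits(ov)]],
      gene_id = brain$gene_id[gi[S4Vectors::subjectHits(ov)]],
      cnv_row = ci[S4Vectors::queryHits(ov)], stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(individual_id = character(), gene_id = character(),
                          cnv_row = integer(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  gene_sets <- lapply(split(hits$gene_id, hits$individual_id),
                      function(g) sort(unique(g)))
  list(hits = hits, gene_sets = gene_sets)
}
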