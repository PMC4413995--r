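#' Overlap CNVRs with gene models and assign gene copy numbers
#'
#' A gene qualifies when its total overlap with the union of CNVR intervals
#' covers at least `min_frac` of the gene length (overlap may be spread
#' over several CNVRs). A qualifying gene inherits the per-population CN of
#' the single CNVR it overlaps most.
#'
#' @param cnvrs a `cnvr_set` from [ascertain_cnvrs()] / [call_cnvrs()].
#' @param genes data.frame `chrom`, `start`, `end`, `name`, `class`
#'   (`OR`/`nonOR`), 0-based half-open.
#' @param min_frac minimum overlapped fraction of the gene (default 0.70).
#' @return data.frame `gene`, `class`, `chrom`, `start`, `end`,
#'   `overlap_frac`, `cnvr` (row index of the dominant CNVR) plus one CN
#'   column per population.
#' @export
overlap_genes <- function(cnvrs, genes, min_frac = 0.70) {
  stopifnot(all(c("chrom", "start", "end", "name", "class") %in%
                names(genes)))
  ggr <- as_granges(genes)
  rgr <- as_granges(cnvrs$regions)
  ov <- GenomicRanges::findOverlaps(ggr, rgr)
  empty <- data.frame(gene = character(0), class = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), overlap_frac = numeric(0),
                      cnvr = integer(0))
  if (length(ov) == 0)
    return(cbind(empty, matrix(numeric(0), 0, ncol(cnvrs$cn),
                               dimnames = list(NULL, colnames(cnvrs$cn)))))
  w <- IRanges::width(IRanges::pintersect(ggr[S4Vectors::queryHits(ov)],
                                          rgr[S4Vectors::subjectHits(ov)]))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  rows <- lapply(unique(qh), function(g) {
    sel <- qh == g
    tot <- sum(w[sel])  # CNVRs never overlap each other, so sum = union
    frac <- tot / (genes$end[g] - genes$start[g])
    if (frac < min_frac) return(NULL)
    dom <- sh[sel][which.max(w[sel])]
    cbind(data.frame(gene = genes$name[g],
                     class = as.character(genes$class[g]),
                     chrom = genes$chrom[g], start = genes$start[g],
                     end = genes$end[g], overlap_frac = frac, cnvr = dom),
          as.data.frame(t(cnvrs$cn[dom, ])))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(cbind(empty, matrix(numeric(0), 0, ncol(cnvrs$cn),
                               dimnames = list(NULL, colnames(cnvrs$cn)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition CNVRs into OR / non-OR / ALL sets
#'
#' `CNVR-OR` contains CNVRs overlapping at least one qualifying OR gene
#' (mixed CNVRs go here: OR takes precedence); `CNVR-nonOR` contains CNVRs
#' overlapping at least one qualifying gene, none of which is an OR;
#' `CNVR-ALL` is every CNVR. OR and non-OR sets are disjoint by
#' construction.
#'
#' @param cnvrs a `cnvr_set`.
#' @param gene_table an [overlap_genes()] result.
#' @return list with integer index vectors `or`, `nonor`, `all` into the
#'   CNVR rows, and `counts`.
#' @export
partition_by_class <- function(cnvrs, gene_table) {
  n <- nrow(cnvrs$regions)
  or_idx <- sort(unique(gene_table$cnvr[gene_table$class == "OR"]))
  genic <- sort(unique(gene_table$cnvr))
  nonor_idx <- setdiff(genic, or_idx)
  list(or = or_idx, nonor = nonor_idx, all = seq_len(n),
       counts = c(or = length(or_idx), nonor = length(nonor_idx),
                  all = n))
}
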