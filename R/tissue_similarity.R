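# Gene-overlap biological similarity between tissues, used to pick
# pretraining tissues: each tissue is summarized by the set of genes nearest
# to the anchors of its positive interactions, and two tissues are compared
# by the overlap of those gene sets.

#' Nearest gene of an anchor
#'
#' The gene whose transcription start site (TSS) is closest to the anchor
#' midpoint; TSS = `start` on the '+' strand and `end - 1` on the '-'
#' strand. Ties are broken by smaller TSS coordinate, then lexicographic
#' gene id.
#'
#' @param chrom,start,end Anchor coordinates (scalars, 0-based half-open).
#' @param annotation A `GenomicRanges::GRanges` with a `name` column (BED
#'   style), or a data.frame with `chrom,start,end,name,strand`.
#' @return The nearest gene id (character scalar).
#' @export
nearest_gene <- function(chrom, start, end, annotation) {
  ann <- annotation_frame(annotation)
  ann <- ann[ann$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0) stopf("no genes on chromosome '%s' in the annotation", chrom)
  mid <- anchor_midpoint(start, end)
  d <- abs(ann$tss - mid)
  cand <- ann[d == min(d), , drop = FALSE]
  cand <- cand[order(cand$tss, cand$name), , drop = FALSE]
  cand$name[1]
}

annotation_frame <- function(annotation) {
  if (methods::is(annotation, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation) - 1L,  # back to 0-based
      end = GenomicRanges::end(annotation),
      name = S4Vectors::mcols(annotation)$name,
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- annotation
  }
  if (nrow(df) == 0) stopf("empty gene annotation")
  if (is.null(df$strand)) df$strand <- "+"
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  df
}

#' Gene set of a tissue's positive interactions
#'
#' The deduplicated union, over all positive interactions, of the nearest
#' gene of each of the two anchors.
#'
#' @param positives Data.frame of positive interactions (standardized
#'   anchors).
#' @param annotation Gene annotation (see [nearest_gene()]).
#' @return Character vector of gene ids (sorted, unique).
#' @export
tissue_gene_set <- function(positives, annotation) {
  if (nrow(positives) == 0) {
    warnf("no positive interactions; returning an empty gene set")
    return(character(0))
  }
  ann <- annotation_frame(annotation)
  genes <- character(0)
  for (a in 1:2) {
    ch <- positives[[paste0("chrom", a)]]
    st <- positives[[paste0("start", a)]]
    en <- positives[[paste0("end", a)]]
    mid <- anchor_midpoint(st, en)
    for (chr in unique(ch)) {
      sub <- ann[ann$chrom == chr, , drop = FALSE]
      if (nrow(sub) == 0) stopf("no genes on chromosome '%s' in the annotation", chr)
      # order by (tss, name) so which.min's first-hit rule applies the
      # smaller-coordinate-then-lexicographic tie-break
      sub <- sub[order(sub$tss, sub$name), , drop = FALSE]
      mids <- mid[ch == chr]
      hit <- vapply(mids, function(m) sub$name[which.min(abs(sub$tss - m))], character(1))
      genes <- c(genes, hit)
    }
  }
  sort(unique(genes))
}

#' Gene-overlap similarity between two tissues
#'
#' The proportion of genes common to both tissues among all genes seen in
#' either (Jaccard index of the two gene sets); 0 when both sets are empty.
#'
#' @param g1,g2 Character vectors of gene ids.
#' @return Similarity in `[0, 1]`.
#' @export
gene_set_similarity <- function(g1, g2) {
  g1 <- unique(g1); g2 <- unique(g2)
  u <- length(union(g1, g2))
  if (u == 0) return(0)
  length(intersect(g1, g2)) / u
}

#' Pairwise similarity matrix over tissues
#'
#' @param positives_by_tissue Named list of positive-interaction data.frames.
#' @param annotation Gene annotation (see [nearest_gene()]).
#' @return A symmetric tissues x tissues matrix with unit diagonal (for
#'   nonempty gene sets), entries in `[0, 1]`.
#' @export
similarity_matrix <- function(positives_by_tissue, annotation) {
  sets <- lapply(positives_by_tissue, tissue_gene_set, annotation = annotation)
  nt <- length(sets)
  m <- matrix(0, nt, nt, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      m[i, j] <- m[j, i] <- gene_set_similarity(sets[[i]], sets[[j]])
    }
  }
  m
}

#' Most similar tissues to a target
#'
#' @param sim Similarity matrix (see [similarity_matrix()]).
#' @param target Target tissue (excluded from the result).
#' @param k Number of tissues to return (default 5).
#' @return Character vector of `k` tissues, most similar first; ties broken
#'   lexicographically by tissue id.
#' @export
top_k_similar <- function(sim, target, k = 5L) {
  if (!target %in% rownames(sim)) stopf("unknown target tissue '%s'", target)
  others <- setdiff(rownames(sim), target)
  if (k > length(others)) {
    stopf("k = %d exceeds the %d available tissues", k, length(others))
  }
  v <- sim[target, others]
  others[order(-v, others)][seq_len(k)]
}

#' Write a similarity matrix as tab-separated text
#' @param sim Similarity matrix.
#' @param path Output path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(tissue = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
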