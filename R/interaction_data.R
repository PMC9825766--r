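# Construction of labeled interaction datasets from pcHi-C summary tables.
#
# Coordinates are 0-based, half-open (BED/BEDPE convention) everywhere.
# An "anchor" is one side of a candidate interaction; anchors are
# standardized to a fixed-width window centered on the original midpoint
# (floor((start + end) / 2)) before any sequence or coverage is extracted.

#' Midpoint of a genomic anchor
#'
#' @param start,end 0-based half-open anchor coordinates (vectors).
#' @return Integer vector of midpoints, `floor((start + end) / 2)`.
#' @export
anchor_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

#' Standardize an anchor to a fixed window around its midpoint
#'
#' pcHi-C anchors come in heterogeneous sizes (restriction fragments). They
#' are standardized to `2 * flank` bp: `flank` bp upstream and downstream of
#' the anchor midpoint, so the default `flank = 1000` yields 2 kb windows.
#'
#' @param start,end 0-based half-open anchor coordinates (vectors).
#' @param flank Half-width in bp around the midpoint (default 1000).
#' @return A data.frame with columns `start`, `end` of the standardized
#'   anchors (width exactly `2 * flank`).
#' @examples
#' standardize_anchor(10000, 14000)  # -> [11000, 13000)
#' @export
standardize_anchor <- function(start, end, flank = 1000L) {
  if (!is_count(flank)) stopf("`flank` must be a positive integer")
  if (any(end <= start)) stopf("anchor end must be greater than start")
  mid <- anchor_midpoint(start, end)
  new_start <- mid - as.integer(flank)
  if (any(new_start < 0)) {
    bad <- which(new_start < 0)
    stopf(
      "%d anchor(s) underflow the chromosome start after standardization (first at input index %d)",
      length(bad), bad[1]
    )
  }
  data.frame(start = new_start, end = mid + as.integer(flank))
}

req_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "fdr")

#' Parse a pcHi-C interaction summary table
#'
#' Reads a BEDPE-like tab-separated file with columns
#' `chrom1 start1 end1 chrom2 start2 end2 fdr` (an optional eighth column is
#' ignored; lines starting with `#` are comments). Each well-formed row
#' becomes one candidate interaction.
#'
#' @param path Path to the tab-separated file.
#' @param tissue Tissue/cell-type identifier attached to every interaction.
#' @param itype Interaction type, `"PE"` (promoter-enhancer) or `"PP"`
#'   (promoter-promoter).
#' @return A data.frame of candidate interactions with columns
#'   `chrom1,start1,end1,chrom2,start2,end2,fdr,tissue,itype`.
#' @export
parse_interactions <- function(path, tissue, itype = c("PE", "PP")) {
  itype <- match.arg(itype)
  if (!file.exists(path)) stopf("interaction file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  # drop a header line if the first retained line is non-numeric in column 2
  if (length(lines) > 0) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2])))) {
      lines <- lines[-1]
      lineno <- lineno[-1]
    }
  }
  if (length(lines) == 0) {
    return(empty_interactions(tissue, itype))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7)) {
    stopf(
      "format error: %d row(s) have fewer than 7 tab-separated columns (first at line %d)",
      sum(nf < 7), lineno[which(nf < 7)[1]]
    )
  }
  m <- t(vapply(fields, function(f) f[1:7], character(7)))
  num <- suppressWarnings(apply(m[, c(2, 3, 5, 6, 7), drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  if (any(is.na(num))) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stopf("format error: non-numeric coordinate or fdr at line %d", lineno[bad])
  }
  fdr <- num[, 5]
  if (any(fdr < 0 | fdr > 1)) {
    bad <- which(fdr < 0 | fdr > 1)[1]
    stopf("value error: fdr outside [0,1] at line %d (value %g)", lineno[bad], fdr[bad])
  }
  data.frame(
    chrom1 = m[, 1], start1 = as.integer(num[, 1]), end1 = as.integer(num[, 2]),
    chrom2 = m[, 4], start2 = as.integer(num[, 3]), end2 = as.integer(num[, 4]),
    fdr = fdr, tissue = tissue, itype = itype,
    stringsAsFactors = FALSE
  )
}

empty_interactions <- function(tissue = character(0), itype = character(0)) {
  data.frame(
    chrom1 = character(0), start1 = integer(0), end1 = integer(0),
    chrom2 = character(0), start2 = integer(0), end2 = integer(0),
    fdr = numeric(0),
    tissue = rep_len(tissue, 0), itype = rep_len(itype, 0),
    stringsAsFactors = FALSE
  )
}

#' Distance between anchor midpoints of candidate interactions
#' @param cands Interaction data.frame (see [parse_interactions()]).
#' @return Numeric vector of |midpoint1 - midpoint2| in bp.
#' @export
interaction_distance <- function(cands) {
  abs(anchor_midpoint(cands$start1, cands$end1) -
        anchor_midpoint(cands$start2, cands$end2))
}

#' Filter to intra-chromosomal interactions within a distance bound
#'
#' Removes inter-chromosomal pairs and pairs whose midpoint distance is
#' strictly greater than `max_distance` (equality is kept). Row order is
#' preserved.
#'
#' @param cands Interaction data.frame.
#' @param max_distance Maximum midpoint distance in bp (default 1e6).
#' @return The filtered data.frame.
#' @export
filter_interactions <- function(cands, max_distance = 1e6) {
  if (nrow(cands) == 0) return(cands)
  keep <- cands$chrom1 == cands$chrom2 & interaction_distance(cands) <= max_distance
  cands[keep, , drop = FALSE]
}

#' Label candidates by FDR into positives and a negative pool
#'
#' Significant interactions (`fdr < pos_cut`) form the positive set;
#' non-significant ones (`fdr > neg_cut`) form the pool from which negatives
#' are drawn. Candidates between the cutoffs are discarded as ambiguous.
#' The defaults (0.1, 0.5) can be moved to stricter regimes such as
#' (0.05, 0.5), (0.1, 0.7) or (0.1, 0.9).
#'
#' @param cands Interaction data.frame.
#' @param pos_cut Positive FDR cutoff (exclusive; default 0.1).
#' @param neg_cut Negative FDR cutoff (exclusive; default 0.5).
#' @return A list with data.frames `positives` and `negative_pool`.
#' @export
label_by_fdr <- function(cands, pos_cut = 0.1, neg_cut = 0.5) {
  if (pos_cut > neg_cut) {
    stopf("configuration error: pos_cut (%g) must be <= neg_cut (%g)", pos_cut, neg_cut)
  }
  list(
    positives = cands[cands$fdr < pos_cut, , drop = FALSE],
    negative_pool = cands[cands$fdr > neg_cut, , drop = FALSE]
  )
}

#' Standardize both anchors of each interaction, dropping out-of-bounds ones
#'
#' Replaces both anchors with `2 * flank`-bp windows centered on their
#' midpoints. Interactions whose standardized anchors would run past either
#' chromosome end (or below 0) are dropped with a warning rather than padded.
#' Duplicate interactions (identical standardized anchor pairs on the same
#' tissue/type) are deduplicated keeping the smallest FDR.
#'
#' @param cands Interaction data.frame.
#' @param genome A `Biostrings::DNAStringSet` (used for chromosome bounds),
#'   or a named vector of chromosome lengths, or `NULL` to skip bounds checks
#'   against chromosome ends.
#' @param flank Half-width in bp (default 1000).
#' @return Interaction data.frame with standardized coordinates.
#' @export
standardize_interactions <- function(cands, genome = NULL, flank = 1000L) {
  if (nrow(cands) == 0) return(cands)
  mid1 <- anchor_midpoint(cands$start1, cands$end1)
  mid2 <- anchor_midpoint(cands$start2, cands$end2)
  flank <- as.integer(flank)
  s1 <- mid1 - flank; e1 <- mid1 + flank
  s2 <- mid2 - flank; e2 <- mid2 + flank
  ok <- s1 >= 0 & s2 >= 0
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    l1 <- lens[cands$chrom1]; l2 <- lens[cands$chrom2]
    if (any(is.na(l1) | is.na(l2))) {
      stopf("unknown chromosome in interactions: %s",
            paste(unique(c(cands$chrom1, cands$chrom2)[is.na(c(l1, l2))]), collapse = ", "))
    }
    ok <- ok & e1 <= l1 & e2 <= l2
  }
  if (any(!ok)) {
    warnf("dropped %d interaction(s) whose standardized anchors overlap a chromosome end", sum(!ok))
  }
  out <- cands[ok, , drop = FALSE]
  out$start1 <- s1[ok]; out$end1 <- e1[ok]
  out$start2 <- s2[ok]; out$end2 <- e2[ok]
  key <- paste(out$tissue %||% "", out$itype %||% "", out$chrom1, out$start1,
               out$chrom2, out$start2, sep = ":")
  if (anyDuplicated(key)) {
    out <- out[order(key, out$fdr), , drop = FALSE]
    out <- out[!duplicated(paste(out$tissue %||% "", out$itype %||% "", out$chrom1,
                                 out$start1, out$chrom2, out$start2, sep = ":")), , drop = FALSE]
    out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stopf("`genome` must be a DNAStringSet or a named vector of lengths")
  }
}

#' GC content of interactions over their standardized anchors
#'
#' Computes the GC fraction used for GC-matched negative sampling. By
#' default GC is measured over the concatenation of the two standardized
#' anchor sequences; `per = "anchor"` returns a two-column matrix instead.
#'
#' @param cands Interaction data.frame with standardized coordinates.
#' @param genome A `Biostrings::DNAStringSet` reference.
#' @param per `"pair"` (default, one value per interaction) or `"anchor"`.
#' @return Numeric vector in `[0, 1]` (or an n x 2 matrix for `per = "anchor"`).
#' @export
interaction_gc <- function(cands, genome, per = c("pair", "anchor")) {
  per <- match.arg(per)
  gc1 <- anchor_gc(genome, cands$chrom1, cands$start1, cands$end1)
  gc2 <- anchor_gc(genome, cands$chrom2, cands$start2, cands$end2)
  if (per == "anchor") return(cbind(gc1, gc2))
  w1 <- cands$end1 - cands$start1
  w2 <- cands$end2 - cands$start2
  (gc1 * w1 + gc2 * w2) / (w1 + w2)
}

anchor_gc <- function(genome, chrom, start, end) {
  if (length(chrom) == 0) return(numeric(0))
  seqs <- fetch_sequences(genome, chrom, start, end)
  counts <- Biostrings::letterFrequency(seqs, letters = c("G", "C"))
  rowSums(counts) / Biostrings::width(seqs)
}

#' Draw GC-matched negatives from the negative pool
#'
#' Matches the negatives' GC distribution to the positives' by decile
#' histogram matching: the positive GC values define 10 (by default) quantile
#' bins; from each bin the same number (times `ratio`) of pool members is
#' sampled without replacement. When a bin has too few pool members, the
#' shortfall is filled with the unused pool members closest in GC to the bin
#' center. Deterministic given `seed`.
#'
#' @param positives Data.frame of positives with a `gc` column.
#' @param pool Data.frame of pool candidates with a `gc` column.
#' @param ratio Negatives per positive (1 for balanced, 5 for the unbalanced
#'   regime).
#' @param bins Number of GC quantile bins (default 10, i.e. deciles).
#' @param seed Integer seed.
#' @return A data.frame of `ratio * nrow(positives)` sampled negatives.
#' @export
sample_gc_matched_negatives <- function(positives, pool, ratio = 1L, bins = 10L, seed = 1L) {
  if (is.null(positives$gc) || is.null(pool$gc)) {
    stopf("both `positives` and `pool` need a precomputed `gc` column")
  }
  n_needed <- as.integer(ratio) * nrow(positives)
  if (nrow(pool) < n_needed) {
    stopf("insufficient negative pool: need %d, have %d (deficit %d)",
          n_needed, nrow(pool), n_needed - nrow(pool))
  }
  with_seed_(seed, {
    brks <- unique(quantile(positives$gc, probs = seq(0, 1, length.out = bins + 1)))
    if (length(brks) < 2) {
      # degenerate positives (single GC value): one narrow bin at that value,
      # so only equal-GC pool members match and shortfalls fill nearest-GC
      brks <- brks + c(-1e-9, 1e-9)
    } else {
      # open the outer bins so every pool member falls in some bin
      brks[1] <- -Inf
      brks[length(brks)] <- Inf
    }
    pos_bin <- cut(positives$gc, brks, labels = FALSE, include.lowest = TRUE)
    pool_bin <- cut(pool$gc, brks, labels = FALSE, include.lowest = TRUE)
    need <- tabulate(pos_bin, nbins = length(brks) - 1) * as.integer(ratio)
    taken <- rep(FALSE, nrow(pool))
    chosen <- integer(0)
    shortfall <- integer(0)  # bin ids, one entry per missing draw
    for (b in seq_along(need)) {
      if (need[b] == 0) next
      avail <- which(pool_bin == b & !taken)
      k <- min(length(avail), need[b])
      if (k > 0) {
        pick <- if (length(avail) == 1) avail else sample(avail, k)
        chosen <- c(chosen, pick)
        taken[pick] <- TRUE
      }
      if (k < need[b]) shortfall <- c(shortfall, rep(b, need[b] - k))
    }
    if (length(shortfall) > 0) {
      centers <- vapply(split(positives$gc, pos_bin), mean, numeric(1))
      for (b in shortfall) {
        avail <- which(!taken)
        pick <- avail[which.min(abs(pool$gc[avail] - centers[[as.character(b)]]))]
        chosen <- c(chosen, pick)
        taken[pick] <- TRUE
      }
    }
    out <- pool[chosen, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Random train/validation/test split
#'
#' Partitions `1:n` into disjoint index sets with the requested fractions.
#' Sizes are `floor(n * f)` for all parts but the last, which takes the
#' remainder; with the default (0.70, 0.15, 0.15) and `n = 100` this gives
#' 70/15/15. A two-part split such as `c(0.85, 0.15)` (used for pretraining)
#' returns `train` and `validation` only.
#'
#' @param n Number of items.
#' @param fractions Numeric vector summing to 1 (length 2 or 3).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list of class `"dataset_split"` with elements `train`,
#'   `validation` (and `test` for 3-part splits) plus the `seed`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("`fractions` must sum to 1")
  k <- length(fractions)
  if (!k %in% c(2L, 3L)) stopf("`fractions` must have length 2 or 3")
  if (n < k) stopf("cannot split %d item(s) into %d parts", n, k)
  with_seed_(seed, {
    perm <- sample.int(n)
    sizes <- floor(n * fractions[-k])
    sizes <- c(sizes, n - sum(sizes))
    ends <- cumsum(sizes)
    starts <- c(1, head(ends, -1) + 1)
    parts <- lapply(seq_len(k), function(i) {
      if (sizes[i] == 0L) integer(0) else sort(perm[starts[i]:ends[i]])
    })
    names(parts) <- c("train", "validation", "test")[seq_len(k)]
    structure(c(parts, list(seed = as.integer(seed))), class = "dataset_split")
  })
}

#' Build a labeled per-tissue dataset from candidate interactions
#'
#' Full construction pipeline: intra-chromosomal distance filter, anchor
#' standardization (with chromosome-end bounds from the genome), FDR
#' labeling, GC computation, GC-matched negative sampling, and assembly into
#' one labeled table.
#'
#' @param cands Interaction data.frame (e.g. from [parse_interactions()]).
#' @param genome A `Biostrings::DNAStringSet` reference.
#' @param pos_fdr,neg_fdr FDR cutoffs (defaults 0.1 and 0.5).
#' @param ratio Negatives per positive (default 1).
#' @param max_distance Distance filter in bp (default 1e6).
#' @param flank Anchor half-width in bp (default 1000).
#' @param bins GC quantile bins for matching (default 10).
#' @param seed Integer seed for the negative sampler.
#' @return A labeled interaction data.frame with added columns `label`
#'   (1 positive / 0 negative), `distance` (bp) and `gc`.
#' @export
prepare_dataset <- function(cands, genome, pos_fdr = 0.1, neg_fdr = 0.5,
                            ratio = 1L, max_distance = 1e6, flank = 1000L,
                            bins = 10L, seed = 1L) {
  cands <- filter_interactions(cands, max_distance)
  cands <- standardize_interactions(cands, genome, flank)
  lab <- label_by_fdr(cands, pos_fdr, neg_fdr)
  pos <- lab$positives
  pool <- lab$negative_pool
  if (nrow(pos) == 0) stopf("no positive interactions after filtering/labeling")
  pos$gc <- interaction_gc(pos, genome)
  pool$gc <- interaction_gc(pool, genome)
  neg <- sample_gc_matched_negatives(pos, pool, ratio = ratio, bins = bins, seed = seed)
  pos$label <- 1L
  neg$label <- 0L
  out <- rbind(pos, neg)
  out$distance <- interaction_distance(out)
  rownames(out) <- NULL
  out
}

#' Write / read a labeled dataset as tab-separated text
#'
#' @param dataset Labeled interaction data.frame.
#' @param path Output path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   data.frame.
#' @export
write_dataset <- function(dataset, path) {
  write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a dataset split as a header-bearing index table
#'
#' @param split A `"dataset_split"` object.
#' @param path Output path.
#' @export
write_split <- function(split, path) {
  parts <- intersect(c("train", "validation", "test"), names(split))
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(part = p, index = split[[p]])
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  parts <- split(df$index, df$part)
  out <- lapply(intersect(c("train", "validation", "test"), names(parts)),
                function(p) sort(parts[[p]]))
  names(out) <- intersect(c("train", "validation", "test"), names(parts))
  structure(c(out, list(seed = NA_integer_)), class = "dataset_split")
}
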