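# Multi-modal featurization: one-hot anchor sequence (S), windowed coverage
# features (R, plus optional conservation / DNA-shape aux tracks) and scaled
# anchor distance (D).

#' One-hot encode a DNA sequence
#'
#' Maps `A -> (1,0,0,0)`, `C -> (0,1,0,0)`, `G -> (0,0,1,0)`,
#' `T -> (0,0,0,1)` (case-insensitive); ambiguous `N` bases become all-zero
#' rows.
#'
#' @param seq A DNA string (single character scalar).
#' @return A `nchar(seq) x 4` numeric matrix with columns `A,C,G,T`.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  bad <- is.na(idx) & chars != "N"
  if (any(bad)) {
    stopf("encoding error: unexpected character '%s' at position %d",
          chars[which(bad)[1]], which(bad)[1])
  }
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Fetch the genomic sequence of anchors from a reference
#'
#' @param genome A `Biostrings::DNAStringSet`.
#' @param chrom,start,end Anchor coordinates (0-based half-open, vectors).
#' @return A `DNAStringSet` of uppercased forward-strand sequences of width
#'   `end - start`.
#' @export
fetch_sequences <- function(genome, chrom, start, end) {
  if (!methods::is(genome, "DNAStringSet")) {
    stopf("`genome` must be a Biostrings::DNAStringSet")
  }
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss) > 0) stopf("unknown chromosome(s): %s", paste(miss, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(start < 0 | end > lens[chrom])) {
    stopf("anchor out of chromosome bounds (first at index %d)",
          which(start < 0 | end > lens[chrom])[1])
  }
  # DNAStringSet storage is already uppercase (lowercase FASTA input is
  # normalized on read), so forward-strand subsequences suffice
  Biostrings::subseq(genome[chrom], start = start + 1L, end = as.integer(end))
}

#' Fetch one anchor's sequence as a character string
#' @inheritParams fetch_sequences
#' @return A character scalar.
#' @export
fetch_anchor_sequence <- function(genome, chrom, start, end) {
  as.character(fetch_sequences(genome, chrom[1], start[1], end[1]))[[1]]
}

#' Sliding-window featurization of a per-base track
#'
#' Summarizes a per-base signal over an anchor into window means: value `i`
#' is the arithmetic mean of `values[(i-1)*step + 1 .. (i-1)*step + window]`.
#' At the defaults (2000-bp anchor, window 1000, step 50) this yields 21
#' features per anchor per track.
#'
#' @param values Per-base numeric vector spanning the anchor.
#' @param window Window size in bp (default 1000).
#' @param step Sliding step in bp (default 50).
#' @return Numeric vector of length `(length(values) - window) / step + 1`.
#' @export
bin_track <- function(values, window = 1000L, step = 50L) {
  n <- length(values)
  if (window > n) stopf("configuration error: window (%d) exceeds track length (%d)", window, n)
  if ((n - window) %% step != 0) {
    stopf("configuration error: (length - window) = %d is not divisible by step = %d",
          n - window, step)
  }
  if (any(!is.finite(values))) stopf("track values must be finite")
  k <- (n - window) %/% step + 1L
  cs <- c(0, cumsum(values))
  starts <- (seq_len(k) - 1L) * step
  (cs[starts + window + 1L] - cs[starts + 1L]) / window
}

#' Counts-per-million normalization of raw coverage
#'
#' @param counts Per-base raw counts.
#' @param library_size Total mapped reads (or total signal) of the library.
#' @return `counts * 1e6 / library_size`.
#' @export
normalize_coverage <- function(counts, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0) {
    stopf("`library_size` must be a single positive number")
  }
  counts * 1e6 / library_size
}

#' Anchor distance and its scaled form
#'
#' Distance is measured between the midpoints of the two anchors; the scaled
#' form divides by the distance-filter bound (1e6 bp by default) so values
#' lie in `[0, 1]` for any interaction that passed the filter.
#'
#' @param a1,a2 Lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return `compute_distance`: distance in bp. `scale_distance`: scaled value.
#' @export
compute_distance <- function(a1, a2) {
  if (!identical(as.character(a1$chrom), as.character(a2$chrom))) {
    stopf("anchors are on different chromosomes")
  }
  abs(anchor_midpoint(a1$start, a1$end) - anchor_midpoint(a2$start, a2$end))
}

#' @rdname compute_distance
#' @param bp Distance in bp.
#' @param max_distance Scaling denominator (default 1e6, the filter bound).
#' @export
scale_distance <- function(bp, max_distance = 1e6) {
  bp / max_distance
}

# Per-base values of a coverage track over an anchor. `track` is an RleList
# (per-chromosome run-length encoded signal), as produced by
# GenomicRanges::coverage() or read_bedgraph_track().
track_values <- function(track, chrom, start, end) {
  if (!chrom %in% names(track)) stopf("track has no chromosome '%s'", chrom)
  rle <- track[[chrom]]
  n <- end - start
  if (end <= length(rle)) {
    as.numeric(rle[(start + 1L):end])
  } else {
    # beyond recorded signal: impute zeros (callers count imputed bases)
    v <- numeric(n)
    if (start < length(rle)) {
      got <- as.numeric(rle[(start + 1L):length(rle)])
      v[seq_along(got)] <- got
    }
    v
  }
}

#' Read a bedGraph file into a per-chromosome run-length track
#'
#' @param path bedGraph file path.
#' @return An `RleList` of per-base values, suitable for [build_feature_bundles()].
#' @export
read_bedgraph_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

#' Build model-ready feature bundles for a labeled dataset
#'
#' Produces the tensors the classifier consumes, for any subset of the
#' feature modalities:
#' \describe{
#'   \item{S}{one-hot sequence, array `(n, L, 4, 2)` — anchor length L rows,
#'     4 base columns, the two anchors stacked as channels;}
#'   \item{R}{windowed coverage, array `(n, W, M, 2)` — W window features
#'     (21 at the defaults) per track for M tracks, anchors as channels;}
#'   \item{D}{scaled distance, numeric vector of length n;}
#'   \item{aux}{windowed conservation / DNA-shape features with the same
#'     `(n, W, A, 2)` contract as R.}
#' }
#'
#' @param dataset Labeled interaction data.frame with standardized anchors.
#' @param genome `DNAStringSet` reference (required when `"S"` is active).
#' @param tracks Named list of coverage `RleList`s (required for `"R"`).
#' @param aux_tracks Named list of per-base auxiliary `RleList`s (for `"aux"`).
#' @param active Character subset of `c("S","R","D","aux")`.
#' @param window,step Windowing parameters for R/aux tracks (defaults 1000/50).
#' @param library_sizes Named numeric vector of per-track library sizes for
#'   CPM normalization; by default the total signal of each track.
#' @param max_distance Distance-scaling denominator (default 1e6).
#' @return A list of class `"feature_bundles"` with elements among
#'   `S`, `R`, `D`, `aux`, plus `label` and `meta` (tissue/itype).
#' @export
build_feature_bundles <- function(dataset, genome = NULL, tracks = NULL,
                                  aux_tracks = NULL, active = c("S", "R", "D"),
                                  window = 1000L, step = 50L,
                                  library_sizes = NULL, max_distance = 1e6) {
  active <- match.arg(active, c("S", "R", "D", "aux"), several.ok = TRUE)
  n <- nrow(dataset)
  out <- list()
  if ("S" %in% active) {
    if (is.null(genome)) stopf("resource error: active feature 'S' needs `genome`")
    out$S <- onehot_array(dataset, genome)
  }
  if ("R" %in% active) {
    if (is.null(tracks) || length(tracks) == 0) {
      stopf("resource error: active feature 'R' needs `tracks`")
    }
    out$R <- track_array(dataset, tracks, window, step, library_sizes, normalize = TRUE)
  }
  if ("D" %in% active) {
    out$D <- scale_distance(interaction_distance(dataset), max_distance)
  }
  if ("aux" %in% active) {
    if (is.null(aux_tracks) || length(aux_tracks) == 0) {
      stopf("resource error: active feature 'aux' needs `aux_tracks`")
    }
    out$aux <- track_array(dataset, aux_tracks, window, step, NULL, normalize = FALSE)
  }
  out$label <- dataset$label
  out$meta <- list(tissue = unique(dataset$tissue), itype = unique(dataset$itype),
                   n = n, active = active)
  structure(out, class = "feature_bundles")
}

onehot_array <- function(dataset, genome) {
  n <- nrow(dataset)
  L <- unique(c(dataset$end1 - dataset$start1, dataset$end2 - dataset$start2))
  if (length(L) != 1) stopf("anchors must be standardized to one width before featurization")
  arr <- array(0, dim = c(n, L, 4L, 2L))
  for (a in 1:2) {
    seqs <- fetch_sequences(genome,
                            dataset[[paste0("chrom", a)]],
                            dataset[[paste0("start", a)]],
                            dataset[[paste0("end", a)]])
    cm <- as.matrix(seqs)  # n x L character matrix
    for (b in 1:4) {
      arr[, , b, a] <- (cm == c("A", "C", "G", "T")[b]) * 1
    }
  }
  arr
}

track_array <- function(dataset, tracks, window, step, library_sizes, normalize) {
  n <- nrow(dataset)
  L <- unique(c(dataset$end1 - dataset$start1, dataset$end2 - dataset$start2))
  if (length(L) != 1) stopf("anchors must be standardized to one width before featurization")
  k <- (L - window) %/% step + 1L
  if ((L - window) %% step != 0) {
    stopf("configuration error: anchor width %d incompatible with window %d / step %d",
          L, window, step)
  }
  M <- length(tracks)
  arr <- array(0, dim = c(n, k, M, 2L))
  offs <- (seq_len(k) - 1L) * step
  for (m in seq_len(M)) {
    tr <- tracks[[m]]
    lib <- if (normalize) {
      if (!is.null(library_sizes)) library_sizes[[names(tracks)[m] %||% m]]
      else sum(vapply(tr, function(r) sum(as.numeric(r)), numeric(1)))
    } else NULL
    for (a in 1:2) {
      ch <- dataset[[paste0("chrom", a)]]
      st <- dataset[[paste0("start", a)]]
      for (chr in unique(ch)) {
        sel <- which(ch == chr)
        if (!chr %in% names(tr)) stopf("track has no chromosome '%s'", chr)
        rle <- tr[[chr]]
        # all (anchor x window) means in one Views pass; window means of a
        # CPM-scaled track equal scaled window means (linearity)
        starts <- rep(st[sel], each = k) + offs + 1L
        max_end <- max(starts) + window - 1L
        if (length(rle) < max_end) {
          rle <- c(rle, S4Vectors::Rle(0, max_end - length(rle)))
        }
        vm <- IRanges::viewMeans(IRanges::Views(rle, start = starts, width = window))
        if (normalize) vm <- normalize_coverage(vm, lib)
        arr[sel, , m, a] <- matrix(vm, ncol = k, byrow = TRUE)
      }
    }
  }
  arr
}

#' Subset feature bundles by interaction index
#' @param bundles A `"feature_bundles"` object.
#' @param idx Integer indices of interactions to keep.
#' @return A `"feature_bundles"` object restricted to `idx`.
#' @export
subset_bundles <- function(bundles, idx) {
  out <- bundles
  for (nm in intersect(c("S", "R", "aux"), names(bundles))) {
    out[[nm]] <- bundles[[nm]][idx, , , , drop = FALSE]
  }
  if (!is.null(bundles$D)) out$D <- bundles$D[idx]
  out$label <- bundles$label[idx]
  out$meta$n <- length(idx)
  out
}

#' Write / read feature bundles as a plain-text container
#'
#' The on-disk container is a directory holding one JSON manifest
#' (`manifest.json`: component names, dimensions, metadata) and one
#' whitespace-free flat text file per array component.
#'
#' @param bundles A `"feature_bundles"` object.
#' @param dir Output directory (created if needed).
#' @export
write_bundles <- function(bundles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- intersect(c("S", "R", "D", "aux"), names(bundles))
  manifest <- list(components = comps, meta = bundles$meta,
                   dims = lapply(bundles[comps], function(x) dim(x) %||% length(x)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  for (cm in comps) {
    writeLines(format(as.numeric(bundles[[cm]]), digits = 17, scientific = TRUE, trim = TRUE),
               file.path(dir, paste0(cm, ".txt")))
  }
  writeLines(as.character(bundles$label), file.path(dir, "label.txt"))
  invisible(dir)
}

#' @rdname write_bundles
#' @export
read_bundles <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  out <- list()
  for (cm in manifest$components) {
    v <- as.numeric(readLines(file.path(dir, paste0(cm, ".txt"))))
    d <- manifest$dims[[cm]]
    out[[cm]] <- if (length(d) > 1) array(v, dim = d) else v
  }
  out$label <- as.integer(readLines(file.path(dir, "label.txt")))
  out$meta <- manifest$meta
  structure(out, class = "feature_bundles")
}
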