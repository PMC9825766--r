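# Synthetic multi-tissue pcHi-C studies: a random genome with planted
# motifs, gene annotation, per-tissue interaction tables with FDRs and
# ground-truth labels, and per-tissue epigenetic coverage tracks. Every
# output is in the format the pipeline consumes (FASTA, BED, BEDPE-like
# TSV, bedGraph), so the full workflow is exercisable without downloads.
#
# What the generator emulates: positives carry a shared sequence motif
# (common across tissues, with per-interaction probability p_shared) and
# optionally a tissue-private motif (p_priv) planted at uniform random
# offsets inside both standardized anchors; positive anchors receive a
# multiplicative fold-enrichment over Poisson background coverage; positive
# distances are drawn shorter than negative ones ("shifted" mode) or from
# the identical sampler ("matched" mode); FDRs are Uniform(0, 0.1) for true
# positives and Uniform(0.5, 1) for true negatives so that FDR labeling at
# the default cutoffs recovers the planted truth exactly.

#' Simulation configuration
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_genes Genes to place uniformly on the genome.
#' @param gc Genome GC fraction (default 0.5).
#' @param tissues Character vector of tissue identifiers.
#' @param itypes Interaction types to generate per tissue (default PE & PP).
#' @param n_pos Positives per tissue (scalar, or named per-tissue vector;
#'   e.g. 200 for a small-tissue regime vs 5000 for a large one).
#' @param pool_factor Negative-pool size as a multiple of `n_pos`.
#' @param flank Anchor half-width in bp (default 1000, i.e. 2 kb anchors).
#' @param p_shared Probability a positive interaction carries the shared
#'   motif (in both anchors).
#' @param p_priv Probability a positive carries its tissue's private motif.
#' @param motif_len Length of generated motifs (default 10).
#' @param motif_copies Occurrences planted per anchor when a motif is
#'   planted (default 3, emulating clustered binding sites in regulatory
#'   anchors rather than a single isolated site).
#' @param shared_motif,private_motifs Explicit motif strings (defaults:
#'   drawn randomly from the seed; `private_motifs` named by tissue).
#' @param marks Names of epigenetic coverage tracks (default the four-mark
#'   panel: open chromatin, H3K4me3, H3K4me1, H3K27ac).
#' @param background_rate Poisson background coverage per base.
#' @param enrichment_fold Coverage fold-change at positive anchors
#'   (1 = no coverage signal).
#' @param distance_mode `"shifted"` (positives closer) or `"matched"`
#'   (identical distance samplers for both classes).
#' @param pos_dist,neg_dist Distance ranges (bp) for positives/negatives in
#'   shifted mode; matched mode uses `pos_dist` for both.
#' @param n_aux Number of auxiliary smooth per-base tracks (conservation /
#'   DNA-shape stand-ins) to generate.
#' @param seed Integer seed; everything is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(chrom_lengths = c(chrS1 = 400000L, chrS2 = 400000L),
                       n_genes = 80L, gc = 0.5,
                       tissues = c("T1", "T2", "T3"),
                       itypes = c("PE", "PP"),
                       n_pos = 300L, pool_factor = 2,
                       flank = 1000L,
                       p_shared = 0.9, p_priv = 0,
                       motif_len = 10L, motif_copies = 3L,
                       shared_motif = NULL, private_motifs = NULL,
                       marks = c("openchrom", "H3K4me3", "H3K4me1", "H3K27ac"),
                       background_rate = 0.2, enrichment_fold = 5,
                       distance_mode = c("shifted", "matched"),
                       pos_dist = c(5000, 50000),
                       neg_dist = c(5000, 500000),
                       n_aux = 0L, seed = 1L) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(p_shared >= 0, p_shared <= 1, p_priv >= 0, p_priv <= 1,
            all(n_pos > 0), background_rate > 0, enrichment_fold >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chrS", seq_along(chrom_lengths))
  }
  if (length(n_pos) == 1) n_pos <- stats::setNames(rep(n_pos, length(tissues)), tissues)
  if (any(2 * flank + 10 > chrom_lengths)) stopf("genome too small for the requested anchors")
  max_d <- if (distance_mode == "shifted") max(neg_dist) else max(pos_dist)
  if (any(chrom_lengths < max_d + 4 * flank)) {
    stopf("genome too small for the requested anchor distances")
  }
  structure(list(
    chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes), gc = gc,
    tissues = tissues, itypes = itypes, n_pos = n_pos,
    pool_factor = pool_factor, flank = as.integer(flank),
    p_shared = p_shared, p_priv = p_priv, motif_len = as.integer(motif_len),
    motif_copies = as.integer(motif_copies),
    shared_motif = shared_motif, private_motifs = private_motifs,
    marks = marks, background_rate = background_rate,
    enrichment_fold = enrichment_fold, distance_mode = distance_mode,
    pos_dist = pos_dist, neg_dist = neg_dist, n_aux = as.integer(n_aux),
    seed = as.integer(seed)
  ), class = "sim_config")
}

random_motif <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate the random genome and gene annotation
#'
#' @param cfg A [sim_config()].
#' @return A study list with `cfg`, `chars` (per-chromosome character
#'   vectors), `genome` (`DNAStringSet`) and `genes` (BED-style data.frame).
#' @export
simulate_genome <- function(cfg) {
  with_seed_(cfg$seed, {
    probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
               T = (1 - cfg$gc) / 2)
    chars <- lapply(cfg$chrom_lengths, function(L) {
      sample(names(probs), L, replace = TRUE, prob = probs)
    })
    genes <- if (cfg$n_genes > 0) {
      chrom <- sample(names(cfg$chrom_lengths), cfg$n_genes, replace = TRUE)
      width <- sample(500:5000, cfg$n_genes, replace = TRUE)
      start <- vapply(seq_len(cfg$n_genes), function(i) {
        sample.int(cfg$chrom_lengths[[chrom[i]]] - width[i], 1) - 1L
      }, integer(1))
      g <- data.frame(chrom = chrom, start = start, end = start + width,
                      name = sprintf("gene_%04d", seq_len(cfg$n_genes)),
                      score = 0L,
                      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
      g[order(g$chrom, g$start), ]
    } else {
      warnf("0 genes requested; emitting an empty annotation")
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0), score = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    }
    study <- list(cfg = cfg, chars = chars, genes = genes,
                  interactions = list(), tracks = list(), aux_tracks = NULL)
    if (is.null(study$cfg$shared_motif)) {
      study$cfg$shared_motif <- random_motif(cfg$motif_len)
    }
    if (is.null(study$cfg$private_motifs)) {
      study$cfg$private_motifs <- stats::setNames(
        vapply(cfg$tissues, function(t) random_motif(cfg$motif_len), character(1)),
        cfg$tissues)
    }
    study$genome <- chars_to_genome(study$chars)
    study
  })
}

chars_to_genome <- function(chars) {
  Biostrings::DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
}

draw_distance <- function(n, range) {
  round(runif(n, range[1], range[2]))
}

#' Generate one tissue/type interaction set with planted signal
#'
#' Draws positive and pool-negative interactions, plants motifs into the
#' genome inside positive anchors, and attaches FDRs consistent with the
#' truth labels. Deterministic given the study seed, tissue and type.
#'
#' @param study A study from [simulate_genome()].
#' @param tissue Tissue identifier (must be in the config).
#' @param itype `"PE"` or `"PP"`.
#' @return The updated study; the new table is in
#'   `study$interactions[[tissue]][[itype]]` with columns
#'   `chrom1,...,fdr,tissue,itype,truth`.
#' @export
simulate_interactions <- function(study, tissue, itype = "PE") {
  cfg <- study$cfg
  if (!tissue %in% cfg$tissues) stopf("unknown tissue '%s'", tissue)
  # per-(tissue,type) stream seed so sets are independent but reproducible
  stream <- cfg$seed + 7919L * match(tissue, cfg$tissues) +
    104729L * match(itype, c("PE", "PP"))
  with_seed_(stream, {
    n_pos <- cfg$n_pos[[tissue]]
    n_neg <- ceiling(cfg$pool_factor * n_pos)
    n <- n_pos + n_neg
    truth <- rep(c(1L, 0L), c(n_pos, n_neg))
    rng <- if (cfg$distance_mode == "matched") {
      function(k, lab) draw_distance(k, cfg$pos_dist)
    } else {
      function(k, lab) draw_distance(k, if (lab == 1) cfg$pos_dist else cfg$neg_dist)
    }
    d <- c(rng(n_pos, 1), rng(n_neg, 0))
    chrom <- sample(names(cfg$chrom_lengths), n, replace = TRUE)
    lens <- cfg$chrom_lengths[chrom]
    lo <- 2 * cfg$flank
    mid1 <- floor(runif(n, lo, lens - lo - d))
    mid2 <- mid1 + d
    # anchors emitted with fragment-like heterogeneous widths; the pipeline
    # re-standardizes around the midpoints
    w1 <- 2 * round(runif(n, cfg$flank, 2 * cfg$flank))
    w2 <- 2 * round(runif(n, cfg$flank, 2 * cfg$flank))
    df <- data.frame(
      chrom1 = chrom, start1 = as.integer(pmax(0, mid1 - w1 / 2)),
      end1 = as.integer(mid1 + w1 / 2),
      chrom2 = chrom, start2 = as.integer(mid2 - w2 / 2),
      end2 = as.integer(mid2 + w2 / 2),
      fdr = ifelse(truth == 1, runif(n, 0, 0.0999), runif(n, 0.5001, 1)),
      tissue = tissue, itype = itype, truth = truth,
      stringsAsFactors = FALSE
    )
    # plant motif copies at random offsets inside both standardized anchors
    # of selected positives
    plant <- function(chars, chrom, mid, motif) {
      m <- strsplit(motif, "")[[1]]
      for (cp in seq_len(cfg$motif_copies)) {
        off <- sample.int(2 * cfg$flank - length(m), 1)
        at <- (mid - cfg$flank) + off  # 0-based anchor start + offset
        chars[[chrom]][(at + 1):(at + length(m))] <- m
      }
      chars
    }
    pos_i <- which(truth == 1)
    has_shared <- runif(length(pos_i)) < cfg$p_shared
    has_priv <- runif(length(pos_i)) < cfg$p_priv
    for (j in seq_along(pos_i)) {
      i <- pos_i[j]
      if (has_shared[j]) {
        study$chars <- plant(study$chars, chrom[i], mid1[i], cfg$shared_motif)
        study$chars <- plant(study$chars, chrom[i], mid2[i], cfg$shared_motif)
      }
      if (has_priv[j]) {
        pm <- cfg$private_motifs[[tissue]]
        study$chars <- plant(study$chars, chrom[i], mid1[i], pm)
        study$chars <- plant(study$chars, chrom[i], mid2[i], pm)
      }
    }
    if (is.null(study$interactions[[tissue]])) study$interactions[[tissue]] <- list()
    study$interactions[[tissue]][[itype]] <- df
    study$genome <- chars_to_genome(study$chars)
    study
  })
}

#' Generate per-tissue epigenetic coverage tracks
#'
#' Poisson background coverage per base, with the configured multiplicative
#' fold-enrichment over the standardized anchors of that tissue's true
#' positive interactions (all generated types).
#'
#' @param study A study whose interactions for `tissue` exist.
#' @param tissue Tissue identifier.
#' @return The updated study; tracks are in `study$tracks[[tissue]]`, one
#'   `RleList` per mark.
#' @export
simulate_tracks <- function(study, tissue) {
  cfg <- study$cfg
  ints <- do.call(rbind, study$interactions[[tissue]])
  if (is.null(ints)) stopf("no interactions generated yet for tissue '%s'", tissue)
  pos <- ints[ints$truth == 1, , drop = FALSE]
  stream <- cfg$seed + 15485863L * match(tissue, cfg$tissues)
  with_seed_(stream, {
    rates <- lapply(cfg$chrom_lengths, function(L) rep(cfg$background_rate, L))
    for (a in 1:2) {
      mid <- anchor_midpoint(pos[[paste0("start", a)]], pos[[paste0("end", a)]])
      ch <- pos[[paste0("chrom", a)]]
      for (i in seq_along(mid)) {
        at <- (mid[i] - cfg$flank + 1):(mid[i] + cfg$flank)
        rates[[ch[i]]][at] <- cfg$background_rate * cfg$enrichment_fold
      }
    }
    study$tracks[[tissue]] <- lapply(stats::setNames(cfg$marks, cfg$marks), function(mk) {
      methods::as(lapply(rates, function(r) S4Vectors::Rle(rpois(length(r), r))),
                  "SimpleRleList")
    })
  })
  study
}

simulate_aux_tracks <- function(study) {
  cfg <- study$cfg
  if (cfg$n_aux == 0) return(study)
  nms <- c("phastcons_synth", "MGW_synth", "HelT_synth", "ProT_synth", "Roll_synth")
  nms <- nms[seq_len(min(cfg$n_aux, length(nms)))]
  with_seed_(cfg$seed + 32452843L, {
    study$aux_tracks <- lapply(stats::setNames(nms, nms), function(nm) {
      methods::as(lapply(cfg$chrom_lengths, function(L) {
        # smooth bounded signal: random walk passed through a logistic squash
        S4Vectors::Rle(round(1 / (1 + exp(-cumsum(rnorm(L, sd = 0.02)))), 4))
      }), "SimpleRleList")
    })
  })
  study
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_interactions()] for every
#' tissue/type, [simulate_tracks()] for every tissue, and auxiliary tracks
#' if requested.
#'
#' @param cfg A [sim_config()].
#' @return A study list: `cfg`, `genome` (`DNAStringSet`), `genes`
#'   (data.frame), `interactions[[tissue]][[itype]]`,
#'   `tracks[[tissue]][[mark]]` (`RleList`), `aux_tracks`.
#' @export
simulate_study <- function(cfg) {
  study <- simulate_genome(cfg)
  for (t in cfg$tissues) {
    for (it in cfg$itypes) study <- simulate_interactions(study, t, it)
  }
  for (t in cfg$tissues) study <- simulate_tracks(study, t)
  simulate_aux_tracks(study)
}

#' Write a synthetic study to disk in pipeline-consumable formats
#'
#' FASTA genome, BED gene annotation, one BEDPE-like TSV per tissue/type
#' (columns `chrom1 start1 end1 chrom2 start2 end2 fdr type`), matching
#' `*_truth.tsv` truth tables, and one bedGraph per tissue/mark.
#'
#' @param study A study from [simulate_study()].
#' @param dir Output directory.
#' @param tracks Also write coverage bedGraphs (default TRUE; they are the
#'   bulkiest output).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, tracks = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(study$genome, file.path(dir, "genome.fa"))
  write.table(study$genes, file.path(dir, "genes.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (t in names(study$interactions)) {
    for (it in names(study$interactions[[t]])) {
      df <- study$interactions[[t]][[it]]
      out <- df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "fdr")]
      out$type <- it
      f <- file.path(dir, sprintf("%s_%s.tsv", t, it))
      writeLines(c("# synthetic pcHi-C interaction summary",
                   do.call(paste, c(unname(as.list(out)), sep = "\t"))), f)
      write.table(df, file.path(dir, sprintf("%s_%s_truth.tsv", t, it)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (tracks) {
    for (t in names(study$tracks)) {
      for (mk in names(study$tracks[[t]])) {
        gr <- rlelist_to_granges(study$tracks[[t]][[mk]])
        rtracklayer::export(gr, file.path(dir, sprintf("%s_%s.bedGraph", t, mk)),
                            format = "bedGraph")
      }
    }
  }
  invisible(dir)
}

# per-chromosome run-length signal -> GRanges with a score column,
# zero-coverage runs omitted (bedGraph convention)
rlelist_to_granges <- function(track) {
  parts <- lapply(names(track), function(nm) {
    r <- track[[nm]]
    len <- S4Vectors::runLength(r)
    val <- as.numeric(S4Vectors::runValue(r))
    starts <- cumsum(c(1L, head(len, -1L)))
    keep <- val != 0
    data.frame(chrom = nm, start = starts[keep], width = len[keep],
               score = val[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, width = df$width),
                         score = df$score)
}

#' Featurize one simulated tissue end-to-end
#'
#' Convenience wrapper chaining dataset construction ([prepare_dataset()])
#' and featurization ([build_feature_bundles()]) for a simulated study,
#' returning model-ready bundles plus the labeled dataset.
#'
#' @param study A study from [simulate_study()].
#' @param tissue Tissue identifier.
#' @param itype Interaction type.
#' @param active Feature subset to build.
#' @param window,step Track windowing (defaults scale with the anchor:
#'   `flank` and `flank/10`... explicitly: window = `flank`, step chosen so
#'   21 windows result).
#' @param ratio,seed Passed to [prepare_dataset()].
#' @return A list: `bundles`, `dataset`.
#' @export
featurize_tissue <- function(study, tissue, itype = "PE",
                             active = c("S", "R", "D"),
                             window = NULL, step = NULL, ratio = 1L, seed = 1L) {
  cfg <- study$cfg
  cands <- study$interactions[[tissue]][[itype]]
  if (is.null(cands)) stopf("tissue '%s' type '%s' not simulated", tissue, itype)
  ds <- prepare_dataset(cands, study$genome, flank = cfg$flank, ratio = ratio,
                        seed = seed)
  L <- 2 * cfg$flank
  window <- window %||% cfg$flank
  step <- step %||% ((L - window) %/% 20L)
  bundles <- build_feature_bundles(
    ds, genome = study$genome, tracks = study$tracks[[tissue]],
    aux_tracks = study$aux_tracks, active = active,
    window = window, step = step
  )
  list(bundles = bundles, dataset = ds)
}
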