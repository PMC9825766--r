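# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A deterministic toy genome built from an explicit sequence.
toy_genome <- function(seqs = c(chrT = "ACGTACGTACGTACGTACGT")) {
  Biostrings::DNAStringSet(seqs)
}

# Small simulated study shared by dataset/featurization tests:
# 2 tissues, PE only, 200-bp anchors, shifted distances, planted shared motif.
small_study <- function() {
  cached("small_study", function() {
    simulate_study(sim_config(
      chrom_lengths = c(chrA = 200000L, chrB = 200000L),
      tissues = c("T1", "T2"), itypes = c("PE", "PP"), n_pos = 60L,
      flank = 200L, pos_dist = c(3000, 20000), neg_dist = c(3000, 80000),
      n_genes = 30L, marks = c("openchrom", "H3K4me3"), n_aux = 2L,
      seed = 101L
    ))
  })
}

# Featurized small-study bundles (S+R+D+aux geometry: 400 bp anchors,
# window 200 / step 10 -> 21 windows).
small_bundles <- function() {
  cached("small_bundles", function() {
    featurize_tissue(small_study(), "T1", "PE",
                     active = c("S", "R", "D", "aux"), seed = 5L)
  })
}

# Compact model geometry matching the small study.
small_model_cfg <- function(active = c("S", "R", "D"), seed = 7L, ...) {
  model_config(active = active, anchor_len = 400L, n_windows = 21L,
               n_tracks = 2L, n_aux = 2L, filters = c(16L, 8L, 8L, 8L),
               fusion_filters = 16L, fc_width = 64L, seed = seed, ...)
}

# Tiny random bundles for pure network tests (no genome needed).
random_bundles <- function(n, cfg, seed = 1L, balanced = TRUE) {
  withr::with_seed(seed, {
    out <- list()
    if ("S" %in% cfg$active) {
      out$S <- array(rbinom(n * cfg$anchor_len * 4 * 2, 1, 0.25),
                     c(n, cfg$anchor_len, 4, 2))
    }
    if ("R" %in% cfg$active) {
      out$R <- array(abs(rnorm(n * cfg$n_windows * cfg$n_tracks * 2)),
                     c(n, cfg$n_windows, cfg$n_tracks, 2))
    }
    if ("aux" %in% cfg$active) {
      out$aux <- array(runif(n * cfg$n_windows * cfg$n_aux * 2),
                       c(n, cfg$n_windows, cfg$n_aux, 2))
    }
    if ("D" %in% cfg$active) out$D <- runif(n)
    out$label <- if (balanced) rep_len(c(1L, 0L), n) else rbinom(n, 1, 0.5)
    out$meta <- list(n = n, active = cfg$active, tissue = "toy", itype = "PE")
    structure(out, class = "feature_bundles")
  })
}

# Brute-force O(n^2) AUC oracle (pairwise comparisons, ties count 1/2).
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
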