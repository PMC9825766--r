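# Dataset construction: parsing, anchor standardization, filtering,
# FDR labeling, GC-matched negative sampling, and splits.

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("parse_interactions maps well-formed rows and rejects malformed ones", {
  f <- write_tsv_lines(c(
    "# comment",
    "chr1\t10000\t12000\tchr1\t60000\t62000\t0.02",
    "chr2\t500\t2500\tchr2\t9000\t12000\t0.70"
  ))
  cands <- parse_interactions(f, tissue = "GM", itype = "PE")
  expect_equal(nrow(cands), 2)
  expect_equal(cands$fdr, c(0.02, 0.70))
  expect_equal(cands$chrom1[1], "chr1")
  expect_equal(cands$start2[1], 60000L)
  expect_equal(unique(cands$tissue), "GM")
  expect_equal(unique(cands$itype), "PE")

  # empty file -> empty candidate list
  empty <- parse_interactions(write_tsv_lines("# nothing"), "GM", "PE")
  expect_equal(nrow(empty), 0)

  # fdr out of range names the offending line
  bad <- write_tsv_lines(c("chr1\t0\t100\tchr1\t500\t600\t0.5",
                           "chr1\t0\t100\tchr1\t500\t600\t1.5"))
  expect_error(parse_interactions(bad, "GM", "PE"), "line 2")

  # missing columns is a format error
  shrt <- write_tsv_lines("chr1\t0\t100\tchr1\t500")
  expect_error(parse_interactions(shrt, "GM", "PE"), "format error")
})

test_that("standardize_anchor centers a 2*flank window on the midpoint", {
  expect_equal(standardize_anchor(10000, 14000),
               data.frame(start = 11000L, end = 13000L))
  expect_equal(standardize_anchor(0, 2000), data.frame(start = 0L, end = 2000L))
  # odd-width anchors use the floored midpoint
  expect_equal(standardize_anchor(10, 15, flank = 2)$start, 10L)
  expect_error(standardize_anchor(500, 700), "underflow")
})

test_that("distance filter keeps intra-chromosomal pairs within the bound", {
  mk <- function(chrom2, mid2) data.frame(
    chrom1 = "chr1", start1 = 9000L, end1 = 11000L,
    chrom2 = chrom2, start2 = mid2 - 1000L, end2 = mid2 + 1000L,
    fdr = 0.01, tissue = "t", itype = "PE", stringsAsFactors = FALSE)
  cands <- rbind(mk("chr2", 50000),          # inter-chromosomal
                 mk("chr1", 10000 + 1000000), # exactly at the bound
                 mk("chr1", 10000 + 1000001), # one past the bound
                 mk("chr1", 30000))           # well inside
  kept <- filter_interactions(cands)
  expect_equal(interaction_distance(kept), c(1000000, 20000))
  expect_true(all(kept$chrom1 == kept$chrom2))
})

test_that("distance filter is monotone in max_distance", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      n <- 50
      mid1 <- sample(1e6, n)
      d <- sample(2e6, n)
      cands <- data.frame(
        chrom1 = "chr1", start1 = mid1 - 500, end1 = mid1 + 500,
        chrom2 = "chr1", start2 = mid1 + d - 500, end2 = mid1 + d + 500,
        fdr = runif(n), tissue = "t", itype = "PE")
      lo <- filter_interactions(cands, max_distance = 5e5)
      hi <- filter_interactions(cands, max_distance = 1.5e6)
      key <- function(x) paste(x$start1, x$start2)
      expect_true(all(key(lo) %in% key(hi)))
    }
  })
})

test_that("FDR labeling splits candidates at the configured cutoffs", {
  cands <- data.frame(
    chrom1 = "chr1", start1 = 0L, end1 = 2000L,
    chrom2 = "chr1", start2 = 5000L, end2 = 7000L,
    fdr = c(0.05, 0.6, 0.3, 0.1, 0.5), tissue = "t", itype = "PE")
  lab <- label_by_fdr(cands)
  expect_equal(lab$positives$fdr, 0.05)
  expect_equal(lab$negative_pool$fdr, 0.6)
  # 0.3 discarded; boundary values 0.1 and 0.5 excluded by strict inequality
  expect_equal(nrow(lab$positives) + nrow(lab$negative_pool), 2)
  # alternative regimes move the cutoffs
  lab2 <- label_by_fdr(cands, pos_cut = 0.05, neg_cut = 0.5)
  expect_equal(nrow(lab2$positives), 0)
  expect_error(label_by_fdr(cands, pos_cut = 0.6, neg_cut = 0.5), "configuration")
})

test_that("duplicate standardized anchor pairs keep the smallest FDR", {
  cands <- data.frame(
    chrom1 = "chr1", start1 = c(9000L, 9500L), end1 = c(11000L, 10500L),
    chrom2 = "chr1", start2 = c(19000L, 19500L), end2 = c(21000L, 20500L),
    fdr = c(0.4, 0.05), tissue = "t", itype = "PE")
  std <- standardize_interactions(cands, flank = 1000L)
  expect_equal(nrow(std), 1)
  expect_equal(std$fdr, 0.05)
})

test_that("standardization drops anchors that overlap chromosome ends", {
  genome <- toy_genome(c(chrT = strrep("ACGT", 2000)))  # 8 kb
  cands <- data.frame(
    chrom1 = "chrT", start1 = c(2000L, 7000L), end1 = c(4000L, 7800L),
    chrom2 = "chrT", start2 = c(4000L, 2000L), end2 = c(6000L, 4000L),
    fdr = 0.01, tissue = "t", itype = "PE")
  expect_warning(std <- standardize_interactions(cands, genome, flank = 1000L),
                 "chromosome end")
  expect_equal(nrow(std), 1)
  expect_equal(std$end1 - std$start1, 2000L)
})

test_that("GC-matched sampling matches the positive GC histogram", {
  # bimodal pool, unimodal positives: only matching-GC pool members drawn
  pos <- data.frame(id = 1:50, gc = rep(0.50, 50))
  pool <- data.frame(id = 101:300, gc = rep(c(0.20, 0.50), each = 100))
  neg <- sample_gc_matched_negatives(pos, pool, ratio = 1, seed = 3)
  expect_equal(nrow(neg), 50)
  expect_true(all(neg$gc == 0.50))
  # higher ratios are exact, and sampling is without replacement
  neg5 <- sample_gc_matched_negatives(pos, pool, ratio = 2, seed = 3)
  expect_equal(nrow(neg5), 100)
  expect_false(anyDuplicated(neg5$id) > 0)
  # determinism
  expect_equal(sample_gc_matched_negatives(pos, pool, ratio = 1, seed = 9),
               sample_gc_matched_negatives(pos, pool, ratio = 1, seed = 9))
  # insufficient pool reports the deficit
  expect_error(sample_gc_matched_negatives(pos, pool[1:30, ], ratio = 1, seed = 1),
               "deficit")
})

test_that("sampled negatives track the positive GC distribution (KS < 0.08)", {
  withr::with_seed(11, {
    pos <- data.frame(gc = runif(600, 0.35, 0.65))
    pool <- data.frame(gc = runif(6000, 0.30, 0.70))
    neg <- sample_gc_matched_negatives(pos, pool, ratio = 1, seed = 2)
    ks <- suppressWarnings(stats::ks.test(pos$gc, neg$gc)$statistic)
    expect_lt(unname(ks), 0.08)
  })
})

test_that("splits have the documented sizes and are seeded partitions", {
  sp <- split_dataset(100, seed = 1)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 70L, validation = 15L, test = 15L))
  sp2 <- split_dataset(20, fractions = c(0.85, 0.15), seed = 1)
  expect_equal(lengths(sp2[c("train", "validation")]),
               c(train = 17L, validation = 3L))
  expect_equal(split_dataset(57, seed = 42), split_dataset(57, seed = 42))
  expect_error(split_dataset(2, seed = 1), "split")

  withr::with_seed(8, {
    for (i in 1:1000) {
      n <- sample(3:200, 1)
      sp <- split_dataset(n, seed = sample(1e6, 1))
      all_idx <- c(sp$train, sp$validation, sp$test)
      expect_equal(sort(all_idx), seq_len(n))   # exhaustive & disjoint
    }
  })
})

test_that("prepare_dataset emits labeled interactions satisfying all invariants", {
  st <- small_study()
  cands <- st$interactions$T1$PE
  ds <- prepare_dataset(cands, st$genome, flank = st$cfg$flank, seed = 2)
  expect_true(all(ds$distance <= 1e6))
  expect_true(all(ds$fdr[ds$label == 1] < 0.1))
  expect_true(all(ds$fdr[ds$label == 0] > 0.5))
  expect_true(all(ds$gc >= 0 & ds$gc <= 1))
  expect_true(all(ds$end1 - ds$start1 == 2 * st$cfg$flank))
  expect_equal(sum(ds$label == 1), sum(ds$label == 0))
  # FDR labeling recovers the planted truth exactly
  expect_equal(ds$label, ds$truth)
})

test_that("datasets and splits round-trip through their text formats", {
  st <- small_study()
  ds <- prepare_dataset(st$interactions$T1$PE, st$genome,
                        flank = st$cfg$flank, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  expect_equal(readLines(f, n = 1),
               paste(names(ds), collapse = "\t"))  # header line present
  back <- read_dataset(f)
  expect_equal(back$label, ds$label)
  expect_equal(back$gc, ds$gc, tolerance = 1e-12)

  sp <- split_dataset(nrow(ds), seed = 3)
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, fs)
  back_sp <- read_split(fs)
  expect_equal(back_sp$train, sp$train)
  expect_equal(back_sp$test, sp$test)
})
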