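# Scoring metrics, repeated-split experiments, rank aggregation,
# rank-sum comparison, and cross-prediction.

test_that("AUC matches the pairwise-comparison definition", {
  expect_equal(auc_score(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auc_score(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "both classes")
  # integer score vectors with heavy ties: exact agreement with the oracle
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- 50
      labels <- rep_len(c(1, 0), n)
      scores <- sample(0:5, n, replace = TRUE)
      expect_identical(auc_score(labels, scores), auc_oracle(labels, scores))
    }
  })
})

test_that("AUC agrees with pROC on continuous scores", {
  withr::with_seed(41, {
    labels <- rbinom(100, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(100) + labels
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
    expect_equal(auc_score(labels, scores), ref, tolerance = 1e-12)
  })
})

test_that("AUC is invariant to strictly monotone score transforms", {
  withr::with_seed(17, {
    labels <- rbinom(80, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(80)
    a <- auc_score(labels, scores)
    expect_equal(auc_score(labels, exp(scores)), a)
    expect_equal(auc_score(labels, 3 * scores - 7), a)
    expect_equal(auc_score(labels, pnorm(scores)), a)
  })
})

test_that("AUPRC is step-wise average precision", {
  # perfect ranking: AP = 1
  expect_equal(auprc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  # hand-computed: ranking pos,neg,pos -> AP = (1/1 + 2/3)/2
  expect_equal(auprc_score(c(1, 0, 1), c(0.9, 0.5, 0.3)), (1 + 2 / 3) / 2)
  # naive threshold-walk oracle on random data
  ap_oracle <- function(labels, scores) {
    ths <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0
    ap <- 0
    for (t in ths) {
      sel <- scores >= t
      p <- sum(labels[sel]) / sum(sel)
      r <- sum(labels[sel]) / sum(labels)
      ap <- ap + (r - prev_r) * p
      prev_r <- r
    }
    ap
  }
  withr::with_seed(13, {
    for (i in 1:25) {
      labels <- rep_len(c(1, 0, 0), 60)
      scores <- sample(0:9, 60, replace = TRUE)  # ties included
      expect_equal(auprc_score(labels, scores), ap_oracle(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("repeated-split experiments produce a complete seeded results table", {
  fz <- small_bundles()
  b <- fz$bundles
  # deterministic stand-in scorers (no training) keep this test fast:
  # one distance-based, one random
  methods <- list(
    dist = function(bundles, split) -bundles$D[split$test],
    noise = function(bundles, split) {
      withr::with_seed(split$seed, runif(length(split$test)))
    }
  )
  res <- run_experiments(b, methods, repeats = 10, seeds = 1:10)
  expect_equal(nrow(res), 20)
  expect_equal(as.integer(table(res$method)), c(10L, 10L))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  res2 <- run_experiments(b, methods, repeats = 10, seeds = 1:10)
  expect_equal(res, res2)                       # same seeds -> identical table
  smoke <- run_experiments(b, methods, repeats = 2, seeds = c(5, 9))
  expect_equal(nrow(smoke), 4)
  expect_error(run_experiments(b, methods, repeats = 2, seeds = c(3, 3)),
               "distinct")
})

test_that("rank aggregation ranks methods by median AUC per tissue", {
  res <- expand.grid(tissue = c("A", "B", "C"), method = c("m1", "m2", "m3"),
                     repeat_idx = 1:4, stringsAsFactors = FALSE)
  res$itype <- "PE"
  # m1 best everywhere, m2 and m3 tied on tissue C
  base <- c(m1 = 0.9, m2 = 0.8, m3 = 0.7)
  res$auc <- base[res$method]
  res$auc[res$tissue == "C" & res$method == "m3"] <- 0.8
  rs <- rank_methods(res)
  expect_equal(unname(rs$ranks["A", ]), c(1, 2, 3))
  expect_equal(unname(rs$ranks["C", c("m2", "m3")]), c(2.5, 2.5))  # average ties
  expect_true(all(abs(rowSums(rs$ranks) - 6) < 1e-12))             # permutation sums
  expect_equal(unname(rs$rank_counts["m1", "rank1"]), 3)
  expect_error(rank_methods(res[res$method != "m2" | res$tissue != "B", ]),
               "missing")
})

test_that("method comparison is a two-sided Wilcoxon rank-sum test", {
  m <- cbind(m1 = c(1, 2, 3), m2 = c(4, 5, 6))
  expect_equal(compare_methods(m, "m1", "m2"), 0.1)   # exact: 2/20 assignments
  same <- cbind(a = c(0.7, 0.8, 0.9), b = c(0.7, 0.8, 0.9))
  expect_equal(compare_methods(same, "a", "b"), 1.0)
  expect_error(compare_methods(cbind(a = 1:2, b = 3:4), "a", "b"), "3 tissues")
})

test_that("exact rank-sum p-values match full enumeration for n = 6 + 6", {
  enum_p <- function(x, y) {
    pool <- c(x, y)
    r <- rank(pool)
    n1 <- length(x)
    obs <- sum(r[seq_len(n1)])
    combos <- utils::combn(length(pool), n1)
    sums <- apply(combos, 2, function(ix) sum(r[ix]))
    mu <- n1 * (length(pool) + 1) / 2
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
  }
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- round(runif(6), 6)
      y <- round(runif(6) + 0.2, 6)
      m <- cbind(m1 = x, m2 = y)
      expect_equal(compare_methods(m, "m1", "m2"), enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("cross-prediction scores a model on the other interaction type", {
  cfg <- small_model_cfg(active = c("S", "D"), seed = 3)
  m <- build_model(cfg)
  b_pp <- random_bundles(40, cfg, seed = 8)
  b_pp$meta$itype <- "PP"
  before <- pchicnet:::collect_params(m)
  row <- cross_predict(m, b_pp, tissue = "T1", method = "PE-to-PP")
  expect_equal(row$itype, "PP")
  expect_true(row$auc >= 0 && row$auc <= 1)
  expect_identical(pchicnet:::collect_params(m), before)  # no weight updates
  # same-type evaluation reduces to ordinary scoring
  expect_equal(cross_predict(m, b_pp)$auc,
               auc_score(b_pp$label, predict(m, b_pp)))
  # incompatible feature sets are refused
  cfg_r <- small_model_cfg(active = c("R", "D"), seed = 3)
  expect_error(cross_predict(build_model(cfg_r), b_pp), "incompatible")
})
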