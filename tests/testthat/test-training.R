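# Training regimes: optimizer schedule, early stopping, reproducibility,
# freezing, pretraining, multi-task and transfer mechanics, and the
# distance-only ablation on shifted vs matched fixtures.

# compact S+D bundles from the shared study, used by several blocks
train_fixture <- function() {
  cached("train_fixture", function() {
    st <- small_study()
    out <- list(study = st)
    for (t in c("T1", "T2")) {
      out[[t]] <- featurize_tissue(st, t, "PE", active = c("S", "D"), seed = 4)
    }
    out
  })
}

fast_tcfg <- function(...) {
  train_config(lr = 1e-3, batch_size = 32, ...)
}

test_that("the learning-rate schedule decays and epochs respect the caps", {
  fx <- train_fixture()
  b <- fx$T1$bundles
  sp <- split_dataset(b$meta$n, seed = 1)
  tcfg <- fast_tcfg(max_epochs = 6, patience = 5, seed = 2)
  fit <- train_base(b, sp, small_model_cfg(active = c("S", "D"), seed = 3), tcfg)
  h <- fit$history
  expect_lte(nrow(h), 6)
  expect_true(all(diff(h$lr) < 0))                       # monotone decay
  expect_equal(h$lr, 1e-3 * 0.96^(h$epoch - 1))
  expect_equal(fit$best_val_loss, min(h$val_loss))       # best weights restored
})

test_that("early stopping halts after patience non-decreasing epochs", {
  # random labels carry no signal, so validation loss plateaus quickly
  cfg <- small_model_cfg(active = "D", seed = 5)
  b <- random_bundles(200, cfg, seed = 6, balanced = FALSE)
  b$label <- withr::with_seed(7, sample(b$label))
  sp <- split_dataset(200, seed = 2)
  tcfg <- fast_tcfg(max_epochs = 50, patience = 3, seed = 8)
  fit <- train_base(b, sp, cfg, tcfg)
  h <- fit$history
  expect_lte(nrow(h), 50)
  if (nrow(h) < 50) {
    best_epoch <- which.min(h$val_loss)
    # stopped exactly `patience` epochs after the last improvement
    expect_equal(nrow(h), max(which(h$val_loss == min(h$val_loss))) + 3)
    expect_gte(nrow(h) - best_epoch, 3)
  }
})

test_that("training is reproducible given identical seeds and data", {
  fx <- train_fixture()
  b <- fx$T1$bundles
  sp <- split_dataset(b$meta$n, seed = 9)
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 10)
  tcfg <- fast_tcfg(max_epochs = 5, patience = 5, seed = 11)
  f1 <- train_base(b, sp, mcfg, tcfg)
  f2 <- train_base(b, sp, mcfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1$model, subset_bundles(b, sp$test)),
                   predict(f2$model, subset_bundles(b, sp$test)))
})

test_that("pretraining pools source tissues with an 85/15 split", {
  fx <- train_fixture()
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 12)
  tcfg <- fast_tcfg(max_epochs = 5, patience = 5, seed = 13)
  pre <- pretrain_shared(list(T2 = fx$T2$bundles), exclude = "T1", mcfg, tcfg)
  expect_s3_class(pre$model, "phic_model")
  n_pool <- fx$T2$bundles$meta$n
  expect_equal(length(pre$split$train), floor(0.85 * n_pool))
  expect_equal(length(pre$split$validation), n_pool - floor(0.85 * n_pool))
  expect_null(pre$split$test)
  expect_error(
    pretrain_shared(list(T1 = fx$T1$bundles, T2 = fx$T2$bundles),
                    exclude = "T1", mcfg, tcfg),
    "present in the pretraining pool")
})

test_that("bundle pooling concatenates tissues consistently", {
  fx <- train_fixture()
  pooled <- concat_bundles(list(T1 = fx$T1$bundles, T2 = fx$T2$bundles))
  n1 <- fx$T1$bundles$meta$n
  expect_equal(pooled$meta$n, n1 + fx$T2$bundles$meta$n)
  expect_equal(pooled$S[n1 + 3, , , ], fx$T2$bundles$S[3, , , ])
  expect_equal(pooled$label, c(fx$T1$bundles$label, fx$T2$bundles$label))
})

test_that("multi-task training freezes the shared extractor", {
  fx <- train_fixture()
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 14)
  tcfg <- fast_tcfg(max_epochs = 5, patience = 5, seed = 15)
  pre <- pretrain_shared(list(T2 = fx$T2$bundles), exclude = "T1", mcfg, tcfg)
  shared_before <- pchicnet:::collect_params(pre$model)
  b <- fx$T1$bundles
  sp <- split_dataset(b$meta$n, seed = 16)
  ml <- train_multitask(b, sp, pre, mcfg, tcfg)
  m <- ml$model
  expect_equal(m$mode, "multitask")
  # shared weights bitwise-unchanged by target training
  shared_after <- pchicnet:::collect_params(
    list(extractor = m$shared$extractor, classifier = m$shared$head))
  expect_identical(shared_after[grep("^ext", names(shared_after))],
                   shared_before[grep("^ext", names(shared_before))])
  # classifier consumes [common || private || D]
  expect_equal(nrow(m$classifier$fc1$W), 2 * m$fused_dim + 1)
  # extracted features are [common || private]
  f <- extract_features(m, subset_bundles(b, 1:4))
  expect_equal(ncol(f), 2 * m$fused_dim)
  p <- predict(m, subset_bundles(b, sp$test))
  expect_true(all(p > 0 & p < 1))
})

test_that("multi-task checkpoints round-trip through save/load", {
  fx <- train_fixture()
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 30)
  tcfg <- fast_tcfg(max_epochs = 5, patience = 5, seed = 31)
  pre <- pretrain_shared(list(T2 = fx$T2$bundles), exclude = "T1", mcfg, tcfg)
  b <- fx$T1$bundles
  sp <- split_dataset(b$meta$n, seed = 32)
  ml <- train_multitask(b, sp, pre, mcfg, tcfg)
  probe <- subset_bundles(b, 1:10)
  dir <- withr::local_tempdir()
  save_model(ml$model, dir)
  back <- load_model(dir)
  expect_equal(back$mode, "multitask")
  expect_equal(predict(back, probe), predict(ml$model, probe), tolerance = 1e-6)
})

test_that("transfer learning starts from the pretrained extractor and moves it", {
  fx <- train_fixture()
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 17)
  tcfg <- fast_tcfg(max_epochs = 5, patience = 5, seed = 18)
  pre <- pretrain_shared(list(T2 = fx$T2$bundles), exclude = "T1", mcfg, tcfg)
  pre_w <- pchicnet:::collect_params(pre$model)
  b <- fx$T1$bundles
  sp <- split_dataset(b$meta$n, seed = 19)
  # at learning rate 0 fine-tuning is a no-op: weights stay at initialization
  tl0 <- train_transfer(b, sp, pre, mcfg,
                        train_config(lr = 0, max_epochs = 5, patience = 5,
                                     batch_size = 32, seed = 20))
  w0 <- pchicnet:::collect_params(tl0$model)
  ext <- grep("^ext", names(pre_w), value = TRUE)
  expect_identical(w0[ext], pre_w[ext])
  # with a real learning rate, all layers move
  tl <- train_transfer(b, sp, pre, mcfg, tcfg)
  w1 <- pchicnet:::collect_params(tl$model)
  expect_false(identical(w1[ext], pre_w[ext]))
})

test_that("a frozen extractor yields unchanged features after classifier training", {
  fx <- train_fixture()
  mcfg <- small_model_cfg(active = c("S", "D"), seed = 21)
  m <- freeze_extractor(build_model(mcfg))
  b <- fx$T1$bundles
  probe <- subset_bundles(b, 1:6)
  before <- extract_features(m, probe)
  sp <- split_dataset(b$meta$n, seed = 22)
  fit <- pchicnet:::fit_network(m, b, sp$train, sp$validation,
                                fast_tcfg(max_epochs = 5, patience = 5, seed = 23))
  expect_equal(extract_features(fit$model, probe), before, tolerance = 1e-12)
  # but the classifier did train
  expect_false(identical(fit$model$classifier$fc1$W, m$classifier$fc1$W))
})

test_that("distance alone separates shifted fixtures but not matched ones", {
  fx <- train_fixture()
  st <- fx$study
  dcfg <- small_model_cfg(active = "D", seed = 24)
  tcfg <- fast_tcfg(max_epochs = 40, patience = 5, seed = 25)

  ds_shift <- fx$T1$dataset
  b_shift <- build_feature_bundles(ds_shift, active = "D")
  sp <- split_dataset(b_shift$meta$n, seed = 26)
  fit <- train_base(b_shift, sp, dcfg, tcfg)
  auc_shift <- auc_score(b_shift$label[sp$test],
                         predict(fit$model, subset_bundles(b_shift, sp$test)))
  expect_gt(auc_shift, 0.8)

  cfg_m <- sim_config(chrom_lengths = c(c1 = 400000L, c2 = 400000L),
                      tissues = "T1", itypes = "PE", n_pos = 150L,
                      flank = 200L, distance_mode = "matched",
                      pos_dist = c(3000, 30000), n_genes = 10L,
                      marks = "openchrom", seed = 131L)
  st_m <- simulate_study(cfg_m)
  ds_m <- prepare_dataset(st_m$interactions$T1$PE, st_m$genome,
                          flank = 200L, seed = 2)
  b_m <- build_feature_bundles(ds_m, active = "D")
  sp_m <- split_dataset(b_m$meta$n, seed = 27)
  fit_m <- train_base(b_m, sp_m, dcfg, tcfg)
  auc_m <- auc_score(b_m$label[sp_m$test],
                     predict(fit_m$model, subset_bundles(b_m, sp_m$test)))
  expect_gt(auc_m, 0.30)
  expect_lt(auc_m, 0.70)
})
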