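test_that("conv layer gradients match finite differences", {
  set.seed(1)
  ly <- eegarousal:::nn_conv_layer(5, 2, 3)
  x <- array(rnorm(20 * 2 * 4), c(20, 2, 4))
  fw <- eegarousal:::conv_forward(ly, x)
  g <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- eegarousal:::conv_backward(ly, fw$cache, g)
  eps <- 1e-4
  loss_at <- function(layer, xx) sum(eegarousal:::conv_forward(layer, xx)$out * g)
  for (i in c(1, 8, 17)) {
    lp <- ly; lp$W[i] <- lp$W[i] + eps
    lm <- ly; lm$W[i] <- lm$W[i] - eps
    expect_equal(bw$grads$W[i], (loss_at(lp, x) - loss_at(lm, x)) / (2 * eps),
                 tolerance = 1e-2)
  }
  for (i in c(3, 50)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bw$gx[i], (loss_at(ly, xp) - loss_at(ly, xm)) / (2 * eps),
                 tolerance = 1e-2)
  }
})

test_that("LSTM gradients match finite differences", {
  set.seed(2)
  ly <- eegarousal:::nn_lstm_layer(3, 4)
  X <- array(rnorm(5 * 3 * 6), c(5, 3, 6))  # (B, in, T)
  fw <- eegarousal:::lstm_forward(ly, X)
  g <- array(rnorm(length(fw$seq)), dim(fw$seq))
  bw <- eegarousal:::lstm_backward(ly, fw$cache, g)
  eps <- 1e-5
  loss_at <- function(layer, XX)
    sum(eegarousal:::lstm_forward(layer, XX)$seq * g)
  for (nm in c("W", "U", "b")) {
    i <- 2
    lp <- ly; lp[[nm]][i] <- lp[[nm]][i] + eps
    lm <- ly; lm[[nm]][i] <- lm[[nm]][i] - eps
    expect_equal(bw$grads[[nm]][i],
                 (loss_at(lp, X) - loss_at(lm, X)) / (2 * eps),
                 tolerance = 1e-4)
  }
  i <- 11
  Xp <- X; Xp[i] <- Xp[i] + eps
  Xm <- X; Xm[i] <- Xm[i] - eps
  expect_equal(bw$gx[i], (loss_at(ly, Xp) - loss_at(ly, Xm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("networks reject inputs that do not fit the architecture", {
  cnn <- build_cnn()
  expect_error(train_submodel(cnn, matrix(0, 500, 4), c(0, 1, 0, 1)))
  expect_error(build_cnn(cnn_spec(input_length = 40L)), "shorter than")
  rnn <- build_rnn()
  expect_error(train_submodel(rnn, array(0, c(10, 8, 4)), c(0, 1, 0, 1)))
  expect_error(predict_proba(build_forest(), matrix(0, 3, 42)),
               "not been trained")
})

test_that("training is deterministic and probabilities are valid", {
  set.seed(3)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  # tiny separable waveform problem: arousal = added high-frequency tone
  tt <- (0:5999) / 200
  X <- sapply(seq_len(n), function(i)
    rnorm(6000) + y[i] * 2 * sin(2 * pi * 25 * tt))
  cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 11)
  m1 <- train_submodel(build_cnn(seed = 7), X, y, cfg)
  m2 <- train_submodel(build_cnn(seed = 7), X, y, cfg)
  expect_equal(m1$history$train, m2$history$train, tolerance = 1e-6)
  p1 <- predict_proba(m1, X)
  p2 <- predict_proba(m2, X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(rowSums(p1), rep(1, n), tolerance = 1e-6)
})

test_that("the band-power RNN learns an easy separation", {
  set.seed(4)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  A <- array(exp(rnorm(29 * 8 * n)), c(29, 8, n))
  A[, 3, y == 1] <- A[, 3, y == 1] * 8   # alpha column boosted
  cfg <- train_config(epochs = 10L, batch_size = 16L, seed = 5)
  rnn <- train_submodel(build_rnn(seed = 5), A, y, cfg)
  pr <- predict_proba(rnn, A)
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-6)
  expect_gt(auroc(y, pr[, "arousal"]), 0.95)
  # batch-order invariance of prediction
  perm <- sample(n)
  expect_equal(predict_proba(rnn, A[, , perm])[, "arousal"],
               pr[perm, "arousal"], tolerance = 1e-12)
})

test_that("the forest memorizes training points and reproduces with a seed", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 42), n, 42)
  X[y == 1, 7] <- X[y == 1, 7] + 3
  colnames(X) <- expert_feature_names()
  f1 <- train_submodel(build_forest(seed = 9), X, y)
  f2 <- train_submodel(build_forest(seed = 9), X, y)
  p1 <- predict_proba(f1, X); p2 <- predict_proba(f2, X)
  expect_identical(p1, p2)
  own <- ifelse(y == 1, p1[, "arousal"], p1[, "normal"])
  expect_true(all(own >= 0.5))
  expect_error(train_submodel(build_forest(), X[, 1:10], y), "42")
})

test_that("the pre-merged network stacks a 44-dim embedding", {
  pm_census <- param_census(build_premerge(build_cnn(), build_rnn()))
  expect_equal(pm_census$out_x[pm_census$layer == "Pre-merge concat"], 44L)
  set.seed(6)
  n <- 30
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(6000 * n), 6000, n)
  A <- array(exp(rnorm(29 * 8 * n)), c(29, 8, n))
  A[, 3, y == 1] <- A[, 3, y == 1] * 8
  pm <- build_premerge(build_cnn(seed = 2), build_rnn(seed = 2),
                       freeze_trunks = TRUE)
  pm <- train_submodel(pm, list(wave = X, band = A), y,
                       train_config(epochs = 4L, batch_size = 8L, seed = 3))
  pr <- predict_proba(pm, list(wave = X, band = A))
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-6)
})

test_that("permuted labels leave the merged head uninformative", {
  set.seed(7)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(6000 * n), 6000, n)  # no signal at all
  A <- array(exp(rnorm(29 * 8 * n)), c(29, 8, n))
  y_perm <- sample(y)
  tr <- 1:140; te <- 141:200
  pm <- build_premerge(build_cnn(seed = 4), build_rnn(seed = 4),
                       freeze_trunks = TRUE)
  pm <- train_submodel(pm, list(wave = X[, tr], band = A[, , tr]), y_perm[tr],
                       train_config(epochs = 3L, batch_size = 16L, seed = 8))
  pr <- predict_proba(pm, list(wave = X[, te], band = A[, , te]))
  expect_equal(auroc(y_perm[te], pr[, "arousal"]), 0.5, tolerance = 0.17)
})

test_that("a shift-free generator leaves every feature uninformative", {
  cfg <- synth_config(record_duration = 2100, arousal_band_shift = 1,
                      seed = 55)
  recs <- generate_dataset(cfg, 4)
  feat <- prepare_features(recs, run_config(segment = list(discard_edges = 30),
                                            forest = list(num_trees = 200L)))
  expect_gt(mean(feat$y), 0.2)
  tr <- which(feat$record_id %in% c("synth-01", "synth-02", "synth-03"))
  te <- setdiff(seq_len(feat$n), tr)
  forest <- train_submodel(build_forest(forest_spec(num_trees = 200L),
                                        seed = 10),
                           feat$expert[tr, ], feat$y[tr])
  a <- auroc(feat$y[te], predict_proba(forest, feat$expert[te, ])[, "arousal"])
  expect_equal(a, 0.5, tolerance = 0.12)
})
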