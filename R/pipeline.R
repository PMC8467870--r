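#' Preprocess records and extract every feature set
#'
#' Filters each record with the 127-order low-pass filter, segments it
#' into labeled 30-s windows, and computes the waveform matrix, the
#' 29 x 8 band-power matrices and the 1 x 42 expert vectors for all
#' segments.
#'
#' @param records list of `eeg_record`s (or a single record).
#' @param config a [run_config()].
#' @return list of class `segment_features`: `wave` (6000 x n matrix),
#'   `band` (29 x 8 x n array), `expert` (n x 42 matrix), `y` (labels),
#'   `record_id`, `start_offset`, `n`.
#' @export
prepare_features <- function(records, config = run_config()) {
  if (inherits(records, "eeg_record")) records <- list(records)
  fs <- config$sampling_rate
  filt <- design_filter(
    filter_spec(order = config$filter$order,
                passband_edge = config$filter$passband_edge,
                stopband_edge = config$filter$stopband_edge,
                realization = config$filter$realization), fs)
  tapers <- if (config$spectral$taper_length == 400L &&
                config$spectral$n_tapers == 8L &&
                config$spectral$nw == 4.5) default_tapers()
            else compute_dpss(config$spectral$taper_length,
                              config$spectral$n_tapers, config$spectral$nw)
  segs <- list()
  for (rec in records) {
    filtered <- apply_filter(rec, filt)
    segs <- c(segs, segment_record(filtered,
                                   discard_edges = config$segment$discard_edges,
                                   window = config$segment$window,
                                   min_duration = config$segment$min_duration))
  }
  n <- length(segs)
  if (n == 0) stop("no segments produced; records too short?")
  win <- round(config$segment$window * fs)
  wave <- matrix(NA_real_, win, n)
  band <- array(NA_real_, c(29L, 8L, n))
  expert <- matrix(NA_real_, n, 42L,
                   dimnames = list(NULL, expert_feature_names()))
  for (i in seq_len(n)) {
    x <- segs[[i]]$samples
    wave[, i] <- x
    bm <- band_matrix(x, tapers, ratio_cap = config$spectral$ratio_cap)
    band[, , i] <- bm
    expert[i, ] <- expert_vector(x, bm)
  }
  structure(list(
    wave = wave, band = band, expert = expert,
    y = vapply(segs, function(s) s$label, integer(1)),
    record_id = vapply(segs, function(s) s$record_id, character(1)),
    start_offset = vapply(segs, function(s) s$start_offset, numeric(1)),
    n = n), class = "segment_features")
}

#' Subset a `segment_features` object by segment index
#'
#' @param feat a `segment_features` object.
#' @param idx integer vector of segment indices to keep.
#' @return the subsetted `segment_features`.
#' @export
subset_features <- function(feat, idx) {
  structure(list(wave = feat$wave[, idx, drop = FALSE],
                 band = feat$band[, , idx, drop = FALSE],
                 expert = feat$expert[idx, , drop = FALSE],
                 y = feat$y[idx], record_id = feat$record_id[idx],
                 start_offset = feat$start_offset[idx],
                 n = length(idx)), class = "segment_features")
}

train_all_submodels <- function(feat, config, verbose = FALSE) {
  tc <- function(offset, over = list()) {
    tr <- modifyList(config$train, over)
    train_config(
      epochs = tr$epochs, batch_size = tr$batch_size,
      lr = tr$lr, patience = tr$patience,
      val_fraction = tr$val_fraction,
      seed = config$seed + offset, verbose = verbose)
  }
  cnn <- build_cnn(seed = config$seed + 11L)
  cnn <- train_submodel(cnn, feat$wave, feat$y, tc(1L, config$train_cnn))
  rnn <- build_rnn(seed = config$seed + 12L)
  rnn <- train_submodel(rnn, feat$band, feat$y, tc(2L, config$train_rnn))
  forest <- build_forest(
    forest_spec(num_trees = config$forest$num_trees,
                min_node_size = config$forest$min_node_size),
    seed = config$seed + 13L)
  forest <- train_submodel(forest, feat$expert, feat$y)
  pm <- build_premerge(cnn, rnn, seed = config$seed + 14L,
                       freeze_trunks = config$premerge$freeze_trunks)
  pm <- train_submodel(pm, list(wave = feat$wave, band = feat$band),
                       feat$y, tc(3L, config$train_premerge))
  list(cnn = cnn, rnn = rnn, forest = forest, premerge = pm)
}

submodel_probs <- function(models, feat) {
  list(cnn = predict_proba(models$cnn, feat$wave),
       rnn = predict_proba(models$rnn, feat$band),
       forest = predict_proba(models$forest, feat$expert),
       premerge = predict_proba(models$premerge,
                                list(wave = feat$wave, band = feat$band)))
}

#' Fit the full stacked arousal detector
#'
#' Trains the four base classifiers and the logistic-regression
#' meta-classifier.  Meta-training protocols: `"holdout"` (default)
#' carves off a record-disjoint fraction of the training data, trains
#' the sub-models on the remainder and fits the meta-classifier on the
#' held-out sub-model predictions; `"insample"` trains everything on all
#' data and stacks the in-sample predictions; `"oof"` uses k-fold
#' out-of-fold sub-model predictions (k retrainings -- expensive for the
#' networks).
#'
#' @param feat a `segment_features` object (the training data).
#' @param config a [run_config()].
#' @param verbose print per-epoch training logs.
#' @return An object of class `arousal_detector`: the four trained
#'   sub-models, meta coefficients `beta` and the config.
#' @export
fit_stack <- function(feat, config = run_config(), verbose = FALSE) {
  protocol <- config$meta$protocol
  if (protocol == "holdout") {
    ids <- unique(feat$record_id)
    n_meta <- max(1L, round(config$meta$meta_fraction * length(ids)))
    meta_ids <- with_seed(config$seed + 21L, sample(ids, n_meta))
    meta_idx <- which(feat$record_id %in% meta_ids)
    sub_idx <- setdiff(seq_len(feat$n), meta_idx)
    if (length(meta_idx) == 0 || length(sub_idx) == 0)
      stop("holdout meta split failed; too few records")
    models <- train_all_submodels(subset_features(feat, sub_idx), config,
                                  verbose)
    pr <- submodel_probs(models, subset_features(feat, meta_idx))
    P <- meta_input(unname(pr))
    y_meta <- feat$y[meta_idx]
  } else if (protocol == "insample") {
    models <- train_all_submodels(feat, config, verbose)
    pr <- submodel_probs(models, feat)
    P <- meta_input(unname(pr))
    y_meta <- feat$y
  } else if (protocol == "oof") {
    k <- config$evaluation$k_folds
    ids <- unique(feat$record_id)
    if (length(ids) < k) stop("fewer records than folds for oof stacking")
    # record-disjoint fold assignment
    fold_of_id <- with_seed(config$seed + 21L,
                            stats::setNames(rep_len(seq_len(k),
                                                    length(ids)),
                                            sample(ids)))
    fold <- fold_of_id[feat$record_id]
    Pparts <- vector("list", k); yparts <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      mods <- train_all_submodels(subset_features(feat, tr), config,
                                  verbose)
      pr <- submodel_probs(mods, subset_features(feat, te))
      Pparts[[f]] <- meta_input(unname(pr))
      yparts[[f]] <- feat$y[te]
    }
    P <- do.call(rbind, Pparts)
    y_meta <- unlist(yparts)
    models <- train_all_submodels(feat, config, verbose)
  } else stop("unknown meta protocol: ", protocol)

  mf <- fit_meta(P, y_meta, step0 = config$meta$step0,
                 tol = config$meta$tol, max_iter = config$meta$max_iter)
  structure(list(models = models, beta = mf$beta, meta_fit = mf,
                 protocol = protocol, config = config),
            class = "arousal_detector")
}

#' Train and evaluate the detector on the synthetic benchmark
#'
#' Reproduces the package's reference study conditions end to end:
#' generates a dataset of 4-h synthetic records (about 40% positive 30-s
#' segments after edge discard), holds out a record-disjoint test split,
#' fits the four sub-models and the stacking meta-classifier on the
#' remainder, and evaluates everything on the held-out records.  The
#' training profile is the package's reduced-epoch benchmark profile
#' (the waveform CNN converges on this data within two epochs; the
#' pre-merge trunks are kept frozen so the merged head trains on cached
#' embeddings).
#'
#' @param seed master seed controlling generation, splits and training.
#' @param n_records number of records (default 9, about 2160 segments).
#' @param record_duration per-record duration in seconds.
#' @param test_fraction fraction of records held out for testing.
#' @param verbose print training progress.
#' @return list with `eval` (per-model metrics from
#'   [evaluate_detector()]), `detector`, `n_test`, `n_total`,
#'   `prevalence`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_records = 9L,
                                record_duration = 14400,
                                test_fraction = 0.2, verbose = FALSE) {
  seed <- as.integer(seed) %% 1000000L
  cfg <- run_config(
    seed = seed,
    synth = list(record_duration = record_duration),
    train = list(epochs = 12L, batch_size = 64L, patience = 4L),
    train_cnn = list(epochs = 2L, batch_size = 32L, patience = 2L),
    train_premerge = list(epochs = 8L),
    premerge = list(freeze_trunks = TRUE),
    meta = list(protocol = "holdout"))
  sc <- synth_config(record_duration = record_duration, seed = seed)
  records <- generate_dataset(sc, n_records)
  feat <- prepare_features(records, cfg)
  ids <- unique(feat$record_id)
  n_test <- max(1L, round(test_fraction * length(ids)))
  test_ids <- with_seed(seed + 31L, sample(ids, n_test))
  te <- which(feat$record_id %in% test_ids)
  tr <- setdiff(seq_len(feat$n), te)
  det <- fit_stack(subset_features(feat, tr), cfg, verbose = verbose)
  ev <- evaluate_detector(det, subset_features(feat, te))
  list(eval = ev, detector = det, n_test = length(te), n_total = feat$n,
       prevalence = mean(feat$y))
}

#' Per-segment predictions of the stacked detector
#'
#' @param object an `arousal_detector`.
#' @param feat a `segment_features` object.
#' @param ... unused.
#' @return data.frame with each sub-model's arousal probability, the
#'   meta probability `h`, and the decision `label` (1 iff `h > 0.5`).
#' @export
predict.arousal_detector <- function(object, feat, ...) {
  pr <- submodel_probs(object$models, feat)
  P <- meta_input(unname(pr))
  dec <- predict_meta(P, object$beta)
  data.frame(record_id = feat$record_id, start_offset = feat$start_offset,
             cnn = pr$cnn[, "arousal"], rnn = pr$rnn[, "arousal"],
             forest = pr$forest[, "arousal"],
             premerge = pr$premerge[, "arousal"],
             h = dec$probability, label = dec$label)
}

#' Evaluate the detector and each sub-model on labeled segments
#'
#' @param det an `arousal_detector`.
#' @param feat a `segment_features` object with labels.
#' @return list with per-model metric lists (accuracy, sensitivity,
#'   specificity, precision, auroc) for the four sub-models and the
#'   meta-classifier.
#' @export
evaluate_detector <- function(det, feat) {
  pred <- predict(det, feat)
  score_cols <- c("cnn", "rnn", "forest", "premerge", "h")
  names(score_cols) <- c("cnn", "rnn", "forest", "premerge", "meta")
  out <- list()
  for (nm in names(score_cols)) {
    s <- pred[[score_cols[[nm]]]]
    m <- eval_metrics(confusion(feat$y, s > 0.5))
    m$auroc <- auroc(feat$y, s)
    out[[nm]] <- m
  }
  out
}
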