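#' Full run configuration with package defaults
#'
#' One nested list holding every tunable of the pipeline; serializable to
#' YAML and back losslessly, so any run can be reproduced from its config
#' file plus the seed.
#'
#' @param ... named overrides of the defaults, e.g.
#'   `run_config(train = list(epochs = 3))` (partial lists are merged).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sampling_rate = 200,
    synth = list(record_duration = 14400, arousal_rate = 59,
                 arousal_duration_range = c(3, 15), arousal_band_shift = 3,
                 mains_freq = 60, mains_amplitude = 0.5, noise_floor = 0.1),
    filter = list(order = 127L, passband_edge = 40, stopband_edge = 42,
                  realization = "fir"),
    segment = list(discard_edges = 3600, window = 30, min_duration = 3),
    spectral = list(taper_length = 400L, n_tapers = 8L, nw = 4.5,
                    ratio_cap = 1e6),
    train = list(epochs = 30L, batch_size = 64L, lr = 1e-3, patience = 5L,
                 val_fraction = 0.15),
    # per-network overrides of the base training settings (merged on top):
    # the CNN sees 6000-sample inputs and converges in a couple of epochs,
    # the cheaper RNN benefits from more
    train_cnn = list(), train_rnn = list(), train_premerge = list(),
    forest = list(num_trees = 500L, min_node_size = 1L),
    premerge = list(freeze_trunks = FALSE),
    meta = list(protocol = "holdout", meta_fraction = 0.2, step0 = 0.1,
                tol = 1e-8, max_iter = 1e5),
    evaluation = list(test_fraction = 0.2, k_folds = 5L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
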