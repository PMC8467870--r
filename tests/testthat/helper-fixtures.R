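# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small labeled dataset: 4 records of 25 minutes, short edge discard so
# module tests stay fast (120 segments, both classes well represented)
tiny_config <- function() run_config(
  synth = list(record_duration = 1500),
  segment = list(discard_edges = 30),
  train = list(epochs = 2L, batch_size = 16L, patience = 2L),
  forest = list(num_trees = 100L),
  meta = list(protocol = "insample")
)

tiny_records <- function() fixture("tiny_records", function() {
  cfg <- synth_config(record_duration = 1500, seed = 101)
  generate_dataset(cfg, 4)
})

tiny_features <- function() fixture("tiny_features", function() {
  prepare_features(tiny_records(), tiny_config())
})

# naive reference statistics used as oracles against the vectorized code
naive_mean <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }
naive_sd <- function(x) {
  m <- naive_mean(x); s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
naive_kurtosis <- function(x) {
  m <- naive_mean(x); s4 <- 0
  for (v in x) s4 <- s4 + (v - m)^4
  (s4 / length(x)) / naive_sd(x)^4
}
naive_skewness <- function(x) {
  m <- naive_mean(x); s3 <- 0
  for (v in x) s3 <- s3 + (v - m)^3
  (s3 / length(x)) / naive_sd(x)^3
}
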