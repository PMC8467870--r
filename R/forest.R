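#' Random-forest specification for the expert features
#'
#' @param num_trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(42)) = 6`.
#' @param min_node_size minimal node size (1 = fully grown trees).
#' @param input_dim expected feature dimension (42).
#' @return list of class `forest_spec`.
#' @export
forest_spec <- function(num_trees = 500L, mtry = NULL, min_node_size = 1L,
                        input_dim = 42L) {
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 input_dim = as.integer(input_dim)),
            class = "forest_spec")
}

#' Build the expert-feature random forest
#'
#' @param spec a [forest_spec()].
#' @param seed forest RNG seed (single-threaded fitting, so the same
#'   seed reproduces the forest exactly).
#' @return An object of class `forest_model` (untrained).
#' @export
build_forest <- function(spec = forest_spec(), seed = 1L) {
  structure(list(spec = spec, seed = as.integer(seed), fit = NULL,
                 trained = FALSE),
            class = "forest_model")
}

#' @export
train_submodel.forest_model <- function(model, x, y,
                                        config = train_config()) {
  x <- as.matrix(x)
  if (ncol(x) != model$spec$input_dim)
    stop("expected ", model$spec$input_dim, " features, got ", ncol(x))
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x) %||% paste0("f", seq_len(ncol(x))))
  df$.label <- factor(as.integer(as.logical(y)), levels = c(0, 1))
  mtry <- model$spec$mtry %||% floor(sqrt(ncol(x)))
  model$fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = model$spec$num_trees, mtry = mtry,
    min.node.size = model$spec$min_node_size,
    probability = TRUE, seed = model$seed, num.threads = 1)
  model$feature_names <- names(df)[names(df) != ".label"]
  model$trained <- TRUE
  model
}

#' @export
predict_proba.forest_model <- function(model, x, batch_size = NULL) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  df <- as.data.frame(as.matrix(x))
  names(df) <- model$feature_names
  pr <- predict(model$fit, data = df, num.threads = 1)$predictions
  out <- cbind(normal = pr[, "0"], arousal = pr[, "1"])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
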