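#' Assemble the meta-classifier design matrix
#'
#' Each sub-model contributes its two class probabilities (normal,
#' arousal); with four sub-models and a leading intercept column the meta
#' input is p = (1, p1, ..., p8).
#'
#' @param prob_list list of numeric matrices, each `n x 2` with columns
#'   (p_normal, p_arousal), one per sub-model, in a fixed order.
#' @return An `n x (1 + 2 * length(prob_list))` design matrix.
#' @export
meta_input <- function(prob_list) {
  stopifnot(is.list(prob_list), length(prob_list) >= 1)
  n <- nrow(prob_list[[1]])
  for (pm in prob_list) {
    if (!is.matrix(pm) || ncol(pm) != 2 || nrow(pm) != n)
      stop("each probability block must be an n x 2 matrix")
    if (max(abs(rowSums(pm) - 1)) > 1e-6)
      stop("probability pairs must sum to 1")
  }
  P <- cbind(1, do.call(cbind, prob_list))
  colnames(P) <- c("(intercept)",
                   paste0(rep(paste0("m", seq_along(prob_list)),
                              each = 2),
                          c("_normal", "_arousal")))
  P
}

#' Logistic response h_beta = exp(p'b) / (1 + exp(p'b))
#'
#' Numerically stable for large |p'b| (computed via `plogis`-style
#' branching, no overflow).
#'
#' @param P design matrix (rows are meta inputs, first column intercept)
#'   or a single vector.
#' @param beta coefficient vector (intercept first).
#' @return probabilities in (0, 1).
#' @export
logistic_h <- function(P, beta) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (ncol(P) != length(beta)) stop("dimension mismatch between p and beta")
  eta <- drop(P %*% beta)
  out <- ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  as.numeric(out)
}

#' Mean cross-entropy cost of the meta-classifier
#'
#' J(beta) = -(1/M) sum y log h + (1-y) log(1-h), with probabilities
#' clipped away from 0 and 1 so the logs stay finite.
#'
#' @param P design matrix (M rows).
#' @param y 0/1 labels of length M.
#' @param beta coefficient vector.
#' @param eps clipping bound for the probabilities.
#' @return scalar cost `J >= 0`.
#' @export
meta_cost <- function(P, y, beta, eps = 1e-12) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  M <- nrow(P)
  if (M == 0) stop("empty training set")
  h <- pmin(pmax(logistic_h(P, beta), eps), 1 - eps)
  -mean(y * log(h) + (1 - y) * log(1 - h))
}

#' Fit the stacking coefficients by gradient descent
#'
#' Minimizes the cross-entropy cost from a zero start with backtracking
#' (Armijo) line search; the step grows again after accepted iterations so
#' well-conditioned problems converge quickly.  The design matrix produced
#' by [meta_input()] is rank-deficient (each probability pair sums to one,
#' next to an intercept); gradient descent still converges to a
#' minimum-cost point, which is all the decision rule needs.
#'
#' @param P design matrix (M x d, intercept in column 1).
#' @param y 0/1 labels; both classes must be present.
#' @param step0 initial step size.
#' @param tol convergence tolerance on the gradient infinity norm.
#' @param max_iter iteration cap.
#' @return list with `beta`, `cost`, `grad_norm`, `iterations`,
#'   `converged`.
#' @export
fit_meta <- function(P, y, step0 = 0.1, tol = 1e-8, max_iter = 1e5) {
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2)
    stop("both classes must be present (single-class optimum is unbounded)")
  M <- nrow(P); d <- ncol(P)
  beta <- numeric(d)
  J <- meta_cost(P, y, beta)
  step <- step0
  it <- 0L
  repeat {
    h <- logistic_h(P, beta)
    g <- drop(crossprod(P, h - y)) / M
    gn <- max(abs(g))
    if (gn < tol || it >= max_iter) break
    # Armijo backtracking on the descent direction -g
    g2 <- sum(g * g)
    repeat {
      beta_new <- beta - step * g
      J_new <- meta_cost(P, y, beta_new)
      if (J_new <= J - 1e-4 * step * g2 || step < 1e-14) break
      step <- step / 2
    }
    beta <- beta_new
    J <- J_new
    step <- min(step * 2, 1e3)
    it <- it + 1L
  }
  list(beta = beta, cost = J, grad_norm = max(abs(g)),
       iterations = it, converged = max(abs(g)) < tol)
}

#' Decide arousal from the fitted meta-classifier
#'
#' Declares an arousal only when the posterior probability strictly
#' exceeds 0.5.
#'
#' @param P design matrix or single meta-input vector.
#' @param beta fitted coefficients.
#' @return data.frame with columns `probability` and `label` (0/1).
#' @export
predict_meta <- function(P, beta) {
  h <- logistic_h(P, beta)
  data.frame(probability = h, label = as.integer(h > 0.5))
}
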