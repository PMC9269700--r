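#' Train the motion classifier (multinomial logistic regression)
#'
#' Fits an unregularized multinomial (softmax) logistic regression with
#' class-balanced sample weights by L-BFGS on the weighted negative
#' log-likelihood, with analytic gradients and an iteration cap of 6000.
#' Balanced weighting gives every class the same total weight
#' (`w_i = n / (K * n_class(i))`), which compensates the rest-heavy label
#' distribution of the movement trials; duplicating every training row
#' leaves the fitted decision function unchanged.
#'
#' @param x numeric feature matrix (rows = timesteps).
#' @param y factor (or vector) of class labels; at least two classes must
#'   be present.
#' @param class_weight `"balanced"` or `"uniform"`.
#' @param max_iter L-BFGS iteration cap.
#' @param tol convergence tolerance on the projected gradient of the mean
#'   weighted negative log-likelihood (the reference default of the
#'   field's usual L-BFGS solvers).
#' @param init optional coefficient matrix from a previous fit (same shape
#'   and class levels) used as a warm start; the optimum and stopping
#'   criterion are unchanged.
#' @return An object of class `emg_classifier` with the coefficient matrix
#'   (`(p+1) x K`, first row the intercepts), class levels and convergence
#'   information.
#' @export
train_classifier <- function(x, y, class_weight = c("balanced", "uniform"),
                             max_iter = 6000, tol = 1e-4, init = NULL) {
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- nrow(x); p <- ncol(x); K <- nlevels(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  w <- if (class_weight == "balanced") {
    tab <- tabulate(as.integer(y), K)
    (n / (K * tab))[as.integer(y)]
  } else {
    rep(1, n)
  }
  W <- sum(w)
  # precondition: optimize on standardized columns (same MLE, far better
  # conditioned), then map coefficients back to the original scale
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)
  sigma[sigma <= 0 | !is.finite(sigma)] <- 1
  X <- cbind(`(Intercept)` = 1, sweep(sweep(x, 2, mu), 2, sigma, "/"))
  yi <- as.integer(y)
  # optim() evaluates fn and gr at the same point back-to-back; cache the
  # shared softmax pass so each L-BFGS step costs one matmul pair
  cache <- new.env(parent = emptyenv())
  shared <- function(par) {
    if (!identical(par, cache$par)) {
      B <- matrix(par, p + 1, K)
      st <- softmax_terms(X %*% B, w, yi)
      cache$par <- par
      cache$loglik <- st$loglik
      cache$G <- st$G
    }
    cache
  }
  nll <- function(par) -shared(par)$loglik / W
  gr <- function(par) as.numeric(crossprod(X, shared(par)$G)) / W

  # map a coefficient matrix on the original feature scale to the
  # standardized parameterization used during optimization
  to_std <- function(b) {
    as.numeric(rbind(b[1, ] + colSums(b[-1, , drop = FALSE] * mu),
                     b[-1, , drop = FALSE] * sigma))
  }
  par0 <- numeric((p + 1) * K)
  if (!is.null(init) && identical(colnames(init), levels(y)) &&
      nrow(init) == p + 1) {
    par0 <- to_std(unname(init))
  } else if (n > 40000) {
    # coarse fit on a deterministic row subsample as a warm start; the
    # final optimum and stopping criterion on the full data are unchanged
    idx <- seq.int(1L, n, by = ceiling(n / 20000))
    coarse <- train_classifier(x[idx, , drop = FALSE], y[idx],
                               class_weight = class_weight,
                               max_iter = max_iter, tol = 10 * tol)
    if (identical(coarse$classes, levels(y))) par0 <- to_std(coarse$coef)
  }
  fit <- optim(par0, nll, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = tol, factr = 1e7))
  coef_std <- matrix(fit$par, p + 1, K)
  coef <- rbind(coef_std[1, ] - colSums(coef_std[-1, , drop = FALSE] * mu / sigma),
                coef_std[-1, , drop = FALSE] / sigma)
  dimnames(coef) <- list(c("(Intercept)", colnames(x)), levels(y))
  structure(list(coef = coef, classes = levels(y),
                 feature_names = colnames(x),
                 converged = fit$convergence == 0,
                 value = fit$value, counts = fit$counts,
                 class_weight = class_weight),
            class = "emg_classifier")
}

#' Predict motion classes or class probabilities
#'
#' @param object an `emg_classifier`.
#' @param newdata numeric feature matrix with the training columns.
#' @param type `"class"` for hard labels, `"prob"` for softmax
#'   probabilities.
#' @param ... unused.
#' @return A factor of predicted classes, or a probability matrix.
#' @export
predict.emg_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(newdata))
  Z <- X %*% object$coef
  if (type == "class") {
    return(factor(object$classes[max.col(Z, ties.method = "first")],
                  levels = object$classes))
  }
  zmax <- do.call(pmax, as.data.frame(Z))
  E <- exp(Z - zmax)
  P <- E / rowSums(E)
  colnames(P) <- object$classes
  P
}

#' @export
print.emg_classifier <- function(x, ...) {
  cat(sprintf("<emg_classifier> %d classes (%s), %d features, %sconverged (NLL %.4f)\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              nrow(x$coef) - 1, if (x$converged) "" else "NOT ", x$value))
  invisible(x)
}

#' Classification accuracy in percent
#'
#' `100 * correct / (correct + incorrect)` over paired prediction/truth
#' vectors.
#'
#' @param predictions,truth equal-length vectors of class labels.
#' @return Accuracy in percent.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0 || length(truth) == 0) {
    stop("empty input", call. = FALSE)
  }
  if (length(predictions) != length(truth)) {
    stop("predictions and truth lengths differ", call. = FALSE)
  }
  100 * mean(as.character(predictions) == as.character(truth))
}
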