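#' Fit a linear soft-margin SVM and expose its dual solution
#'
#' Thin wrapper around [e1071::svm()] (libsvm) that returns the pieces the
#' ranking machinery needs: support vectors, signed dual coefficients
#' `alpha_i * y_i`, the primal weight vector of the linear kernel, and the
#' trained dual objective recomputed from those coefficients,
#' `obj = 0.5 * c' K c - sum(alpha)` (the minimized form, as libsvm reports).
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Binary labels (0/1 or a two-level factor); class `1` is the
#'   positive class.
#' @param cost Soft-margin cost parameter C (default 1).
#' @return An `svm_fit` with fields `model` (the e1071 object),
#'   `support_vector_indices`, `dual_coefficients`, `support_vectors`,
#'   `primal_weights`, `objective_value`, `cost`, `feature_names`.
#' @export
fit_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 1L) stop("need >= 2 samples and >= 1 feature")
  yf <- factor(as.integer(as.character(factor(y))), levels = c(0L, 1L))
  if (anyNA(yf)) stop("labels must be binary 0/1")
  if (nlevels(droplevels(yf)) < 2L) stop("both classes must be present")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  model <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  co <- as.numeric(model$coefs)          # alpha_i * y'_i for libsvm's +1 class
  SV <- as.matrix(model$SV)
  # orient so that positive dual coefficients belong to class "1"
  pos_first <- .svm_positive_class(model) == "1"
  if (!pos_first) co <- -co
  w <- drop(crossprod(SV, co))
  K <- tcrossprod(SV)
  obj <- 0.5 * drop(crossprod(co, K %*% co)) - sum(abs(co))
  structure(
    list(model = model,
         support_vector_indices = model$index,
         dual_coefficients = co,
         support_vectors = SV,
         primal_weights = stats::setNames(w, colnames(X)),
         objective_value = obj,
         cost = cost,
         feature_names = colnames(X)),
    class = "svm_fit")
}

# libsvm orders classes by first appearance in the training data; decision
# values are positive for the class it saw first (model$labels[1]).
.svm_positive_class <- function(model) {
  as.character(model$levels[model$labels[1L]])
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("svm_fit: linear kernel, C=%g, %d support vectors, %d features, obj=%.6g\n",
              x$cost, length(x$dual_coefficients), length(x$primal_weights),
              x$objective_value))
  invisible(x)
}

#' Decision values of a fitted SVM, oriented toward class 1
#'
#' @param fit An `svm_fit`.
#' @param X Matrix of samples (rows) to score, same feature columns as used
#'   for training.
#' @return Numeric vector; larger values indicate class 1 (case).
#' @export
svm_decision_values <- function(fit, X) {
  stopifnot(inherits(fit, "svm_fit"))
  dv <- attr(stats::predict(fit$model, as.matrix(X), decision.values = TRUE),
             "decision.values")
  dv <- as.numeric(dv)
  if (.svm_positive_class(fit$model) != "1") dv <- -dv
  dv
}

#' Objective-change weight of one feature
#'
#' The relevance weight of feature `g` is the change in the trained dual
#' objective when `g` is removed from every support vector while the dual
#' coefficients are held fixed:
#' `weight(g) = obj(v_1..v_s) - obj(v_1^(g)..v_s^(g))`.
#' For the linear kernel this equals `0.5 * w_g^2`, half the squared primal
#' weight; the function computes the objective difference explicitly.
#'
#' @param fit An `svm_fit`.
#' @param feature Feature name or column index.
#' @return The scalar weight (non-negative for the linear kernel).
#' @export
feature_weight <- function(fit, feature) {
  stopifnot(inherits(fit, "svm_fit"))
  if (is.character(feature)) {
    g <- match(feature, fit$feature_names)
    if (is.na(g)) stop("unknown feature: ", feature)
  } else {
    g <- as.integer(feature)
    if (g < 1L || g > length(fit$feature_names)) stop("unknown feature index: ", g)
  }
  co <- fit$dual_coefficients
  SV <- fit$support_vectors
  Kdrop <- tcrossprod(SV[, -g, drop = FALSE])
  obj_drop <- 0.5 * drop(crossprod(co, Kdrop %*% co)) - sum(abs(co))
  fit$objective_value - obj_drop
}

# Fast path used by the ranking ensemble: all per-feature objective-change
# weights of a linear fit at once, via the 0.5 * w^2 identity.
.feature_weights_all <- function(fit) {
  0.5 * fit$primal_weights^2
}
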