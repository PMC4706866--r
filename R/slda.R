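#' Fit a shrinkage linear discriminant classifier
#'
#' Two-class LDA with the pooled within-class covariance shrunk toward a
#' scaled identity, `S~ = (1 - lambda) S + lambda (tr(S)/d) I`, which keeps
#' the discriminant stable when the feature count approaches the trial
#' count. The weight vector is `S~^{-1} (mu_C - mu_NC)` and the bias places
#' the decision boundary midway between the projected class means.
#'
#' @param train_feats a [feature_matrix()], or numeric matrix if `labels`
#'   is given.
#' @param labels per-trial labels (ignored when `train_feats` is a
#'   [feature_matrix()]).
#' @param shrinkage `"auto"` for the analytic Ledoit-Wolf-style intensity,
#'   or a fixed value in `[0, 1]` (0 = classical LDA, 1 = nearest class
#'   mean under an isotropic metric).
#' @return An `slda_model`: `weights`, `bias`, `shrinkage`, `class_means`,
#'   `classes` (first class scores positive).
#' @export
fit_slda <- function(train_feats, labels = NULL, shrinkage = "auto") {
  if (inherits(train_feats, "feature_matrix")) {
    X <- train_feats$values
    labels <- train_feats$labels
  } else {
    X <- as.matrix(train_feats)
    if (is.null(labels)) stop("labels are required with a plain matrix")
  }
  classes <- intersect(c("C", "NC"), unique(labels))
  if (length(classes) < 2) classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes")
  i1 <- labels == classes[1]
  i2 <- labels == classes[2]
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("each class needs at least 2 trials")
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  Xc <- rbind(sweep(X[i1, , drop = FALSE], 2, mu1),
              sweep(X[i2, , drop = FALSE], 2, mu2))
  lambda <- if (identical(shrinkage, "auto")) {
    lw_shrinkage(Xc)
  } else {
    if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
      stop("shrinkage must be in [0, 1] or \"auto\"")
    shrinkage
  }
  d <- ncol(X)
  S <- crossprod(Xc) / nrow(Xc)
  St <- (1 - lambda) * S + diag(lambda * sum(diag(S)) / d, d)
  w <- tryCatch(solve(St, mu1 - mu2), error = function(e)
    stop("shrunk covariance is singular; raise the shrinkage", call. = FALSE))
  structure(
    list(weights = as.numeric(w),
         bias = -sum(w * (mu1 + mu2) / 2),
         shrinkage = lambda,
         class_means = rbind(mu1, mu2),
         classes = classes),
    class = "slda_model")
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf("<slda_model> %d features, shrinkage %.4f, classes %s > 0 > %s\n",
              length(x$weights), x$shrinkage, x$classes[1], x$classes[2]))
  invisible(x)
}

#' Predict with a shrinkage LDA model
#'
#' @param model an `slda_model`.
#' @param feats a [feature_matrix()] or numeric matrix with matching
#'   feature count.
#' @return List with `labels` (predicted conditions; an exact tie score maps
#'   to the first class) and signed `scores`.
#' @export
predict_slda <- function(model, feats) {
  X <- if (inherits(feats, "feature_matrix")) feats$values else
    as.matrix(feats)
  if (ncol(X) != length(model$weights))
    stop("feature count (", ncol(X), ") does not match the model (",
         length(model$weights), ")")
  scores <- as.numeric(X %*% model$weights + model$bias)
  list(labels = ifelse(scores >= 0, model$classes[1], model$classes[2]),
       scores = scores)
}
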