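# Ledoit-Wolf-style analytic shrinkage intensity toward a scaled identity.
# X: centered observations in rows. Returns lambda in [0, 1].
lw_shrinkage <- function(X) {
  n <- nrow(X)
  d <- ncol(X)
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / d
  d2 <- sum((S - diag(mu, d))^2)
  if (d2 <= 0) return(0)
  r2 <- rowSums(X^2)
  b2 <- (sum(r2^2) / n - sum(S^2)) / n
  max(0, min(1, b2 / d2))
}

# Between- and within-class scatter of an epoch set, over channels.
# S_b is built from the class-mean ERP matrices (channels x samples),
# S_w from per-trial residuals around the class means. Both are averaged
# over their observation counts.
refsf_scatter <- function(epochs) {
  classes <- intersect(c("C", "NC"), unique(epochs$labels))
  if (length(classes) < 2) classes <- sort(unique(epochs$labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  d <- dim(epochs$data)[2]
  T_ <- dim(epochs$data)[3]
  means <- lapply(classes, function(cl) {
    idx <- which(epochs$labels == cl)
    if (length(idx) < 2) stop("need >= 2 trials per class")
    apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  })
  grand <- Reduce(`+`, means) / length(means)
  S_b <- matrix(0, d, d)
  for (m in means) {
    dm <- m - grand
    S_b <- S_b + tcrossprod(dm)
  }
  S_b <- S_b / (length(means) * T_)
  S_w <- matrix(0, d, d)
  n_obs <- 0
  resid <- NULL
  for (ci in seq_along(classes)) {
    idx <- which(epochs$labels == classes[ci])
    for (i in idx) {
      r <- epochs$data[i, , ] - means[[ci]]
      S_w <- S_w + tcrossprod(r)
      n_obs <- n_obs + T_
    }
  }
  S_w <- S_w / n_obs
  list(S_b = S_b, S_w = S_w, classes = classes, means = means,
       n_obs = n_obs)
}

# residual observations (rows) for the analytic shrinkage estimate
refsf_residuals <- function(epochs, scatter) {
  d <- dim(epochs$data)[2]
  out <- vector("list", n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    ci <- match(epochs$labels[i], scatter$classes)
    out[[i]] <- t(epochs$data[i, , ] - scatter$means[[ci]])
  }
  do.call(rbind, out)
}

# unit-norm columns with the largest-|entry| coefficient positive
fix_sign <- function(W, normalize = TRUE) {
  apply(W, 2, function(w) {
    if (normalize) w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    w
  })
}

#' Fit regularized eigen Fisher spatial filters (REFSF)
#'
#' Estimates linear channel combinations that maximize a Fisher criterion for
#' ERP classification: the ratio of between-class scatter (built from the
#' class-mean ERP matrices) to within-class scatter (built from per-trial
#' residuals around the class means). The within-class scatter is shrunk
#' toward a scaled identity before solving the generalized eigenproblem
#' `S_b w = lambda S_w w`; the top eigenvectors are the spatial filters that
#' project multichannel epochs onto a few discriminant "virtual" channels.
#'
#' @param train an [epoch_set()] with two classes, already cropped to the
#'   time window of interest.
#' @param n_components number of filters to retain (default 5).
#' @param shrink shrinkage intensity in `[0, 1]`, or `"auto"` for an analytic
#'   Ledoit-Wolf-style estimate from the training residuals.
#' @return A `spatial_filter_bank`: `weights` (channels x components, unit
#'   norm, ordered by decreasing eigenvalue), `eigenvalues`, `method`,
#'   `channel_labels`, `shrinkage`.
#' @export
fit_refsf <- function(train, n_components = 5, shrink = "auto") {
  sc <- refsf_scatter(train)
  d <- nrow(sc$S_w)
  if (n_components > d)
    stop("n_components cannot exceed the channel count")
  lambda <- if (identical(shrink, "auto")) {
    lw_shrinkage(refsf_residuals(train, sc))
  } else {
    if (!is.numeric(shrink) || shrink < 0 || shrink > 1)
      stop("shrink must be in [0, 1] or \"auto\"")
    shrink
  }
  Sw <- (1 - lambda) * sc$S_w +
    lambda * diag(sum(diag(sc$S_w)) / d, d)
  R <- tryCatch(chol(Sw), error = function(e)
    stop("regularized within-class scatter is singular; raise `shrink`",
         call. = FALSE))
  Ri <- backsolve(R, diag(d))
  C <- crossprod(Ri, sc$S_b) %*% Ri
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  W <- Ri %*% e$vectors[, seq_len(n_components), drop = FALSE]
  structure(
    list(weights = fix_sign(W),
         eigenvalues = e$values[seq_len(n_components)],
         method = "REFSF", band = NULL, delay = NULL,
         channel_labels = train$channel_labels,
         classes = sc$classes, shrinkage = lambda),
    class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf("<spatial_filter_bank> %s: %d x %d", x$method,
              nrow(x$weights), ncol(x$weights)))
  if (!is.null(x$band))
    cat(sprintf(", band %g-%g Hz, delay %d", x$band[1], x$band[2], x$delay))
  cat(sprintf(", eigenvalues %s\n",
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' Project epochs through a spatial filter bank
#'
#' Premultiplies each trial by the transposed filter weights, turning
#' channel epochs into "virtual channel" epochs labelled `VC1..VCk`.
#'
#' @param epochs an [epoch_set()] whose channels match the bank.
#' @param bank a `spatial_filter_bank` with one weight row per channel.
#' @return An [epoch_set()] with `ncol(bank$weights)` virtual channels.
#' @export
apply_filters <- function(epochs, bank) {
  if (nrow(bank$weights) != length(epochs$channel_labels) ||
      !identical(bank$channel_labels, epochs$channel_labels))
    stop("bank channel labels do not match the epochs",
         if (!is.null(bank$delay) && bank$delay > 0)
           " (delay-augmented CSSP banks are applied by cssp_features())")
  d <- dim(epochs$data)
  k <- ncol(bank$weights)
  out <- array(0, dim = c(d[1], k, d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- crossprod(bank$weights, epochs$data[i, , ])
  epoch_set(out, epochs$labels, epochs$times, epochs$sampling_rate,
            paste0("VC", seq_len(k)), epochs$subject_id)
}

#' Cohort-level channel importance from REFSF weights
#'
#' For each subject, averages the absolute spatial-filter coefficients
#' across components per channel, then linearly maps the per-subject values
#' so the least important channel scores -1 and the most important +1;
#' scores are averaged across subjects and ranked.
#'
#' @param banks list of per-subject REFSF `spatial_filter_bank`s sharing the
#'   same channel labels.
#' @param top_k how many top channels to list (default 14, the upper half of
#'   a 28-channel montage).
#' @return A `channel_importance` object: data.frame `table` with `channel`,
#'   `score` (in `[-1, 1]`), `rank`, and the `selected` top-`top_k` labels.
#' @export
channel_importance <- function(banks, top_k = 14) {
  labels <- banks[[1]]$channel_labels
  for (b in banks)
    if (!identical(b$channel_labels, labels))
      stop("all banks must share the same channel labels")
  if (top_k > length(labels)) stop("top_k exceeds the channel count")
  per_subject <- vapply(banks, function(b) {
    v <- rowMeans(abs(b$weights))
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("degenerate all-equal weights; mapped to 0")
      return(rep(0, length(v)))
    }
    -1 + 2 * (v - rng[1]) / (rng[2] - rng[1])
  }, numeric(length(labels)))
  score <- rowMeans(per_subject)
  rk <- rank(-score, ties.method = "first")
  structure(
    list(table = data.frame(channel = labels, score = score, rank = rk,
                            stringsAsFactors = FALSE),
         selected = labels[order(rk)][seq_len(top_k)]),
    class = "channel_importance")
}

#' @export
print.channel_importance <- function(x, ...) {
  cat("<channel_importance> top channels:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
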