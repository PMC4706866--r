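#' Monte-Carlo majority-vote accuracy
#'
#' Repeatedly draws clusters of `n` same-condition test trials (distinct
#' trials within a cluster, with replacement across clusters), labels each
#' cluster by the majority of the individual classifications, and averages
#' cluster correctness over draws and conditions. This estimates how the
#' classifier would perform over a sequence of `n` identical stimuli.
#'
#' @param correct logical (or 0/1) per-trial correctness indicators.
#' @param conditions optional per-trial condition labels; when given,
#'   clusters are drawn within condition and the estimate averages the
#'   per-condition accuracies.
#' @param n cluster size, odd (ties are undefined otherwise).
#' @param n_draws number of clusters per condition.
#' @param seed integer seed.
#' @return A `majority_vote_estimate`: `n`, `n_draws`, `accuracy` (%),
#'   `se` (standard error, %), `seed`.
#' @export
majority_vote_mc <- function(correct, conditions = NULL, n = 3,
                             n_draws = 1e5, seed = 1L) {
  if (n %% 2 == 0) stop("cluster size n must be odd")
  correct <- as.logical(correct)
  if (is.null(conditions)) conditions <- rep("all", length(correct))
  groups <- split(seq_along(correct), conditions)
  for (g in groups)
    if (length(g) < n)
      stop("each condition needs at least n = ", n, " test trials")
  with_seed(seed, {
    per <- vapply(groups, function(idx) {
      m <- length(idx)
      if (n == 1) {
        draws <- matrix(sample.int(m, n_draws, replace = TRUE), ncol = 1)
      } else {
        draws <- matrix(sample.int(m, n * n_draws, replace = TRUE),
                        nrow = n_draws)
        pairs <- utils::combn(n, 2)
        repeat {
          dup <- rep(FALSE, nrow(draws))
          for (j in seq_len(ncol(pairs)))
            dup <- dup | draws[, pairs[1, j]] == draws[, pairs[2, j]]
          if (!any(dup)) break
          draws[dup, ] <- sample.int(m, n * sum(dup), replace = TRUE)
        }
      }
      hits <- rowSums(matrix(correct[idx][draws], nrow = n_draws)) > n / 2
      c(mean(hits), stats::var(hits))
    }, numeric(2))
    acc <- mean(per[1, ])
    se <- sqrt(sum(per[2, ] / n_draws)) / length(groups)
    structure(list(n = n, n_draws = n_draws, accuracy = 100 * acc,
                   se = 100 * se, seed = seed),
              class = "majority_vote_estimate")
  })
}

#' @export
print.majority_vote_estimate <- function(x, ...) {
  cat(sprintf("<majority_vote_estimate> n = %d: %.2f%% (SE %.3f, %d draws)\n",
              x$n, x$accuracy, x$se, x$n_draws))
  invisible(x)
}

#' Closed-form majority-vote accuracy under independence
#'
#' If single trials are classified correctly independently with probability
#' `p`, a majority vote over `n` trials is correct with probability
#' `sum_{k > n/2} C(n, k) p^k (1-p)^(n-k)` - the binomial oracle against
#' which the Monte-Carlo estimate is checked.
#'
#' @param p single-trial accuracy in `[0, 1]` (vectorized).
#' @param n odd cluster size(s); vectorized when `p` is scalar.
#' @return Majority-vote accuracy in `[0, 1]`.
#' @export
binomial_majority <- function(p, n = 3) {
  if (any(n %% 2 == 0)) stop("cluster size n must be odd")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (length(n) > 1) {
    if (length(p) != 1) stop("vectorize over p or n, not both")
    return(vapply(n, function(k)
      stats::pbinom(floor(k / 2), k, p, lower.tail = FALSE), numeric(1)))
  }
  stats::pbinom(floor(n / 2), n, p, lower.tail = FALSE)
}

#' Summarize per-subject accuracies at the cohort level
#'
#' @param results list of `subject_result`s, or a numeric vector of
#'   per-subject accuracies in percent.
#' @return A `cohort_result`: `per_subject` data.frame, `mean` and sample
#'   `sd` (n - 1 denominator; `NA` for a single subject), `n_subjects`.
#' @export
cohort_summary <- function(results) {
  if (is.numeric(results)) {
    acc <- results
    ids <- sprintf("S%02d", seq_along(acc))
  } else {
    if (length(results) == 0) stop("no subject results")
    acc <- vapply(results, `[[`, numeric(1), "accuracy")
    ids <- vapply(results, `[[`, character(1), "subject_id")
  }
  if (length(acc) == 0) stop("no subject results")
  structure(
    list(per_subject = data.frame(subject_id = ids, accuracy = acc,
                                  stringsAsFactors = FALSE),
         mean = mean(acc),
         sd = if (length(acc) > 1) stats::sd(acc) else NA_real_,
         n_subjects = length(acc)),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects: mean %.2f%%, SD %s\n",
              x$n_subjects, x$mean,
              if (is.na(x$sd)) "not defined (single subject)"
              else sprintf("%.2f", x$sd)))
  invisible(x)
}

#' Binomial chance-level accuracy bound
#'
#' Smallest accuracy whose exceedance probability under random guessing
#' (binomial, p = 0.5, `n_test_trials` trials) is below `alpha`. A
#' classifier scoring at or above this bound performs above chance at level
#' `alpha`.
#'
#' @param n_test_trials number of test trials.
#' @param alpha significance level in (0, 1).
#' @return The accuracy bound in percent.
#' @export
chance_threshold <- function(n_test_trials, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_test_trials < 1) stop("n_test_trials must be >= 1")
  k <- 0:n_test_trials
  tail <- stats::pbinom(k - 1, n_test_trials, 0.5, lower.tail = FALSE)
  100 * k[match(TRUE, tail < alpha)] / n_test_trials
}

#' Behavioral depth-judgement task score
#'
#' Each trial asks whether the object appeared in front of, as far as
#' ("flat"), or behind the screen: +1 for a correct answer, -1 for an
#' incorrect one, 0 for no answer. The normalized score divides by the
#' trial count, mapping the raw range `[-trials, +trials]` to `[-1, 1]`.
#'
#' @param log data.frame with columns `true` (one of `front`, `flat`,
#'   `behind`) and `response` (the same set plus `none`).
#' @return List with `raw` (integer) and `normalized`.
#' @export
task_score <- function(log) {
  log <- as.data.frame(log)
  if (!all(c("true", "response") %in% names(log)))
    stop("log must have columns 'true' and 'response'")
  ok_true <- c("front", "flat", "behind")
  bad <- setdiff(unique(c(log$true, log$response)), c(ok_true, "none"))
  if (length(bad))
    stop("unknown response symbol(s): ", paste(bad, collapse = ", "))
  if (any(!log$true %in% ok_true))
    stop("true positions must be one of front/flat/behind")
  pts <- ifelse(log$response == "none", 0L,
                ifelse(log$response == log$true, 1L, -1L))
  raw <- sum(pts)
  list(raw = raw,
       normalized = if (nrow(log) > 0) raw / nrow(log) else 0)
}
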