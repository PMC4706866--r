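#' Classification pipeline configuration
#'
#' Collects the tunable parameters of the per-subject pipeline. Defaults
#' mirror the reference analysis: 0.5-25 Hz band-pass, epochs -1..+2.5 s,
#' offline artifact rejection, chronological half-split, 5 REFSF virtual
#' channels, a 1 s ERP window starting 100 ms after the marker (the fixed
#' display latency) decimated by 16 (160 features), and - in `"ERP+CSSP"`
#' mode - 3 CSSP pairs per band over delta/theta/alpha/beta in a 1 s window
#' at 1100 ms (24 features), z-score fusion to 184 features and
#' median-ratio selection down to 50.
#'
#' @param mode `"offline"` (with artifact-epoch rejection) or `"online"`
#'   (rejection skipped, simulating a real-time pipeline).
#' @param feature_set `"ERP"` or `"ERP+CSSP"`.
#' @param ... overrides for any other field; see the source for the full
#'   list of fields and defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("offline", "online"),
                            feature_set = c("ERP", "ERP+CSSP"), ...) {
  cfg <- list(
    mode = match.arg(mode),
    feature_set = match.arg(feature_set),
    high_pass = 0.5, low_pass = 25, filter_order = 4,
    epoch_span = c(-1.0, 2.5),
    abs_threshold = 150, z_threshold = 5,
    erp_window_start = 0.100, erp_window_length = 1.0, decimation = 16,
    n_refsf_components = 5, refsf_shrink = "auto",
    cssp_window_start = 1.100, cssp_window_length = 1.0,
    cssp_bands = list(delta = c(1, 3), theta = c(4, 6),
                      alpha = c(7, 13), beta = c(14, 25)),
    cssp_pairs = 3, cssp_delay = 1, cssp_order = 3,
    select_k = 50,
    lda_shrinkage = "auto",
    split = "chronological_halves")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$erp_window_start + cfg$erp_window_length > cfg$epoch_span[2] ||
      cfg$erp_window_start < cfg$epoch_span[1])
    stop("ERP feature window does not fit within the epoch span")
  if (cfg$feature_set == "ERP+CSSP" &&
      (cfg$cssp_window_start + cfg$cssp_window_length > cfg$epoch_span[2]))
    stop("CSSP feature window does not fit within the epoch span")
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full per-subject pipeline
#'
#' Band-pass filter, epoch around C/NC markers, (offline mode only) reject
#' artifact epochs, split chronologically, fit REFSF on the training half,
#' extract decimated ERP features (plus CSSP log band-power features in
#' `"ERP+CSSP"` mode, fused by z-scoring and reduced by median-ratio
#' selection), train shrinkage LDA, and score the held-out second half.
#' Everything data-dependent (spatial filters, normalization, selection,
#' classifier) is fitted strictly on the training half.
#'
#' @param session a [raw_session()].
#' @param cfg a [pipeline_config()].
#' @return A `subject_result`: `subject_id`, single-trial `accuracy` (%),
#'   per-trial test `predictions`, `scores`, `correct` indicators and
#'   `test_labels`, the fitted REFSF `bank`, the `rejection` log (offline),
#'   trial counts and the configuration snapshot.
#' @export
run_subject <- function(session, cfg = pipeline_config()) {
  filt <- stage("bandpass_filter",
                bandpass_filter(session, cfg$high_pass, cfg$low_pass,
                                cfg$filter_order))
  epochs <- stage("extract_epochs", extract_epochs(filt, cfg$epoch_span))
  rejection <- NULL
  if (cfg$mode == "offline") {
    r <- stage("reject_artifact_epochs",
               reject_artifact_epochs(epochs, cfg$abs_threshold,
                                      cfg$z_threshold))
    epochs <- r$epochs
    rejection <- r$log
  }
  run_subject_epochs(epochs, cfg, rejection = rejection)
}

# Pipeline from already filtered (and, offline, cleaned) epochs; used by
# run_subject and by channel-reduction re-training.
run_subject_epochs <- function(epochs, cfg = pipeline_config(),
                               rejection = NULL) {
  halves <- stage("chronological_split", chronological_split(epochs))
  bank <- stage("fit_refsf", fit_refsf(
    crop_epochs(halves$train, cfg$erp_window_start, cfg$erp_window_length),
    n_components = cfg$n_refsf_components, shrink = cfg$refsf_shrink))
  feats <- stage("erp_features", lapply(halves, function(h)
    erp_features(apply_filters(h, bank), cfg$erp_window_start,
                 cfg$erp_window_length, cfg$decimation)))
  if (cfg$feature_set == "ERP+CSSP") {
    banks <- stage("fit_cssp", lapply(cfg$cssp_bands, function(b)
      fit_cssp(crop_epochs(butter_band(halves$train, b, cfg$cssp_order),
                           cfg$cssp_window_start, cfg$cssp_window_length),
               band = b, n_pairs = cfg$cssp_pairs, delay = cfg$cssp_delay)))
    cf <- stage("cssp_features", lapply(halves, function(h)
      cssp_features(h, banks, cfg$cssp_window_start,
                    cfg$cssp_window_length, cfg$cssp_order)))
    fused <- stage("fuse_and_normalize",
                   fuse_and_normalize(list(feats$train, cf$train),
                                      list(feats$test, cf$test)))
    mask <- stage("median_ratio_select",
                  median_ratio_select(fused$train, cfg$select_k))
    train_f <- apply_mask(fused$train, mask)
    test_f <- apply_mask(fused$test, mask)
  } else {
    train_f <- feats$train
    test_f <- feats$test
  }
  model <- stage("fit_slda", fit_slda(train_f, shrinkage = cfg$lda_shrinkage))
  pred <- stage("predict_slda", predict_slda(model, test_f))
  correct <- pred$labels == test_f$labels
  structure(
    list(subject_id = epochs$subject_id,
         accuracy = 100 * mean(correct),
         predictions = pred$labels,
         scores = pred$scores,
         correct = correct,
         test_labels = test_f$labels,
         bank = bank,
         model = model,
         rejection = rejection,
         n_train = n_trials(halves$train),
         n_test = n_trials(halves$test),
         config = cfg),
    class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: %.2f%% single-trial accuracy (%d train / %d test trials)\n",
              x$subject_id, x$accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' Generate and classify a whole synthetic cohort
#'
#' Runs [generate_session()] and [run_subject()] for every subject of a
#' cohort configuration, one at a time (sessions are discarded after use to
#' bound memory).
#'
#' @param config a `synth_config` (see [make_default_config()]).
#' @param cfg a [pipeline_config()].
#' @return List of `subject_result`s.
#' @export
run_cohort <- function(config, cfg = pipeline_config()) {
  lapply(cohort_configs(config), function(sc) {
    session <- generate_session(sc$config, sc$subject_id, sc$seed)
    on.exit(rm(session))
    run_subject(session, cfg)
  })
}
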