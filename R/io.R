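#' Write session events as a tab-separated table
#'
#' Columns: `onset_sample`, `onset_seconds`, `condition`.
#'
#' @param session a [raw_session()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(session, path) {
  ev <- session$events
  out <- data.frame(onset_sample = ev$onset_sample,
                    onset_seconds = (ev$onset_sample - 1) /
                      session$sampling_rate,
                    condition = ev$condition)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events_tsv()]
#'
#' @param path input file path.
#' @return data.frame with `onset_sample` and `condition`.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ev[, c("onset_sample", "condition")]
}

#' Serialize a spatial filter bank to JSON text
#'
#' @param bank a `spatial_filter_bank`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_filter_bank_json <- function(bank, path) {
  obj <- list(method = bank$method,
              channel_labels = bank$channel_labels,
              band = bank$band, delay = bank$delay,
              eigenvalues = bank$eigenvalues,
              shrinkage = bank$shrinkage,
              n_rows = nrow(bank$weights),
              n_components = ncol(bank$weights),
              weights_row_major = as.numeric(t(bank$weights)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spatial filter bank written by [write_filter_bank_json()]
#'
#' @param path input file path.
#' @return A `spatial_filter_bank`.
#' @export
read_filter_bank_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = matrix(obj$weights_row_major, nrow = obj$n_rows,
                          byrow = TRUE),
         eigenvalues = obj$eigenvalues,
         method = obj$method,
         band = obj$band,
         delay = obj$delay,
         channel_labels = obj$channel_labels,
         shrinkage = obj$shrinkage),
    class = "spatial_filter_bank")
}

#' Export a feature matrix as delimited text with a provenance header
#'
#' First row: provenance tags; first column: trial labels.
#'
#' @param feats a [feature_matrix()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_feature_matrix_tsv <- function(feats, path) {
  df <- data.frame(label = feats$labels, feats$values, check.names = FALSE)
  names(df) <- c("label", feats$provenance)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a subject result as JSON text
#'
#' @param result a `subject_result`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_subject_result_json <- function(result, path) {
  obj <- list(subject_id = result$subject_id,
              accuracy = result$accuracy,
              n_train = result$n_train, n_test = result$n_test,
              predictions = result$predictions,
              test_labels = result$test_labels,
              correct = result$correct,
              mode = result$config$mode,
              feature_set = result$config$feature_set)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
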