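#' Read a patient CSV
#'
#' Expects a header `id,x1,x2,x3,x4` (an optional `label` column is kept).
#' Non-numeric factor cells are reported with their row number.
#'
#' @param path CSV file path (decimal point, UTF-8).
#' @return data frame with columns `id`, `x1`..`x4` and optionally `label`.
#' @export
read_patients_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("id", "x1", "x2", "x3", "x4")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    fc_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "fuzzycad_validation_error")
  }
  if (nrow(df) == 0L) {
    fc_stop("no records", "fuzzycad_validation_error")
  }
  for (col in c("x1", "x2", "x3", "x4")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      fc_stop(sprintf("non-numeric value '%s' in column %s, row %d",
                      df[[col]][bad[1]], col, bad[1]),
              "fuzzycad_validation_error")
    }
    df[[col]] <- vals
  }
  keep <- intersect(c("id", "x1", "x2", "x3", "x4", "label"), names(df))
  df[, keep, drop = FALSE]
}

#' Classify a patient CSV file
#'
#' Reads patients from `input`, runs the decision algorithm on every row and
#' writes (or returns) the results: per-class memberships, decision, margin
#' and tie flag. Memberships are printed with six significant digits; the
#' decision is computed before any rounding. Out-of-domain values under the
#' default error policy abort with a message naming the factor and row.
#' Output contains no timestamps, so repeated runs on the same input are
#' byte-identical.
#'
#' @param input path of the input CSV (header `id,x1,x2,x3,x4`).
#' @param output optional path for the results CSV; `NULL` skips writing.
#' @param kb a [knowledge_base()].
#' @param config a [combiner_config()].
#' @return the results data frame, invisibly when `output` is given.
#' @export
classify_csv <- function(input, output = NULL,
                         kb = default_knowledge_base(),
                         config = combiner_config()) {
  patients <- read_patients_csv(input)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    tryCatch(
      infer_cohort(patients[i, , drop = FALSE], kb, config)$results,
      fuzzycad_domain_error = function(e) {
        fc_stop(sprintf("row %d: %s", i, conditionMessage(e)),
                "fuzzycad_domain_error")
      })
  })
  results <- do.call(rbind, rows)
  out <- results
  for (col in c("mu_I", "mu_II", "mu_III", "mu_IV", "margin")) {
    out[[col]] <- formatC(results[[col]], digits = 6, format = "g")
  }
  if (!is.null(output)) {
    write.csv(out, output, row.names = FALSE, quote = FALSE)
    return(invisible(results))
  }
  results
}
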