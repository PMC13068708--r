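TRIALS_SCHEMA_VERSION <- c(major = 1L, minor = 0L)

trials_required_cols <- c("observer_id", "experiment", "regime_standard_ms",
                          "block", "trial_in_block", "order", "comparison_ms",
                          "isi_ms", "stimulus_type", "response_c_longer")
trials_latent_cols <- c("latent_x1", "latent_x2", "latent_reference")

#' Write trial records as versioned CSV
#'
#' One row per trial, durations in milliseconds. The first line is a
#' version marker (`# typeb-trials v1.0`); readers reject files whose major
#' version they do not know. Latent columns are written only when present.
#'
#' @param records Data frame of response records (internal column names as
#'   produced by [run_constant_stimuli()]; `observer_id` and `experiment`
#'   default to 1 and `NA` if absent).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  out <- data.frame(
    observer_id = if ("observer_id" %in% names(records)) records$observer_id else 1L,
    experiment = if ("experiment" %in% names(records)) records$experiment else NA,
    regime_standard_ms = records$standard,
    block = records$block,
    trial_in_block = records$trial_in_block,
    order = records$order,
    comparison_ms = records$comparison,
    isi_ms = records$isi,
    stimulus_type = records$stimulus_type,
    response_c_longer = as.integer(records$response_c_longer))
  if ("x1" %in% names(records)) {
    out$latent_x1 <- records$x1
    out$latent_x2 <- records$x2
    out$latent_reference <- records$reference
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# typeb-trials v%d.%d", TRIALS_SCHEMA_VERSION["major"],
                     TRIALS_SCHEMA_VERSION["minor"]), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read trial records from versioned CSV
#'
#' Validates the version marker, the column schema, and the row contents
#' (order labels, binary responses); violations are rejected with the first
#' offending row number. Missing latent columns are fine.
#'
#' @param path CSV file written by [write_trials()] (or matching its schema;
#'   a missing version line is treated as v1).
#' @return Data frame in internal record format (`standard`, `comparison`,
#'   `first_duration`, `second_duration`, `order`, `isi`, `stimulus_type`,
#'   `response_c_longer`, plus ids and any latents).
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("v([0-9]+)\\.([0-9]+)", first))[[1]]
    if (length(m) == 3L) {
      major <- as.integer(m[2])
      if (major != TRIALS_SCHEMA_VERSION["major"]) {
        stop("read_trials: unknown schema major version ", major)
      }
    }
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(trials_required_cols, names(raw))
  if (length(missing) > 0) {
    stop("read_trials: missing columns: ", paste(missing, collapse = ", "))
  }
  bad_order <- which(!raw$order %in% c("sc", "cs"))
  if (length(bad_order) > 0) {
    stop("read_trials: invalid order value in row ", bad_order[1])
  }
  bad_resp <- which(!raw$response_c_longer %in% c(0L, 1L))
  if (length(bad_resp) > 0) {
    stop("read_trials: invalid response_c_longer in row ", bad_resp[1])
  }
  out <- data.frame(
    observer_id = raw$observer_id,
    experiment = raw$experiment,
    standard = raw$regime_standard_ms,
    block = raw$block,
    trial_in_block = raw$trial_in_block,
    order = raw$order,
    comparison = raw$comparison_ms,
    isi = raw$isi_ms,
    stimulus_type = raw$stimulus_type,
    response_c_longer = as.integer(raw$response_c_longer),
    stringsAsFactors = FALSE)
  out$first_duration <- ifelse(out$order == "sc", out$standard, out$comparison)
  out$second_duration <- ifelse(out$order == "sc", out$comparison, out$standard)
  if (all(trials_latent_cols %in% names(raw))) {
    out$x1 <- raw$latent_x1
    out$x2 <- raw$latent_x2
    out$reference <- raw$latent_reference
  }
  out
}
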