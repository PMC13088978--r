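# File formats: compound tables, delta-Tm tables, raw melt-curve tables
# (CSV, UTF-8, comma-separated, '.' decimal, empty cells for missing),
# JSON-lines screening traces, JSON reports, and the run manifest.

#' Read a compound table
#'
#' CSV with header and columns `compound_id` (required, unique), and/or
#' `smiles`, `library_tag`, `fingerprint` (a 0/1 bit-string, abstract mode).
#' Rows with unparseable SMILES (when SMILES is the only structure source)
#' are excluded and reported in the `"excluded"` attribute, mirroring
#' valid-data filtering; duplicate ids are an error.
#'
#' @param path CSV file path.
#' @param validate_smiles check SMILES parseability at read time (requires
#'   ChemmineOB; default `TRUE` when no fingerprint column is present).
#' @return a `data.frame` of compound records with attribute `"excluded"`
#'   (a character vector of dropped compound ids).
#' @export
read_compound_table <- function(path, validate_smiles = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  header <- tryCatch(names(utils::read.csv(path, nrows = 1)),
                     error = function(e) character(0))
  assert_that(length(header) > 0, "compound table is empty")
  # id, SMILES and fingerprint bit-string columns must never be read as
  # numbers (a 256-digit bit string parses as a float otherwise)
  classes <- c(compound_id = "character", smiles = "character",
               fingerprint = "character")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = classes[names(classes) %in% header])
  assert_that(nrow(df) > 0, "compound table is empty")
  assert_that("compound_id" %in% names(df),
              "compound table needs a compound_id column")
  assert_that("smiles" %in% names(df) || "fingerprint" %in% names(df),
              "compound table needs a smiles or fingerprint column")
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup)) {
    stop_iterscreen("iterscreen_duplicate_id",
                    sprintf("duplicate compound_id: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (is.null(validate_smiles)) {
    validate_smiles <- !("fingerprint" %in% names(df))
  }
  excluded <- character(0)
  if (validate_smiles && "smiles" %in% names(df)) {
    ok <- vapply(df$smiles, function(s) {
      if (is.na(s) || !nzchar(s)) return(FALSE)
      !inherits(tryCatch(ob_canonical_smiles(s), error = identity),
                "error")
    }, logical(1))
    excluded <- df$compound_id[!ok]
    if (length(excluded)) {
      message(sprintf("excluding %d compound(s) with unparseable SMILES: %s",
                      length(excluded), paste(excluded, collapse = ", ")))
      df <- df[ok, , drop = FALSE]
    }
  }
  attr(df, "excluded") <- excluded
  df
}

#' Read a delta-Tm table
#'
#' CSV with columns `compound_id`, `motif_id`, `delta_tm_C`, `valid`.
#'
#' @param path CSV file path.
#' @param threshold active-call cutoff (degrees C).
#' @return a [screen_table()].
#' @export
read_delta_tm_table <- function(path, threshold = 1) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("compound_id" %in% names(df)) df$compound_id <- as.character(df$compound_id)
  need <- c("compound_id", "motif_id", "delta_tm_C", "valid")
  assert_that(all(need %in% names(df)),
              paste("delta-Tm table needs columns:",
                    paste(need, collapse = ", ")))
  screen_table(df$compound_id, df$motif_id, df$delta_tm_C,
               valid = as.logical(df$valid), threshold = threshold)
}

#' Write a delta-Tm table
#'
#' @param table a [screen_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_delta_tm_table <- function(table, path) {
  out <- data.frame(compound_id = table$compound_id,
                    motif_id = table$motif_id,
                    delta_tm_C = table$delta_tm,
                    valid = table$valid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a raw melt-curve table
#'
#' Long-format CSV: `compound_id`, `motif_id`, `temperature_C`,
#' `fluorescence`, `is_reference`, optionally `plate`.
#'
#' @param path CSV file path.
#' @return a `data.frame` suitable for [analyze_melt_curves()].
#' @export
read_melt_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("compound_id" %in% names(df)) df$compound_id <- as.character(df$compound_id)
  need <- c("compound_id", "motif_id", "temperature_C", "fluorescence",
            "is_reference")
  assert_that(all(need %in% names(df)),
              paste("melt table needs columns:", paste(need, collapse = ", ")))
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' Serialize a screening trace to JSON lines
#'
#' The first line is a header (motif, selection mode, library sizes, config
#' snapshot); each following line is one iteration record. Scores are
#' written at full precision so a rerun is byte-identical; no timestamps are
#' embedded.
#'
#' @param trace a `screen_trace`.
#' @param path output path (conventionally `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "screen_trace"))
  header <- list(record = "header", motif = trace$motif,
                 selection = trace$selection, n_library = trace$n_library,
                 n_valid = trace$n_valid,
                 actives_total = trace$actives_total,
                 config = unclass(trace$config))
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"),
    vapply(trace$iterations, function(r) {
      r$record <- "iteration"
      r$scores <- if (is.null(r$scores)) NULL else as.list(r$scores)
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                    null = "null"))
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines screening trace
#'
#' Reconstructs a `screen_trace` (without the fitted forest, which is not
#' serialized) from a file written by [write_trace()].
#'
#' @param path trace file path.
#' @return a `screen_trace`.
#' @export
read_trace <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  assert_that(identical(header$record, "header"), "not a trace file")
  iters <- lapply(lines[-1], function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    r$record <- NULL
    if (!is.null(r$scores)) r$scores <- unlist(r$scores)
    r$iteration <- as.integer(r$iteration)
    r
  })
  tested <- unlist(lapply(iters, `[[`, "selected"))
  structure(
    list(motif = header$motif, selection = header$selection,
         config = do.call(screen_config, header$config[
           intersect(names(header$config), names(formals(screen_config)))]),
         n_library = header$n_library, n_valid = header$n_valid,
         actives_total = header$actives_total, iterations = iters,
         tested_ids = tested, final_model = NULL, library_ids = NULL),
    class = "screen_trace")
}

#' Write an evaluation report as JSON
#'
#' @param report a named list (as produced by [evaluate_screen()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Build a run manifest
#'
#' Reproducibility record for a pipeline run: configuration snapshot, seeds,
#' package version, and md5 digests of the input files. Every artifact a run
#' emits can be traced back to its manifest; all randomness in a run flows
#' from the manifest seeds.
#'
#' @param config the run configuration (list).
#' @param inputs named character vector of input file paths (possibly
#'   empty).
#' @param seed the master seed of the run.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0), seed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  structure(
    list(package = "iterscreen",
         version = as.character(utils::packageVersion("iterscreen")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = config, input_digests = digests),
    class = "run_manifest")
}
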