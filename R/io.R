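# Reading, validating and writing the plastid measurement table, plus JSON
# provenance sidecars for every file an analysis emits.
#
# Table schema (CSV or TSV, UTF-8, "." decimal separator), one row per
# plastid:
#   line, stoma_id, gc_id, plastid_id, length_um, chlorophyllous (0/1),
#   reticulate (0/1)

plastid_columns <- function() {
  c("line", "stoma_id", "gc_id", "plastid_id",
    "length_um", "chlorophyllous", "reticulate")
}

#' Validate a plastid measurement table
#'
#' Checks the schema, value domains and structural invariants of a tidy
#' plastid table: positive finite lengths, 0/1 or logical flags, no
#' reticulate chloroplasts (web-like structures are chlorophyll-less by
#' definition), unique plastid ids, and exactly two GCs per stoma. In
#' strict mode (the default — the taxonomy is closed, so deviations are
#' findings, not noise) any violation is an error naming the offending
#' rows; in permissive mode stomata without exactly two GCs are dropped
#' with a warning.
#'
#' @param x Data frame to validate.
#' @param permissive Drop incomplete stomata instead of erroring.
#' @return The validated tibble (possibly with rows dropped), with
#'   `chlorophyllous` and `reticulate` as logical columns.
#' @export
validate_plastid_table <- function(x, permissive = FALSE) {
  missing_cols <- setdiff(plastid_columns(), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("plastid table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[plastid_columns()]
  row_err <- function(what, rows) {
    abort(sprintf("%s at row(s): %s", what,
                  paste(head(rows, 10), collapse = ", ")))
  }

  if (!is.numeric(x$length_um)) {
    row_err("non-numeric length_um", which(is.na(suppressWarnings(as.numeric(x$length_um)))))
  }
  bad_len <- which(!is.finite(x$length_um) | x$length_um <= 0)
  if (length(bad_len) > 0) row_err("non-positive or non-finite length_um", bad_len)

  to_flag <- function(v, name) {
    if (is.logical(v)) return(v)
    if (is.numeric(v) && all(v %in% c(0, 1))) return(v == 1)
    row_err(paste0("column ", name, " must be logical or 0/1"),
            which(!(v %in% c(0, 1, TRUE, FALSE))))
  }
  x$chlorophyllous <- to_flag(x$chlorophyllous, "chlorophyllous")
  x$reticulate <- to_flag(x$reticulate, "reticulate")

  conflict <- which(x$reticulate & x$chlorophyllous)
  if (length(conflict) > 0) {
    row_err("reticulate plastids must be chlorophyll-less", conflict)
  }

  dup <- which(duplicated(x$plastid_id))
  if (length(dup) > 0) row_err("duplicate plastid_id", dup)

  gc_per_stoma <- x %>%
    distinct(.data$line, .data$stoma_id, .data$gc_id) %>%
    count(.data$line, .data$stoma_id, name = "n_gcs")
  bad <- gc_per_stoma %>% filter(.data$n_gcs != 2)
  if (nrow(bad) > 0) {
    msg <- sprintf("%d stoma(ta) without exactly 2 GCs: %s",
                   nrow(bad), paste(head(bad$stoma_id, 5), collapse = ", "))
    if (!permissive) abort(msg)
    warn(paste0("dropping ", msg))
    x <- x %>%
      filter(!(paste(.data$line, .data$stoma_id) %in%
                 paste(bad$line, bad$stoma_id)))
  }
  x
}

#' Read a plastid measurement table
#'
#' Reads the documented CSV/TSV schema (delimiter chosen from the file
#' extension: `.tsv`/`.tab`/`.txt` are tab-separated, anything else
#' comma-separated) and validates it with [validate_plastid_table()].
#' Identical content in either dialect yields an identical tibble.
#'
#' @param path Path to the file.
#' @param permissive Passed to [validate_plastid_table()].
#' @return Validated tibble, one row per plastid.
#' @export
read_plastid_table <- function(path, permissive = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  delim <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  x <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(
      line = readr::col_character(),
      stoma_id = readr::col_character(),
      gc_id = readr::col_character(),
      plastid_id = readr::col_character(),
      length_um = readr::col_double(),
      chlorophyllous = readr::col_double(),
      reticulate = readr::col_double()
    ),
    progress = FALSE
  )
  problems <- readr::problems(x)
  if (nrow(problems) > 0) {
    abort(sprintf("malformed input at line(s): %s",
                  paste(head(problems$row, 10), collapse = ", ")))
  }
  validate_plastid_table(x, permissive = permissive)
}

#' Write a plastid measurement table
#'
#' Writes the documented schema with `chlorophyllous`/`reticulate` encoded
#' as 0/1; the delimiter follows the file extension as in
#' [read_plastid_table()]. Writing then reading a table is lossless up to
#' float formatting.
#'
#' @param x Plastid tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plastid_table <- function(x, path) {
  x <- validate_plastid_table(x)
  out <- x %>%
    mutate(chlorophyllous = as.integer(.data$chlorophyllous),
           reticulate = as.integer(.data$reticulate))
  delim <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Write a JSON provenance sidecar for an output file
#'
#' Records, next to any emitted table, everything needed to regenerate it:
#' free-form parameters (seed, n_trials, type counts, ...) plus the package
#' version and a timestamp. The sidecar lands at `<path>.meta.json`.
#'
#' @param path Path of the data file the sidecar describes.
#' @param ... Named parameters to record.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar <- function(path, ...) {
  meta <- c(
    list(
      file = basename(path),
      package = "gcplastid",
      version = as.character(utils::packageVersion("gcplastid")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    list(...)
  )
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
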