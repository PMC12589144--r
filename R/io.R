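#' Read a patient cohort from a delimited text file
#'
#' Reads a CSV or TSV file with one header row and one row per patient.
#' Numeric cells may carry thousands separators (stripped on read); a
#' ferritin cell with a `">"` prefix, or equal to the configured assay
#' ceiling, is stored as a censored value at the ceiling. Empty cells become
#' missing fields. Logical cells accept TRUE/FALSE, T/F, yes/no and 1/0.
#'
#' @param path Path to the file. The delimiter is taken from `sep`, else
#'   from the extension (`.csv` comma, `.tsv`/`.txt` tab), else sniffed
#'   from the header line.
#' @param schema Column mapping from canonical field names (see
#'   [patient_record()]) to the file's column names: a named character
#'   vector (`c(ferritin_ugL = "peak_ferritin")`) or the path to a YAML
#'   file holding one. Unmapped canonical names are looked up verbatim.
#' @param sep Field delimiter, overriding autodetection.
#' @param ceiling Ferritin assay ceiling (ug/L).
#' @param provenance Free text recorded on the cohort; defaults to the path.
#' @return An [hlh_cohort()].
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL,
                        ceiling = FERRITIN_CEILING, provenance = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sep %||% .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = character(), fileEncoding = "UTF-8")
  schema <- .resolve_schema(schema)
  required <- c("patient_id", "ferritin_ugL")
  file_col <- function(canon) schema[[canon]] %||% canon
  missing_req <- required[!vapply(required, function(cn)
    file_col(cn) %in% names(raw), logical(1))]
  if (length(missing_req)) {
    stop("schema error: required column(s) not found in ", path, ": ",
         paste(vapply(missing_req, file_col, ""), collapse = ", "))
  }

  n <- nrow(raw)
  out <- data.frame(patient_id = trimws(raw[[file_col("patient_id")]]),
                    stringsAsFactors = FALSE)
  problems <- character()
  get_cells <- function(canon) {
    fc <- file_col(canon)
    if (fc %in% names(raw)) trimws(raw[[fc]]) else rep("", n)
  }
  parse_num <- function(canon) {
    cells <- gsub(",", "", get_cells(canon), fixed = TRUE)
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & cells != "" & is.na(vals))
    if (length(bad)) {
      problems <<- c(problems, sprintf("row %d, column '%s': '%s'",
                                       bad, file_col(canon),
                                       get_cells(canon)[bad]))
    }
    vals
  }
  parse_lgl <- function(canon) {
    cells <- tolower(get_cells(canon))
    vals <- rep(NA, n)
    vals[cells %in% c("true", "t", "yes", "y", "1")] <- TRUE
    vals[cells %in% c("false", "f", "no", "n", "0")] <- FALSE
    bad <- which(cells != "" & is.na(vals))
    if (length(bad)) {
      problems <<- c(problems, sprintf("row %d, column '%s': '%s'",
                                       bad, file_col(canon),
                                       get_cells(canon)[bad]))
    }
    vals
  }

  ferr_cells <- gsub(",", "", get_cells("ferritin_ugL"), fixed = TRUE)
  censored <- startsWith(ferr_cells, ">")
  ferr_num <- suppressWarnings(as.numeric(sub("^>", "", ferr_cells)))
  bad <- which(ferr_cells == "" | is.na(ferr_num))
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d, column '%s': '%s'",
                                    bad, file_col("ferritin_ugL"),
                                    get_cells("ferritin_ugL")[bad]))
  }
  censored <- censored | (!is.na(ferr_num) & ferr_num >= ceiling)
  ferr_num[censored] <- ceiling
  out$ferritin_ugL <- ferr_num
  out$ferritin_censored <- censored

  for (col in setdiff(.numeric_columns, "ferritin_ugL")) out[[col]] <- parse_num(col)
  for (col in setdiff(.logical_columns, "ferritin_censored")) out[[col]] <- parse_lgl(col)
  cond <- get_cells("conditions")
  out$conditions <- ifelse(cond == "", NA_character_, cond)

  if (length(problems)) {
    stop("malformed cell(s) in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  hlh_cohort(out, provenance = provenance %||% path, ceiling = ceiling)
}

#' Write a patient cohort to a delimited text file
#'
#' The inverse of [read_cohort()]: censored ferritin is written with a
#' `">"` prefix, missing fields as empty cells. A written cohort reads back
#' field-for-field identical.
#'
#' @param cohort An [hlh_cohort()].
#' @param path Output path; delimiter from `sep` or the extension.
#' @param sep Field delimiter, overriding autodetection.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  stopifnot(inherits(cohort, "hlh_cohort"))
  sep <- sep %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  out <- as.data.frame(cohort)[, .cohort_columns]
  out$ferritin_ugL <- ifelse(cohort$ferritin_censored,
                             paste0(">", .num2chr(cohort$ferritin_ugL)),
                             .num2chr(cohort$ferritin_ugL))
  for (col in setdiff(.numeric_columns, "ferritin_ugL")) {
    out[[col]] <- .num2chr(out[[col]])
  }
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- ""
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.num2chr <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, scientific = FALSE, digits = 15),
    character(1))
  out
}

.detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) return("\t")
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

.resolve_schema <- function(schema) {
  if (is.null(schema)) return(list())
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema)) &&
      file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    stop("schema must be a named mapping: canonical field -> file column")
  }
  unknown <- setdiff(names(schema), .cohort_columns)
  if (length(unknown)) {
    stop("schema maps unknown field(s): ", paste(unknown, collapse = ", "))
  }
  as.list(schema)
}
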