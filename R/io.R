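# canonical raw-record columns and which of them are mandatory numerics
.raw_columns <- c(
  "patient_id", "age", "primary_site", "laterality", "grade",
  "nodes_examined", "clinical_stage", "pathologic_stage",
  "clinical_tumor_size", "pathology_tumor_size", "treatment_sequence",
  "survival_months", "vital_status"
)
.mandatory_numeric <- c("age", "laterality", "grade", "clinical_stage",
  "pathologic_stage", "survival_months")
.optional_numeric <- c("nodes_examined", "clinical_tumor_size", "pathology_tumor_size")

.parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "NA"), NA, x)))

#' Read a patient-level cohort table
#'
#' Reads a delimited text file (comma by default, tab auto-detected from
#' the extension or via `sep`) with a header row, maps file columns to the
#' canonical record schema, and validates each row. Rows whose mandatory
#' fields fail to parse, whose codes fall outside their enumerated ranges,
#' or whose treatment sequence does not start with the operation token are
#' excluded; the exclusion count is reported.
#'
#' @param path path to the delimited file.
#' @param schema named character vector mapping canonical column names to
#'   file column names; `NULL` (default) assumes the file already uses
#'   canonical names. A plain `key = value` text file is also accepted via
#'   [read_schema()].
#' @param sep field separator; default `","`, or `"\t"` when the file
#'   extension is `.tsv`/`.txt`.
#' @return data frame of raw patient records (one per retained row) with
#'   attribute `n_excluded` giving the number of dropped rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(synthetic_config(n = 20), seed = 1), f)
#' nrow(read_cohort(f))
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  )
  if (is.null(schema)) {
    schema <- stats::setNames(.raw_columns, .raw_columns)
  }
  miss <- setdiff(.raw_columns, names(schema))
  if (length(miss) > 0) stop("schema lacks mappings for: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(schema[.raw_columns]), names(raw))
  if (length(absent) > 0) stop("input lacks column(s): ", paste(absent, collapse = ", "))

  rec <- data.frame(
    patient_id = raw[[schema[["patient_id"]]]],
    age = .parse_num(raw[[schema[["age"]]]]),
    primary_site = raw[[schema[["primary_site"]]]],
    laterality = .parse_num(raw[[schema[["laterality"]]]]),
    grade = .parse_num(raw[[schema[["grade"]]]]),
    nodes_examined = .parse_num(raw[[schema[["nodes_examined"]]]]),
    clinical_stage = .parse_num(raw[[schema[["clinical_stage"]]]]),
    pathologic_stage = .parse_num(raw[[schema[["pathologic_stage"]]]]),
    clinical_tumor_size = .parse_num(raw[[schema[["clinical_tumor_size"]]]]),
    pathology_tumor_size = .parse_num(raw[[schema[["pathology_tumor_size"]]]]),
    treatment_sequence = .normalize_treatment(raw[[schema[["treatment_sequence"]]]]),
    survival_months = .parse_num(raw[[schema[["survival_months"]]]]),
    vital_status = tolower(raw[[schema[["vital_status"]]]]),
    stringsAsFactors = FALSE
  )

  # mandatory fields must parse; empty-string mandatory raw cells count as malformed
  bad_parse <- Reduce(`|`, lapply(.mandatory_numeric, function(cl) {
    cell <- raw[[schema[[cl]]]]
    is.na(rec[[cl]]) & !(is.na(cell) | cell %in% c("", "NA"))
  }))
  bad_missing <- Reduce(`|`, lapply(
    c("age", "survival_months"),
    function(cl) is.na(rec[[cl]])
  ))
  in_range <- function(x, lo, hi, allowed = NULL) {
    if (!is.null(allowed)) is.na(x) | x %in% allowed else is.na(x) | (x >= lo & x <= hi)
  }
  bad_code <- !in_range(rec$laterality, 0, 4) |
    !in_range(rec$grade, NA, NA, allowed = c(1, 2, 3, 4, 9)) |
    !in_range(rec$clinical_stage, 0, 4) |
    !in_range(rec$pathologic_stage, 0, 4) |
    !(rec$vital_status %in% c("alive", "dead"))
  first_step <- vapply(.treatment_steps(rec$treatment_sequence),
    function(s) if (length(s) == 0 || is.na(s[1])) "" else s[1], character(1))
  bad_op <- first_step != "OP"
  neg <- (!is.na(rec$age) & rec$age < 0) |
    (!is.na(rec$survival_months) & rec$survival_months < 0) |
    (!is.na(rec$nodes_examined) & rec$nodes_examined < 0) |
    (!is.na(rec$clinical_tumor_size) & rec$clinical_tumor_size < 0) |
    (!is.na(rec$pathology_tumor_size) & rec$pathology_tumor_size < 0)

  drop <- bad_parse | bad_missing | bad_code | bad_op | neg
  n_excluded <- sum(drop)
  if (n_excluded > 0) {
    .msg(n_excluded, " of ", nrow(rec), " row(s) excluded ",
      "(unparseable, out-of-range, or non-operation-initial)")
  }
  out <- rec[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write raw patient records as delimited text
#'
#' Companion to [read_cohort()]; the written file round-trips.
#'
#' @param records raw patient-record data frame.
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records[, .raw_columns],
    file = path, sep = sep,
    row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a column-mapping schema from a key=value text file
#'
#' Each non-blank, non-`#` line has the form `canonical_name = file column`.
#'
#' @param path path to the mapping file.
#' @return named character vector suitable for [read_cohort()]'s `schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed schema line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(
    vapply(kv, function(m) trimws(m[3]), character(1)),
    vapply(kv, function(m) trimws(m[2]), character(1))
  )
}

#' Write a discretized cohort table as delimited text
#'
#' @param cohort a `cohort_table`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cohort),
    file = path, sep = sep,
    row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
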