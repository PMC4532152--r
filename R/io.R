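#' Validated delimited-table IO
#'
#' Every file the pipeline reads or writes is UTF-8 tab-separated text
#' with a mandatory header and "." as decimal separator.  Readers
#' validate each column against a schema and fail with the row number
#' and field name, never silently coercing.
#'
#' @name table_io
NULL

## a column spec; `allowed` restricts to a value set, `min` a lower bound
col_spec <- function(type = c("integer", "numeric", "character", "logical"),
                     min = NULL, allowed = NULL, na_ok = FALSE) {
  list(type = match.arg(type), min = min, allowed = allowed, na_ok = na_ok)
}

schema_register_events <- function() list(
  person_id = col_spec("character"),
  year = col_spec("integer"),
  category = col_spec("character", allowed = EVENT_CATEGORIES),
  primary_icd10 = col_spec("character"),
  quantity = col_spec("numeric", min = 0),
  reimbursement_entitled = col_spec("logical", na_ok = TRUE),
  uses_anticholinergic = col_spec("logical", na_ok = TRUE),
  age_group = col_spec("character"),
  sex = col_spec("character", allowed = c("female", "male"))
)

schema_smoking <- function() list(
  year = col_spec("integer"),
  age_group = col_spec("character"),
  sex = col_spec("character", allowed = c("female", "male")),
  category = col_spec("character", allowed = SMOKING_CATEGORIES),
  fraction = col_spec("numeric", min = 0)
)

schema_population <- function() list(
  year = col_spec("integer"),
  age_group = col_spec("character"),
  sex = col_spec("character", allowed = c("female", "male")),
  count = col_spec("numeric", min = 0)
)

schema_price_index <- function() list(
  year = col_spec("integer"),
  index = col_spec("numeric", min = 1e-12)
)

schema_utilisation_fixture <- function() list(
  year = col_spec("integer"),
  population = col_spec("numeric", min = 0),
  phc_hospital_days = col_spec("numeric", min = 0),
  shc_hospital_days = col_spec("numeric", min = 0),
  shc_outpatient_visits = col_spec("numeric", min = 0),
  sickness_allowance_days = col_spec("numeric", min = 0),
  disability_pension_subjects = col_spec("numeric", min = 0)
)

schema_cost_components <- function() list(
  year = col_spec("integer"),
  component = col_spec("character"),
  euros = col_spec("numeric", min = 0),
  euros_per_100k = col_spec("numeric", min = 0)
)

#' Read and validate a delimited table
#'
#' @param path tab-separated UTF-8 file with a header row.
#' @param schema named list of column specs (internal schemas cover the
#'   pipeline's file kinds).
#' @param sep field separator (default tab).
#' @return a validated `data.table`.
#' @export
read_table <- function(path, schema, sep = "\t") {
  if (!file.exists(path)) abort("file not found: %s", path)
  dt <- fread(path, sep = sep, header = TRUE, na.strings = "NA",
              colClasses = "character", encoding = "UTF-8")
  if (!setequal(names(dt), names(schema))) {
    abort("%s: wrong header; expected columns: %s", path,
          paste(names(schema), collapse = ", "))
  }
  setcolorder(dt, names(schema))
  for (col in names(schema)) {
    sp <- schema[[col]]
    raw <- dt[[col]]
    val <- switch(sp$type,
      integer = suppressWarnings(as.integer(raw)),
      numeric = suppressWarnings(as.numeric(raw)),
      logical = suppressWarnings(as.logical(raw)),
      character = raw
    )
    bad_na <- is.na(val) & !(is.na(raw) | raw == "NA")
    if (any(bad_na)) {
      abort("%s: row %d, field '%s': cannot parse value '%s'",
            path, which(bad_na)[1], col, raw[which(bad_na)[1]])
    }
    if (!sp$na_ok && anyNA(val)) {
      abort("%s: row %d, field '%s': missing value",
            path, which(is.na(val))[1], col)
    }
    if (!is.null(sp$min)) {
      bad <- !is.na(val) & val < sp$min
      if (any(bad)) {
        abort("%s: row %d, field '%s': value %s below minimum %s",
              path, which(bad)[1], col, val[which(bad)[1]], sp$min)
      }
    }
    if (!is.null(sp$allowed)) {
      bad <- !is.na(val) & !(val %in% sp$allowed)
      if (any(bad)) {
        abort("%s: row %d, field '%s': value '%s' not among: %s",
              path, which(bad)[1], col, val[which(bad)[1]],
              paste(sp$allowed, collapse = ", "))
      }
    }
    set(dt, j = col, value = val)
  }
  dt[]
}

#' Write a delimited table
#'
#' Tab-separated, UTF-8, "." decimal separator, header mandatory.
#'
#' @param x data.frame / data.table.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA",
         scipen = 50)
  invisible(path)
}

#' Write register events as one file per register
#'
#' @param events register-event table.
#' @param dir output directory (created if needed).
#' @return invisibly the written paths.
#' @export
write_registers <- function(events, dir) {
  events <- as.data.table(events)
  validate_register_events(events)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cat in EVENT_CATEGORIES) {
    sub <- events[category == cat]
    if (nrow(sub) == 0) next
    p <- file.path(dir, paste0(cat, ".tsv"))
    write_table(sub, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read register files from a directory
#'
#' Reads every `*.tsv` file in `dir` against the register-event schema
#' and validates the combined table.
#'
#' @param dir directory of register files.
#' @return a validated register-event `data.table`.
#' @export
read_registers <- function(dir) {
  if (!dir.exists(dir)) abort("register directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) return(empty_register_events())
  ev <- rbindlist(lapply(files, read_table, schema = schema_register_events()))
  validate_register_events(ev)
  ev
}
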