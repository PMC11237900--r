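## Long-format table model: every assay travels as a tidy table with declared
## key columns (jointly unique) and value columns with units. The canonical
## interchange format is CSV; XLSX is accepted on input only.

#' Declare an assay schema
#'
#' A schema names the key columns (whose combinations must be unique), the
#' value columns, and the measurement units attached to each value column.
#'
#' @param name schema name
#' @param keys character vector of key column names
#' @param values character vector of value column names
#' @param units named character vector, one entry per value column
#' @param optional character vector of optional annotation columns
#' @return an object of class `assay_schema`
#' @export
assay_schema <- function(name, keys, values, units = NULL, optional = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(keys), length(keys) >= 1L,
            is.character(values), length(values) >= 1L)
  if (!is.null(units) && !all(names(units) %in% values))
    stop_schema("units must be named by value columns")
  structure(list(name = name, keys = keys, values = values,
                 units = units, optional = optional),
            class = "assay_schema")
}

#' Built-in assay schemas
#'
#' Schemas for the three assays of the pipeline: replicate hindlimb posture
#' readings (mm), stretch force traces (grams vs mm), and per-side gene
#' expression (relative units or Cq).
#'
#' @param assay one of `"posture"`, `"force"`, `"expression"`, `"cq"`
#' @return an [assay_schema]
#' @export
builtin_schema <- function(assay = c("posture", "force", "expression", "cq")) {
  assay <- match.arg(assay)
  switch(assay,
    posture = assay_schema("posture",
      keys = c("rat_id", "timepoint", "replicate"),
      values = "reading_mm", units = c(reading_mm = "mm"),
      optional = c("treatment", "lesion_side", "antagonist")),
    force = assay_schema("force",
      keys = c("rat_id", "limb", "timepoint", "replicate", "sample"),
      values = c("distance_mm", "force_g"),
      units = c(distance_mm = "mm", force_g = "g"),
      optional = c("treatment", "lesion_side")),
    expression = assay_schema("expression",
      keys = c("rat_id", "region", "side", "gene"),
      values = "value", units = c(value = "relative"),
      optional = c("treatment", "lesion_side")),
    cq = assay_schema("cq",
      keys = c("rat_id", "region", "side", "gene"),
      values = "cq", units = c(cq = "Cq"),
      optional = c("treatment", "lesion_side")))
}

validate_long_table <- function(df, schema) {
  need <- c(schema$keys, schema$values)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_schema(sprintf("schema '%s': missing column(s): %s",
                        schema$name, paste(missing, collapse = ", ")))
  if (nrow(df)) {
    key <- do.call(paste, c(df[schema$keys], sep = "\r"))
    if (anyDuplicated(key))
      stop_integrity(sprintf("schema '%s': duplicate keys (first: %s)",
                             schema$name, key[which(duplicated(key))[1L]]))
  }
  keep <- intersect(c(schema$keys, schema$values, schema$optional), names(df))
  df <- df[keep]
  structure(df, schema = schema, class = c("long_table", "data.frame"))
}

#' Read a long-format assay table
#'
#' Reads a CSV or XLSX file and validates it against an assay schema:
#' required columns present, key combinations unique. Missing values are
#' kept as explicit `NA`, never dropped.
#'
#' @param path file path (`.csv` or `.xlsx`)
#' @param schema an [assay_schema]
#' @return a validated `long_table` (data.frame with the schema attached)
#' @export
read_long_table <- function(path, schema) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = as.data.frame(readxl::read_xlsx(path), stringsAsFactors = FALSE),
    stop_io(sprintf("unsupported format '.%s' (CSV or XLSX)", ext)))
  validate_long_table(df, schema)
}

#' Construct a long table from a data.frame
#'
#' @param df data.frame holding key and value columns
#' @param schema an [assay_schema]
#' @return a validated `long_table`
#' @export
as_long_table <- function(df, schema) validate_long_table(as.data.frame(df), schema)

#' Write a results table with run metadata
#'
#' Writes a deterministic CSV (rows sorted by key columns) and a JSON
#' sidecar `<path>.meta.json` recording the seed, configuration hash and
#' package version so every output is traceable to its run.
#'
#' @param table a `long_table` or plain data.frame
#' @param path output CSV path (parent directory must exist)
#' @param seed integer seed used for the producing run (recorded, not used)
#' @param config configuration object hashed into the sidecar
#' @return `path`, invisibly
#' @export
write_results <- function(table, path, seed = NA_integer_, config = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory does not exist: %s", dir))
  df <- as.data.frame(table)
  schema <- attr(table, "schema")
  sort_cols <- if (!is.null(schema)) intersect(schema$keys, names(df)) else names(df)
  if (nrow(df) && length(sort_cols))
    df <- df[do.call(order, df[sort_cols]), , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write: %s", path))
  meta <- list(seed = seed, config_hash = config_hash(config),
               schema = if (!is.null(schema)) schema$name else NA,
               n_rows = nrow(df),
               package = "lrasym",
               version = as.character(utils::packageVersion("lrasym")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
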