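#' Entity-by-condition abundance table
#'
#' The common container for all omics layers: a numeric matrix with entities
#' (genes, proteins, peptides or metabolites) in rows and steady-state
#' conditions in columns, tagged with the unit of the values. Tables in
#' `"relative_to_reference"` units must name a reference condition and carry
#' value 1 in the reference column for every entity measured there.
#'
#' @param values numeric matrix with rownames (entity ids) and colnames
#'   (condition ids). No negative values are allowed.
#' @param unit one of `"copies_per_cell"`, `"intensity"`,
#'   `"relative_to_reference"`, `"mmol_per_gDW"`.
#' @param reference_condition condition id, required when
#'   `unit = "relative_to_reference"`.
#' @return an `omics_table` object.
#' @export
omics_table <- function(values, unit, reference_condition = NULL) {
  unit <- match.arg(unit, c(
    "copies_per_cell", "intensity",
    "relative_to_reference", "mmol_per_gDW"
  ))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics_table values need entity rownames and condition colnames")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("omics_table values must be non-negative")
  }
  if (unit == "relative_to_reference") {
    if (is.null(reference_condition) ||
      !reference_condition %in% colnames(values)) {
      stop("relative_to_reference tables need a reference_condition column")
    }
    ref <- values[, reference_condition]
    bad <- which(!is.na(ref) & abs(ref - 1) > 1e-9)
    if (length(bad)) {
      stop(
        "reference column must be 1 for every entity present; offending: ",
        paste(utils::head(rownames(values)[bad], 3), collapse = ", ")
      )
    }
  }
  structure(
    list(
      values = values,
      unit = unit,
      reference_condition = reference_condition
    ),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(
    "omics_table:", nrow(x$values), "entities x", ncol(x$values),
    "conditions [", x$unit, "]\n"
  )
  if (!is.null(x$reference_condition)) {
    cat("reference condition:", x$reference_condition, "\n")
  }
  print(utils::head(x$values, 4))
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

entities <- function(x) rownames(x$values)
conditions <- function(x) colnames(x$values)

#' Write / read an omics table as TSV
#'
#' Tables are stored with an `entity_id` column followed by one numeric column
#' per condition; the unit (and reference condition, if any) are recorded in
#' `# key: value` header comments so a round trip preserves the object.
#'
#' @param x an [omics_table()].
#' @param path file path.
#' @return `write_omics_table` returns `path` invisibly; `read_omics_table`
#'   returns an [omics_table()].
#' @export
write_omics_table <- function(x, path) {
  stopifnot(inherits(x, "omics_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", x$unit), con)
  if (!is.null(x$reference_condition)) {
    writeLines(paste0("# reference_condition: ", x$reference_condition), con)
  }
  chr <- matrix(format_full(x$values),
    nrow = nrow(x$values),
    dimnames = dimnames(x$values)
  )
  df <- data.frame(
    entity_id = rownames(x$values), chr,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_omics_table
#' @export
read_omics_table <- function(path) {
  header <- readLines(path, n = 10)
  meta <- grep("^# ", header, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(hit)) {
      return(NULL)
    }
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (names(df)[1] != "entity_id") {
    stop("malformed omics table header: first column must be entity_id")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance cells in ", path)
  rownames(vals) <- df$entity_id
  omics_table(vals,
    unit = get_meta("unit") %||% "intensity",
    reference_condition = get_meta("reference_condition")
  )
}
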