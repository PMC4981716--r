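# Tabular I/O. Canonical dialect: TSV with an optional leading
# "#units:" comment line tagging each column's unit.

#' Write a table as TSV with a units header
#'
#' @param df data frame.
#' @param path output path.
#' @param units optional named character vector (column -> unit tag)
#'   written as a leading \code{#units:} comment line.
#' @export
write_units_tsv <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) {
    miss <- setdiff(names(df), names(units))
    if (length(miss)) units[miss] <- "-"
    writeLines(paste0("#units: ",
                      paste(names(df), unname(units[names(df)]),
                            sep = "=", collapse = "\t")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a unit-tagged TSV
#'
#' Reads a TSV written by [write_units_tsv()] (or any plain TSV/CSV; the
#' delimiter is inferred from the extension). A leading \code{#units:}
#' line is parsed into the \code{"units"} attribute.
#'
#' @param path input path.
#' @param required_columns optional character vector; a structured error
#'   names any that are missing.
#' @param numeric_columns optional character vector validated as fully
#'   numeric; offending rows are reported by line.
#' @return data frame with attribute \code{units} (may be NULL).
#' @export
read_units_tsv <- function(path, required_columns = NULL,
                           numeric_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1)
  units <- NULL
  if (startsWith(first, "#units:")) {
    kv <- strsplit(trimws(sub("^#units:", "", first)), "\t")[[1]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    units <- stats::setNames(vapply(parts, `[`, "", 2),
                             vapply(parts, `[`, "", 1))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(required_columns)) {
    miss <- setdiff(required_columns, names(df))
    if (length(miss))
      stop("missing required column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_columns, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric values in column '", col, "' of ",
           basename(path), " at data row(s): ",
           paste(bad, collapse = ", "))
    df[[col]] <- v
  }
  attr(df, "units") <- units
  df
}

#' Read a steady-state bioreactor table
#'
#' Validates the canonical steady-state schema (\code{organism},
#' \code{Ii}, \code{D}, \code{OD730}, \code{x}, \code{O2_uM},
#' \code{pH}); a \code{mu} column is accepted in place of, or alongside,
#' \code{D} (either may serve as the specific growth rate under
#' turbidostat operation).
#'
#' @param path TSV/CSV path.
#' @return validated data frame; if \code{mu} is absent it is copied
#'   from \code{D}.
#' @export
read_steady_state_table <- function(path) {
  df <- read_units_tsv(path,
                       required_columns = c("Ii", "OD730", "x", "O2_uM"),
                       numeric_columns = c("Ii", "D", "mu", "OD730", "x",
                                           "O2_uM", "pH"))
  if (!"mu" %in% names(df) && !"D" %in% names(df))
    stop("steady-state table needs a 'mu' or 'D' column")
  if (!"mu" %in% names(df)) df$mu <- df$D
  if (!"D" %in% names(df)) df$D <- df$mu
  if (any(df$x <= 0)) stop("biomass column x must be positive")
  df
}

#' Read an expression matrix TSV
#'
#' First column = gene identifier, remaining columns = condition labels.
#' Duplicate gene ids are a structured error naming the offenders.
#'
#' @param path TSV path.
#' @return numeric matrix, genes x conditions.
#' @export
read_expression_matrix <- function(path) {
  df <- read_units_tsv(path)
  if (ncol(df) < 2) stop("expression table needs gene + condition columns")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("RPKM values must be non-negative")
  rownames(m) <- ids
  m
}

#' Read gas-liquid parameters from a JSON block
#'
#' Expects fields \code{kla}, optionally \code{kla_units}
#' (\code{"per_h"}/\code{"per_min"}), \code{kH}, \code{pO2_in},
#' \code{O2_in}; missing optional fields take the [gas_params()]
#' defaults.
#'
#' @param path JSON file.
#' @return a [gas_params()] object.
#' @export
read_gas_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$kla)) stop("gas parameter block must define kla")
  gas_params(kla = x$kla,
             kH = x$kH %||% 1.08,
             pO2_in = x$pO2_in %||% 0,
             O2_in = x$O2_in %||% 0,
             kla_units = x$kla_units %||% "per_h")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip hidden ground-truth columns before any estimator sees a table
drop_truth_columns <- function(df) {
  df[, !startsWith(names(df), "truth_"), drop = FALSE]
}
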