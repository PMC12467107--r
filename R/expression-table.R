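#' Construct an expression table
#'
#' An `expression_table` holds one species' gene-by-stage abundance matrix
#' together with its unit tag. Values must be non-negative and finite;
#' missing measurements are `NA` (never silently zero, because "not
#' detected in the transcriptome" and "measured as low" are distinct
#' states downstream).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   stages in columns (colnames = native stage labels).
#' @param species Species identifier string.
#' @param unit One of [EXPRESSION_UNITS].
#' @return An object of class `expression_table`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("GAPDH", "ODC"), c("Egg", "7 hpf")))
#' expression_table(m, species = "demo", unit = "RPM")
#' @export
expression_table <- function(values, species, unit = "UNKNOWN") {
  unit <- match.arg(toupper(unit), EXPRESSION_UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and stage colnames", call. = FALSE)
  x <- structure(
    list(values = values, species = as.character(species), unit = unit),
    class = "expression_table"
  )
  validate_expression_table(x)
  x
}

#' Validate an expression table
#'
#' Checks the structural invariants: non-negative finite values (NA
#' allowed), unique gene symbols, unique stage labels. Errors name the
#' offending gene/stage so malformed input files are locatable.
#'
#' @param x An `expression_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_expression_table <- function(x) {
  v <- x$values
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(v)))
    stop("duplicate stage label(s): ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(v) & (v < 0 | !is.finite(v)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(v)[bad[1, 1]]; s <- colnames(v)[bad[1, 2]]
    stop(sprintf("negative or non-finite value at gene '%s', stage '%s': %g",
                 g, s, v[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %s: %d genes x %d stages [%s]\n",
              x$species, nrow(x$values), ncol(x$values), x$unit))
  cat("stages:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression table from TSV/CSV
#'
#' Expected layout: first column gene symbols, header row = native stage
#' labels, numeric body, decimal point ".". Blank cells become `NA`
#' (missing), never 0. The file extension selects the separator
#' (`.csv` = comma, otherwise tab).
#'
#' @param path Path to the file.
#' @param species Species identifier to attach.
#' @param unit Abundance unit of the file (one of [EXPRESSION_UNITS]).
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path, species, unit = "UNKNOWN") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("need a gene column plus >= 1 stage column", call. = FALSE)
  genes <- trimws(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  body[trimws(body) == ""] <- NA_character_
  num <- suppressWarnings(apply(body, 2, as.numeric))
  num <- matrix(num, nrow = nrow(body), dimnames = NULL)
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at gene '%s', stage '%s': '%s'",
                 genes[bad[1, 1]], colnames(df)[-1][bad[1, 2]],
                 body[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(df)[-1])
  expression_table(num, species = species, unit = unit)
}

#' Write an expression table to TSV/CSV
#'
#' Inverse of [read_expression_table()]: values are written with full
#' precision (`format(..., digits = 17)`) so a write-then-read round trip
#' reproduces the matrix bit-for-bit. `NA` cells are written empty.
#'
#' @param x An `expression_table`.
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- x$values
  chr <- matrix(vapply(v, function(z) {
    if (is.na(z)) "" else format(z, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1)), nrow = nrow(v))
  df <- data.frame(gene = rownames(v), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(v))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
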