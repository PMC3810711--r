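#' Protein-by-sample intensity matrix with provenance
#'
#' A light container for the assembled expression surface: a numeric matrix
#' with proteins as rows and samples as columns, plus an ordered record of
#' the transforms that produced it (e.g. `"collapse"`, `"log2"`,
#' `"quantile"`).
#'
#' @param values numeric matrix, proteins x samples, with dimnames.
#' @param provenance character vector of transform names already applied.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_fmt("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("`values` must have protein row names and sample column names")
  if (anyNA(values))
    stop_fmt("intensity matrix contains missing values")
  structure(list(values = values, provenance = as.character(provenance)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("provenance:", if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
      else "(raw)", "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

append_provenance <- function(m, step) {
  m$provenance <- c(m$provenance, step)
  m
}

#' Write / read an intensity matrix as TSV
#'
#' TSV with proteins as rows, first column `protein_id`; provenance is kept
#' in `#`-prefixed header comments so pipeline stages remain inspectable.
#'
#' @param m an `intensity_matrix`.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in m$provenance) writeLines(sprintf("# provenance: %s", p), con)
  df <- data.frame(protein_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  prov_lines <- grep("^# provenance: ", lines, value = TRUE)
  provenance <- sub("^# provenance: ", "", prov_lines)
  df <- utils::read.delim(text = lines, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$protein_id
  intensity_matrix(vals, provenance)
}
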