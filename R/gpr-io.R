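GPR_COLUMNS <- c("Block", "Column", "Row", "Name", "ID",
                 "F635 Median", "B635 Median", "Flags")

#' Read a GenePix results (gpr) file
#'
#' Parses a single-channel (635 nm) gpr file in the ATF 1.0 dialect: an
#' `ATF` magic line, a counts line, optional quoted `"key=value"` header
#' records, a quoted column-name line, and tab-separated data lines. Only
#' the eight columns `Block`, `Column`, `Row`, `Name`, `ID`,
#' `F635 Median`, `B635 Median` and `Flags` are required; any extra
#' columns are tolerated and ignored.
#'
#' @param path path to a gpr file.
#' @param sample_id sample identifier; defaults to the file basename
#'   without the `.gpr` extension.
#' @return An object of class `array_scan`: a list with `sample_id`,
#'   `spots` (a data frame with columns `block`, `row`, `column`, `name`,
#'   `id`, `f_median`, `b_median`, `flags`) and `meta` (named character
#'   vector of header records).
#' @export
read_gpr <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_fmt("gpr file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L || !grepl("^ATF", lines[[1L]]))
    stop_fmt("%s: not an ATF file (missing 'ATF' magic line)", path)
  counts <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop_fmt("%s: malformed ATF counts line (line 2)", path)
  n_header <- counts[[1L]]
  unquote <- function(x) gsub('^"|"$', "", x)

  meta <- character()
  if (n_header > 0L) {
    hdr <- unquote(lines[2L + seq_len(n_header)])
    kv <- regmatches(hdr, regexpr("=", hdr), invert = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", "")
    meta <- stats::setNames(vals, keys)
  }

  col_line <- 3L + n_header
  col_names <- unquote(strsplit(lines[[col_line]], "\t")[[1L]])
  missing_cols <- setdiff(GPR_COLUMNS, col_names)
  if (length(missing_cols))
    stop_fmt("%s: missing required gpr column(s): %s", path,
             paste(missing_cols, collapse = ", "))

  data_lines <- lines[seq.int(col_line + 1L, length(lines))]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) stop_fmt("%s: no data lines", path)
  cells <- strsplit(data_lines, "\t")
  idx <- match(GPR_COLUMNS, col_names)
  grab <- function(j) unquote(vapply(cells, function(r) {
    if (length(r) < j) "" else r[[j]]
  }, ""))
  num <- function(col_name) {
    raw <- grab(idx[[match(col_name, GPR_COLUMNS)]])
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out))
    if (length(bad))
      stop_fmt("%s: malformed numeric value '%s' in column '%s' at line %d",
               path, raw[bad[[1L]]], col_name, col_line + bad[[1L]])
    out
  }
  spots <- data.frame(
    block    = as.integer(num("Block")),
    row      = as.integer(num("Row")),
    column   = as.integer(num("Column")),
    name     = grab(idx[[4L]]),
    id       = grab(idx[[5L]]),
    f_median = num("F635 Median"),
    b_median = num("B635 Median"),
    flags    = as.integer(num("Flags")),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(spots[c("block", "row", "column")]))
    stop_fmt("%s: duplicated (block,row,column) spot coordinates", path)
  if (any(spots$f_median < 0) || any(spots$b_median < 0))
    stop_fmt("%s: negative intensity values", path)
  meta["original_filename"] <- basename(path)
  array_scan(sample_id %||% sub("\\.gpr$", "", basename(path), ignore.case = TRUE),
             spots, meta)
}

#' Construct an array scan
#'
#' @param sample_id non-empty sample identifier.
#' @param spots data frame of spot records (see [read_gpr()]).
#' @param meta named character vector of metadata (lot, scan date, ...).
#' @return An `array_scan` object.
#' @export
array_scan <- function(sample_id, spots, meta = character()) {
  if (!nzchar(sample_id)) stop_fmt("sample_id must be non-empty")
  if (!nrow(spots)) stop_fmt("array scan must contain at least one spot")
  structure(list(sample_id = sample_id, spots = spots,
                 meta = if (length(meta)) meta else stats::setNames(character(), character())),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s': %d spots, %d flagged bad\n",
              x$sample_id, nrow(x$spots), sum(x$spots$flags < 0)))
  invisible(x)
}

#' Write an array scan as a gpr file
#'
#' Emits an ATF 1.0 file re-readable by [read_gpr()] with identical spot
#' records.
#'
#' @param scan an `array_scan`.
#' @param path output path.
#' @export
write_gpr <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  meta <- scan$meta[setdiff(names(scan$meta), "original_filename")]
  hdr <- if (length(meta)) sprintf('"%s=%s"', names(meta), unname(meta)) else character()
  fmt_num <- function(x) {
    out <- ifelse(x == floor(x) & abs(x) < 1e15,
                  sprintf("%.0f", x), sprintf("%.17g", x))
    out
  }
  sp <- scan$spots
  lines <- c(
    "ATF\t1.0",
    sprintf("%d\t%d", length(hdr), length(GPR_COLUMNS)),
    hdr,
    paste(sprintf('"%s"', GPR_COLUMNS), collapse = "\t"),
    paste(sp$block, sp$column, sp$row,
          sprintf('"%s"', sp$name), sprintf('"%s"', sp$id),
          fmt_num(sp$f_median), fmt_num(sp$b_median), sp$flags,
          sep = "\t")
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop_fmt("cannot write gpr file %s: %s",
                                              path, conditionMessage(e)))
  invisible(path)
}

#' Read a study design table
#'
#' Tab- or comma-separated table with header columns `sample_id`, `group`,
#' `lot` and optionally `day` and `filename` (defaulting to
#' `<sample_id>.gpr`).
#'
#' @param path path to the design table.
#' @return A `study_design` data frame.
#' @export
read_design <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  study_design(df)
}

#' @rdname read_design
#' @param df data frame with at least `sample_id`, `group`, `lot`.
#' @export
study_design <- function(df) {
  need <- c("sample_id", "group", "lot")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_fmt("study design lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_fmt("study design has duplicated sample_ids")
  if (any(!nzchar(df$group)) || any(!nzchar(df$lot)))
    stop_fmt("study design has empty group or lot labels")
  if (is.null(df$filename)) df$filename <- paste0(df$sample_id, ".gpr")
  class(df) <- c("study_design", "data.frame")
  df
}

#' Write a study design table as TSV
#' @param design a `study_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a study: one gpr file per design row
#'
#' Batch-reads every array of a study, matching design rows to files via
#' the design's `filename` column. Files present in the directory but
#' absent from the design are skipped with a warning; design rows without
#' a file are an error listing the affected sample ids.
#'
#' @param design a `study_design` (or path to one).
#' @param gpr_dir directory containing the gpr files.
#' @return A list with `scans` (named list of `array_scan`, in design
#'   order) and `design`.
#' @export
load_study <- function(design, gpr_dir) {
  if (is.character(design)) design <- read_design(design)
  design <- study_design(as.data.frame(design))
  paths <- file.path(gpr_dir, design$filename)
  missing <- !file.exists(paths)
  if (any(missing))
    stop_fmt("missing gpr file(s) for sample_id(s): %s",
             paste(design$sample_id[missing], collapse = ", "))
  extra <- setdiff(list.files(gpr_dir, pattern = "\\.gpr$", ignore.case = TRUE),
                   design$filename)
  if (length(extra))
    warning(sprintf("%d gpr file(s) without a design row skipped: %s",
                    length(extra), paste(extra, collapse = ", ")), call. = FALSE)
  scans <- Map(function(p, sid, lot) {
    s <- read_gpr(p, sample_id = sid)
    s$meta["lot"] <- lot
    s
  }, paths, design$sample_id, design$lot)
  names(scans) <- design$sample_id
  list(scans = scans, design = design)
}

#' Collapse spot-level scans to a protein-level intensity matrix
#'
#' Aggregates duplicate spots per protein on each array after optional
#' local-background subtraction (`signal = max(f_median - b_median, 1)`,
#' keeping the subsequent log2 defined), excluding flagged-bad spots
#' (`flags < 0`) and control features. Control features (spot names
#' matching any of `control_patterns`, case-insensitive substring match)
#' are excluded from the matrix but returned in a side table.
#'
#' If every replicate of a protein is flagged on some array, the array's
#' minimum observed protein value is imputed and a warning is emitted, so
#' downstream scoring always sees complete columns.
#'
#' @param scans list of `array_scan` sharing one layout.
#' @param control_patterns character vector of control-name substrings.
#' @param background `"subtract"` (default) or `"none"`.
#' @param aggregate `"mean"` (default) or `"median"` over unflagged
#'   duplicate spots.
#' @return An `intensity_matrix`; attribute `"controls"` holds the
#'   aggregated control-feature matrix.
#' @export
collapse_features <- function(scans,
                              control_patterns = c("control", "buffer", "empty"),
                              background = c("subtract", "none"),
                              aggregate = c("mean", "median")) {
  background <- match.arg(background)
  aggregate <- match.arg(aggregate)
  if (!length(scans)) stop_fmt("no scans supplied")
  layout <- scans[[1L]]$spots[c("block", "row", "column", "name", "id")]
  for (s in scans[-1L]) {
    l2 <- s$spots[c("block", "row", "column", "name", "id")]
    if (!identical(dim(l2), dim(layout)) || !isTRUE(all.equal(layout, l2, check.attributes = FALSE)))
      stop_fmt("array layouts differ between '%s' and '%s'",
               scans[[1L]]$sample_id, s$sample_id)
  }
  lname <- tolower(layout$name)
  is_control <- Reduce(`|`, lapply(tolower(control_patterns),
                                   function(p) grepl(p, lname, fixed = TRUE)),
                       accumulate = FALSE) %||% rep(FALSE, nrow(layout))

  agg_fun <- if (aggregate == "mean") mean else stats::median
  one_array <- function(s, keep) {
    sp <- s$spots[keep, ]
    sig <- if (background == "subtract") pmax(sp$f_median - sp$b_median, 1) else sp$f_median
    ok <- sp$flags >= 0
    vals <- tapply(sig[ok], factor(sp$id[ok], levels = unique(sp$id)), agg_fun)
    as.numeric(vals)[match(unique(sp$id), names(vals))]
  }

  protein_ids <- unique(layout$id[!is_control])
  vals <- vapply(scans, one_array, numeric(length(protein_ids)), keep = !is_control)
  vals <- matrix(vals, nrow = length(protein_ids),
                 dimnames = list(protein_ids,
                                 vapply(scans, `[[`, "", "sample_id")))
  na_cells <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(na_cells)) {
    warning(sprintf("%d protein/array cell(s) had all spots flagged; imputed array minimum",
                    nrow(na_cells)), call. = FALSE)
    for (j in unique(na_cells[, 2L])) {
      col <- vals[, j]
      vals[is.na(col), j] <- min(col, na.rm = TRUE)
    }
  }
  out <- intensity_matrix(vals, provenance = sprintf(
    "collapse(background=%s, aggregate=%s)", background, aggregate))
  if (any(is_control)) {
    ctrl_ids <- unique(layout$id[is_control])
    cv <- vapply(scans, one_array, numeric(length(ctrl_ids)), keep = is_control)
    cv <- matrix(cv, nrow = length(ctrl_ids),
                 dimnames = list(ctrl_ids, colnames(vals)))
    attr(out, "controls") <- cv
  }
  out
}
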