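#' Segmentation run metadata
#'
#' Records the tool version and the segmentation settings that produced a
#' mask or measurement table, so that a past run can be reproduced and so the
#' explorer stage can verify that pooled data came from one tool version.
#'
#' @param tool_version non-empty version string.
#' @param settings named list of segmentation/quantification settings
#'   (scalars; serialized as `key\tvalue` lines).
#' @param number_format decimal dialect; only `"US"` (`.` decimal separator)
#'   is supported.
#' @return an object of class `run_metadata`.
#' @export
run_metadata <- function(tool_version, settings = list(),
                         number_format = "US") {
  if (!is.character(tool_version) || length(tool_version) != 1L ||
      !nzchar(tool_version))
    stop("tool_version must be a non-empty string")
  number_format <- match.arg(number_format, "US")
  structure(list(tool_version = tool_version, settings = settings,
                 number_format = number_format),
            class = "run_metadata")
}

#' @export
print.run_metadata <- function(x, ...) {
  cat("<run_metadata> version", x$tool_version, "|",
      length(x$settings), "settings\n")
  invisible(x)
}

meta_to_lines <- function(meta) {
  c(paste0("# tool_version\t", meta$tool_version),
    paste0("# number_format\t", meta$number_format),
    vapply(names(meta$settings), function(k) {
      paste0("# ", k, "\t", format(meta$settings[[k]], scientific = FALSE))
    }, ""))
}

lines_to_meta <- function(lines) {
  kv <- strsplit(sub("^# ", "", lines), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[[2]] else "", "")
  tool_version <- if ("tool_version" %in% keys) vals[keys == "tool_version"][1]
                  else NA_character_
  settings <- as.list(vals[!keys %in% c("tool_version", "number_format")])
  names(settings) <- keys[!keys %in% c("tool_version", "number_format")]
  num <- suppressWarnings(lapply(settings, function(v) {
    nv <- as.numeric(v)
    if (!is.na(nv)) nv else v
  }))
  list(tool_version = tool_version, settings = num)
}

#' Per-cilium measurement table
#'
#' One row per detected cilium; the unit record of all downstream analysis.
#' Carries the run metadata of the segmentation/quantification run that
#' produced it plus, once pooled, group and replicate identity.
#'
#' @param records data.frame with one row per cilium; must contain a unique
#'   `id` column.
#' @param metadata a [run_metadata()] or `NULL` (version unknown).
#' @param source_image name of the source stack.
#' @param group_label,replicate_id identity labels (may be `NA` before
#'   pooling).
#' @return an object of class `cilia_table`.
#' @export
cilia_table <- function(records, metadata = NULL, source_image = NA_character_,
                        group_label = NA_character_,
                        replicate_id = NA_character_) {
  stopifnot(is.data.frame(records))
  if (!"id" %in% names(records)) stop("records must have an 'id' column")
  if (anyDuplicated(records$id)) stop("record ids must be unique in a table")
  structure(list(records = records, metadata = metadata,
                 source_image = source_image, group_label = group_label,
                 replicate_id = replicate_id),
            class = "cilia_table")
}

#' @export
print.cilia_table <- function(x, ...) {
  cat(sprintf("<cilia_table> %d cilia, %d measurements%s\n",
              nrow(x$records), ncol(x$records) - 1L,
              if (!is.null(x$metadata))
                paste0(", version ", x$metadata$tool_version)
              else ", version unknown"))
  invisible(x)
}

# micrometric columns are written with fixed 3-decimal formatting; counts stay
# integer. "." is the only accepted decimal separator (US number format).
format_cell <- function(v) {
  if (is.numeric(v) && !all(v == round(v), na.rm = TRUE))
    sprintf("%.3f", v)
  else if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
  else as.character(v)
}

#' Write a per-cilium table as TSV
#'
#' UTF-8 TSV with a leading `#`-prefixed metadata block (tool version, number
#' format, settings), one header row, `.` decimal separator and fixed
#' 3-decimal formatting for non-integer numeric columns. [read_cilia_table()]
#' inverts it exactly.
#'
#' @param table a [cilia_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cilia_table <- function(table, path) {
  stopifnot(inherits(table, "cilia_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(table$metadata)) writeLines(meta_to_lines(table$metadata), con)
  rec <- table$records
  writeLines(paste(names(rec), collapse = "\t"), con)
  if (nrow(rec)) {
    cells <- vapply(seq_along(rec), function(j) format_cell(rec[[j]]),
                    character(nrow(rec)))
    if (nrow(rec) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a per-cilium TSV table
#'
#' Parses the `#` metadata block into [run_metadata()] (a missing version
#' yields a table flagged "version unknown"; the explorer warns later).
#' Numeric columns are parsed strictly: a comma-decimal cell raises a dialect
#' error and any other non-numeric cell in a numeric column raises rather
#' than silently coercing to `NA`.
#'
#' @param path TSV path.
#' @param group_label,replicate_id optional identity labels to attach.
#' @return a [cilia_table()].
#' @export
read_cilia_table <- function(path, group_label = NA_character_,
                             replicate_id = NA_character_) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no header row in ", path)
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  rows <- lapply(body[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  if (length(rows) && any(lengths(rows) != length(header)))
    stop("ragged rows in ", path)
  cols <- lapply(seq_along(header), function(j) {
    vapply(rows, `[`, "", j)
  })
  names(cols) <- header
  cols <- lapply(cols, parse_column)
  rec <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  if (!length(rows)) {
    rec <- rec[0, , drop = FALSE]
  }
  meta <- NULL
  version_known <- FALSE
  if (length(meta_lines)) {
    m <- lines_to_meta(meta_lines)
    if (!is.na(m$tool_version)) {
      meta <- run_metadata(m$tool_version, m$settings)
      version_known <- TRUE
    } else if (length(m$settings)) {
      meta <- run_metadata("unknown", m$settings)
    }
  }
  tab <- cilia_table(rec, metadata = meta,
                     source_image = basename(path),
                     group_label = group_label, replicate_id = replicate_id)
  attr(tab, "version_unknown") <- !version_known
  tab
}

# strict numeric parsing: all-numeric-looking columns become numeric; a column
# that is mostly numeric but holds a stray cell raises; comma decimals raise a
# dedicated dialect error.
parse_column <- function(x) {
  if (!length(x)) return(character(0))
  if (any(grepl("^-?[0-9]+,[0-9]+$", x)))
    stop("comma decimal separator found ('", x[grepl(",", x)][1],
         "'); tables must use the US number format with '.' decimals")
  num_like <- grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x) |
    x %in% c("NA", "NaN", "Inf", "-Inf")
  if (all(num_like)) {
    as.numeric(ifelse(x == "NA", NA, x))
  } else if (any(num_like)) {
    stop("non-numeric cell '", x[!num_like][1], "' in a numeric column")
  } else {
    x
  }
}

#' Read an experimental metafile
#'
#' A key/value table (TSV or CSV; two columns) carrying experimental
#' annotations (objective, fluorophores, ...). Annotations are attached to the
#' analysis report verbatim; unknown keys are preserved. On a duplicate key
#' the last value wins with a warning. An unreadable file yields a warning
#' and an empty annotation set so the analysis can proceed.
#'
#' @param path metafile path.
#' @return named character vector of annotations (possibly empty).
#' @export
read_metafile <- function(path) {
  if (!file.exists(path)) {
    warning("metafile unreadable (no such file: ", path,
            "); proceeding without metadata")
    return(setNames(character(0), character(0)))
  }
  res <- tryCatch({
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(setNames(character(0), character(0)))
    sep <- if (grepl("\t", lines[[1]])) "\t" else ","
    kv <- strsplit(lines, sep, fixed = TRUE)
    keys <- vapply(kv, function(x) trimws(x[[1]]), "")
    vals <- vapply(kv, function(x)
      if (length(x) > 1) trimws(paste(x[-1], collapse = sep)) else "", "")
    if (length(keys) && identical(tolower(keys[1]), "key")) {
      keys <- keys[-1]; vals <- vals[-1]
    }
    if (anyDuplicated(keys)) {
      warning("duplicate metafile key(s): ",
              paste(unique(keys[duplicated(keys)]), collapse = ", "),
              "; last value wins")
      keep <- !duplicated(keys, fromLast = TRUE)
      keys <- keys[keep]; vals <- vals[keep]
    }
    setNames(vals, keys)
  }, error = function(e) {
    warning("metafile unreadable (", conditionMessage(e),
            "); proceeding without metadata")
    setNames(character(0), character(0))
  })
  res
}
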