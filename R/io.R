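#' Read a numeric matrix from delimited text
#'
#' Delimiter inferred from the extension (`.csv` comma, `.tsv`/`.txt`
#' tab). An optional header row of labels is detected (first row
#' non-numeric) and preserved as dimnames. Ragged rows and non-numeric
#' cells are reported with their row (and column) position.
#'
#' @param path file path.
#' @param header force header handling; `NA` (default) auto-detects.
#' @return Numeric matrix, with column names when a header is present.
#' @export
read_matrix <- function(path, header = NA) {
  stop_if(!file.exists(path), "file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) > 1)
    stop(sprintf("ragged file %s: row %d has %d fields, expected %d",
                 path, which(lens != lens[1])[1], lens[lens != lens[1]][1],
                 lens[1]), call. = FALSE)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(cells[[1]])))
  has_header <- if (is.na(header)) !first_numeric else header
  labels <- NULL
  if (has_header) {
    labels <- trimws(cells[[1]])
    cells <- cells[-1]
  }
  m <- t(vapply(cells, function(r) suppressWarnings(as.numeric(r)),
                numeric(lens[1])))
  if (length(cells) == 1) m <- matrix(m, nrow = 1)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at data row %d, column %d",
                 path, bad[1], bad[2]), call. = FALSE)
  }
  if (!is.null(labels)) colnames(m) <- labels
  m
}

#' Write a numeric matrix as delimited text
#'
#' Full precision (17 significant digits), so write-then-read round-trips
#' exactly; delimiter inferred from the extension as in [read_matrix].
#'
#' @param m numeric matrix.
#' @param path destination path (`.csv` or `.tsv`).
#' @param labels optional column labels written as a header row.
#' @export
write_matrix <- function(m, path, labels = colnames(m)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels)) writeLines(paste(labels, collapse = sep), con)
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = sep)), con)
  invisible(path)
}

#' Read and validate a parcellation label table
#'
#' Expects delimited text with columns `roi_name`, `network`,
#' `hemisphere`. Networks must be one of the eight resting-state labels
#' (visual, somatomotor, dorsal attention, salience/ventral attention,
#' limbic, control, DMN, subcortical); hemispheres `L`/`R`; ROI names
#' unique. A bundled synthetic 116-ROI table (100 cortical + 16
#' subcortical) ships as
#' `system.file("extdata", "parcellation_116_synthetic.csv", package = "mouec")`.
#'
#' @param path file path (comma- or tab-separated by extension).
#' @return Validated data frame, with attribute `network_counts`.
#' @export
read_parcellation <- function(path) {
  stop_if(!file.exists(path), "file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("roi_name", "network", "hemisphere")
  missing_cols <- setdiff(need, names(tab))
  stop_if(length(missing_cols) > 0, "parcellation misses column(s): %s",
          paste(missing_cols, collapse = ", "))
  allowed <- c("visual", "somatomotor", "dorsal attention",
               "salience/ventral attention", "limbic", "control", "DMN",
               "subcortical")
  bad <- setdiff(unique(tab$network), allowed)
  stop_if(length(bad) > 0, "unknown network label(s): %s",
          paste(bad, collapse = ", "))
  stop_if(!all(tab$hemisphere %in% c("L", "R")),
          "hemisphere must be 'L' or 'R'")
  dup <- tab$roi_name[duplicated(tab$roi_name)]
  stop_if(length(dup) > 0, "duplicate ROI name(s): %s",
          paste(unique(dup), collapse = ", "))
  attr(tab, "network_counts") <- table(tab$network)
  tab
}

#' Write a session's time series as delimited text
#'
#' Rows are time points, columns ROIs, with ROI labels as the header.
#'
#' @param session a [ts_session].
#' @param path destination (`.csv` or `.tsv`).
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ts_session"))
  write_matrix(session$data, path, labels = session$node_labels)
}

#' Read a session's time series from delimited text
#'
#' @param path file path (header row = ROI labels).
#' @param dt sampling period in seconds.
#' @param subject_id,group,condition identifiers.
#' @return A [ts_session].
#' @export
read_session <- function(path, dt, subject_id = NA_character_,
                         group = NA_character_, condition = NA_character_) {
  m <- read_matrix(path)
  ts_session(m, dt = dt, node_labels = colnames(m),
             subject_id = subject_id, group = group, condition = condition)
}
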