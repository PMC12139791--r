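# Readers/writers for the package's on-disk dialects: delimited-text edge
# masks and connectomes, CSV session manifests, CSV go/no-go trial tables.
# Every reader is the inverse of its writer on the writer's own output.

# Read a delimited numeric matrix, tolerating comma or whitespace separation
# and an optional header line.
read_delim_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(
    read.table(path, sep = sep, header = FALSE, colClasses = "numeric"),
    error = function(e) NULL
  )
  if (is.null(tab)) {  # retry assuming a header row of column names
    tab <- tryCatch(
      read.table(path, sep = sep, header = TRUE, colClasses = "numeric"),
      error = function(e) stop("cannot parse numeric matrix from ", path,
                               call. = FALSE)
    )
  }
  unname(as.matrix(tab))
}

#' Read a binary edge mask from a delimited text file
#'
#' Accepts either a full symmetric 0/1 matrix or a strictly triangular one
#' (which is mirrored), whitespace- or comma-delimited, with or without a
#' header line — the dialect used by published network-mask repositories.
#'
#' @param path Path to the mask file.
#' @param n_nodes Expected number of nodes; the parsed matrix must be
#'   `n_nodes` x `n_nodes`.
#' @param label Label to attach; defaults to the file name.
#' @return An [edge_mask()].
#' @export
read_edge_mask <- function(path, n_nodes, label = basename(path)) {
  m <- read_delim_matrix(path)
  if (nrow(m) != n_nodes || ncol(m) != n_nodes) {
    stop(sprintf("mask %s is %dx%d, expected %dx%d",
                 path, nrow(m), ncol(m), n_nodes, n_nodes), call. = FALSE)
  }
  edge_mask(m, label = label)
}

#' Write an edge mask as tab-delimited 0/1 text
#'
#' @param mask An [edge_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_mask <- function(mask, path) {
  stopifnot(inherits(mask, "edge_mask"))
  write.table(mask$matrix, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Full-precision formatting so that text round-trips reproduce doubles
# exactly (17 significant digits).
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

#' Read/write a Fisher-z connectome as delimited text
#'
#' `write_conn_matrix()` stores the full square matrix at 17 significant
#' digits (exact double round-trip); when any node is invalid it also writes
#' a `<path>.valid` sidecar of per-node 0/1 flags. `read_conn_matrix()` uses
#' the sidecar when present and otherwise flags all-NaN rows as invalid.
#'
#' @param path Path of the matrix file.
#' @param meta Optional metadata list attached to the result.
#' @return `read_conn_matrix()` returns a [conn_matrix()];
#'   `write_conn_matrix()` returns `path` invisibly.
#' @export
read_conn_matrix <- function(path, meta = NULL) {
  m <- read_delim_matrix(path)
  if (nrow(m) != ncol(m)) {
    stop("connectome file must hold a square matrix: ", path, call. = FALSE)
  }
  sidecar <- paste0(path, ".valid")
  valid <- if (file.exists(sidecar)) {
    as.logical(scan(sidecar, what = integer(), quiet = TRUE))
  } else NULL
  conn_matrix(m, valid_nodes = valid, meta = meta)
}

#' @param conn A [conn_matrix()].
#' @rdname read_conn_matrix
#' @export
write_conn_matrix <- function(conn, path) {
  stopifnot(inherits(conn, "conn_matrix"))
  lines <- apply(conn$values, 1L, function(row) {
    paste(format_full(row), collapse = "\t")
  })
  writeLines(lines, path)
  if (!all(conn$valid_nodes)) {
    writeLines(as.character(as.integer(conn$valid_nodes)),
               paste0(path, ".valid"))
  }
  invisible(path)
}

MANIFEST_COLUMNS <- c("subject_id", "condition", "run_type", "path",
                      "max_displacement_mm", "mean_censored_motion_mm",
                      "frac_censored", "missing_nodes")

#' Read a session manifest
#'
#' The manifest is a CSV with one row per subject x condition x run-type
#' session, carrying the motion quality-control metrics that drive run
#' exclusion. Required columns: `subject_id`, `condition` (MA/PL),
#' `run_type` (rest/mid/doors1/doors2/orientation), `path`,
#' `max_displacement_mm`, `mean_censored_motion_mm`, `frac_censored`,
#' `missing_nodes` (semicolon-separated 1-based node indices, may be empty).
#' An optional `session_index` column records administration order.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one row per session; `missing_nodes` is a
#'   list-column of integer vectors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(missing_nodes = "character"))
  missing <- setdiff(MANIFEST_COLUMNS, names(tab))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_cond <- setdiff(unique(tab$condition), CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition value(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  bad_run <- setdiff(unique(tab$run_type), RUN_TYPES)
  if (length(bad_run)) {
    stop("unknown run_type value(s): ", paste(bad_run, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(tab$frac_censored) &
          (tab$frac_censored < 0 | tab$frac_censored > 1))) {
    stop("frac_censored must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(tab)
  out$subject_id <- as.character(out$subject_id)
  out$missing_nodes <- lapply(tab$missing_nodes, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) integer(0)
    else as.integer(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  })
  out
}

#' Write a session manifest
#'
#' @param manifest Tibble/data frame in the layout produced by
#'   [read_manifest()] (list-column `missing_nodes` allowed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- as.data.frame(manifest)
  if (is.list(out$missing_nodes)) {
    out$missing_nodes <- vapply(out$missing_nodes, paste, character(1),
                                collapse = ";")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a go/no-go trial table
#'
#' CSV with columns `trial_index`, `category` ("go"/"nogo") and `responded`
#' (0/1), one row per trial of a continuous performance run.
#'
#' @param path CSV path.
#' @return `read_gradcpt_trials()` returns a tibble with logical
#'   `responded`; `write_gradcpt_trials()` returns `path` invisibly.
#' @export
read_gradcpt_trials <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "category", "responded")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$category), c("go", "nogo"))
  if (length(bad)) {
    stop("unknown trial category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("trial table has no trials", call. = FALSE)
  tab$responded <- as.logical(tab$responded)
  tibble::as_tibble(tab)
}

#' @param trials Trial-table tibble/data frame.
#' @rdname read_gradcpt_trials
#' @export
write_gradcpt_trials <- function(trials, path) {
  out <- as.data.frame(trials)
  out$responded <- as.integer(out$responded)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
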