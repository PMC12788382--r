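# Plain-text readers and writers for FCN stacks, persistence diagrams and
# results. All writers are deterministic: fixed ordering and floats at 17
# significant digits, so identical inputs give byte-identical files.
# All indices written to or read from disk are 0-based.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out
}

#' Write an FCN stack to disk
#'
#' Two dialects: `"delimited"` writes one comma-separated file per
#' timepoint (`fcn_0000.csv`, zero-padded 0-based index) into the directory
#' `path`; `"archive"` writes a single file whose first line is `T,R`
#' followed by the `T` stacked `R x R` matrices. Values carry 17
#' significant digits so a round trip is bit-faithful.
#'
#' @param fcn A `tempoph_fcn`.
#' @param path Target directory (`delimited`) or file (`archive`).
#' @param dialect `"delimited"` or `"archive"`.
#' @return `path`, invisibly.
#' @export
write_fcn_stack <- function(fcn, path, dialect = c("delimited", "archive")) {
  stopifnot(inherits(fcn, "tempoph_fcn"))
  dialect <- match.arg(dialect)
  d <- dim(fcn$matrices)
  if (dialect == "delimited") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_len(d[1])) {
      m <- fcn$matrices[t, , ]
      lines <- apply(m, 1, function(row) paste(fmt_num(row), collapse = ","))
      writeLines(lines, file.path(path, sprintf("fcn_%04d.csv", t - 1L)))
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d,%d", d[1], d[2]), con)
    for (t in seq_len(d[1])) {
      m <- fcn$matrices[t, , ]
      writeLines(apply(m, 1, function(row) paste(fmt_num(row),
                                                 collapse = ",")), con)
    }
  }
  invisible(path)
}

read_matrix_lines <- function(lines, t_label) {
  rows <- strsplit(lines, ",", fixed = TRUE)
  vals <- lapply(rows, as.numeric)
  R <- length(vals[[1]])
  if (any(lengths(vals) != R))
    stop_param("timepoint %d: ragged rows", t_label)
  m <- do.call(rbind, vals)
  if (nrow(m) != R)
    stop_param("timepoint %d: matrix is not square (%d x %d)",
               t_label, nrow(m), R)
  m
}

#' Read an FCN stack from disk
#'
#' Inverse of [write_fcn_stack()]. Validates every timepoint: square shape,
#' consistent region count, no NaN; symmetry within `1e-8` (symmetrized by
#' averaging, with attribute `asymmetry_warning` set if any averaging
#' happened); unit diagonal within `1e-6`; entries within
#' `[-1 - 1e-9, 1 + 1e-9]` (clipped). Violations raise a format error
#' naming the offending (0-based) timepoint.
#'
#' @param path Directory (`delimited`) or file (`archive`).
#' @param dialect `"delimited"` or `"archive"`.
#' @param tr_ms Sampling period recorded on the result (default `NA`).
#' @return A `tempoph_fcn`.
#' @export
read_fcn_stack <- function(path, dialect = c("delimited", "archive"),
                           tr_ms = NA_real_) {
  dialect <- match.arg(dialect)
  if (dialect == "delimited") {
    files <- sort(list.files(path, pattern = "^fcn_\\d+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop_param("no per-timepoint files found in %s", path)
    mats <- lapply(seq_along(files), function(i) {
      read_matrix_lines(readLines(files[i]), i - 1L)
    })
  } else {
    lines <- readLines(path)
    hdr <- as.integer(strsplit(lines[1], ",", fixed = TRUE)[[1]])
    if (length(hdr) != 2L || anyNA(hdr))
      stop_param("archive header must be 'T,R'")
    Tn <- hdr[1]; R <- hdr[2]
    if (length(lines) != 1L + Tn * R)
      stop_param("archive has %d data lines, expected %d",
                 length(lines) - 1L, Tn * R)
    mats <- lapply(seq_len(Tn), function(t) {
      read_matrix_lines(lines[(1L + (t - 1L) * R + 1L):(1L + t * R)], t - 1L)
    })
  }
  R <- nrow(mats[[1]])
  asym_flag <- FALSE
  for (t in seq_along(mats)) {
    m <- mats[[t]]
    if (nrow(m) != R)
      stop_param("timepoint %d: inconsistent region count (%d vs %d)",
                 t - 1L, nrow(m), R)
    if (anyNA(m))
      stop_param("timepoint %d: NaN entries", t - 1L)
    asym <- max_asymmetry(m)
    if (asym > 1e-8)
      stop_param("timepoint %d: asymmetry %g exceeds tolerance 1e-8",
                 t - 1L, asym)
    if (asym > 0) {
      mats[[t]] <- (m + t(m)) / 2
      asym_flag <- TRUE
      m <- mats[[t]]
    }
    if (max(abs(diag(m) - 1)) > 1e-6)
      stop_param("timepoint %d: diagonal departs from 1 by more than 1e-6",
                 t - 1L)
    if (max(abs(m)) > 1 + 1e-9)
      stop_param("timepoint %d: entries outside [-1 - 1e-9, 1 + 1e-9]",
                 t - 1L)
    m[m > 1] <- 1
    m[m < -1] <- -1
    mats[[t]] <- m
  }
  arr <- array(NA_real_, c(length(mats), R, R))
  for (t in seq_along(mats)) arr[t, , ] <- mats[[t]]
  out <- fcn_sequence(arr, tr_ms = tr_ms)
  attr(out, "asymmetry_warning") <- asym_flag
  out
}

#' Write persistence diagrams to delimited text
#'
#' One row per interval with columns `timepoint,birth,death` (0-based
#' timepoints; infinite deaths serialized as the token `inf`), plus a JSON
#' sidecar `<path>.index.json` enumerating every timepoint and its interval
#' count, so empty diagrams survive a round trip.
#'
#' @param diagrams Nonempty list of [persistence_diagram()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_persistence_diagrams <- function(diagrams, path) {
  stopifnot(is.list(diagrams), length(diagrams) > 0L)
  lapply(diagrams, function(d) stopifnot(inherits(d, "tempoph_diagram")))
  lines <- "timepoint,birth,death"
  for (t in seq_along(diagrams)) {
    m <- unclass(diagrams[[t]])
    if (nrow(m) > 0L)
      lines <- c(lines, sprintf("%d,%s,%s", t - 1L,
                                fmt_num(m[, 1]), fmt_num(m[, 2])))
  }
  writeLines(lines, path)
  idx <- list(n_timepoints = length(diagrams),
              timepoints = seq_along(diagrams) - 1L,
              counts = vapply(diagrams, nrow, integer(1)))
  jsonlite::write_json(idx, paste0(path, ".index.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read persistence diagrams written by [write_persistence_diagrams()]
#'
#' @param path File path; the sidecar `<path>.index.json` is used when
#'   present (required to reconstruct empty diagrams).
#' @return List of `tempoph_diagram` objects.
#' @export
read_persistence_diagrams <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != "timepoint,birth,death")
    stop_param("unexpected diagram file header")
  body <- lines[-1]
  parse_val <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    out[x == "inf"] <- Inf
    out[x == "-inf"] <- -Inf
    out
  }
  if (length(body) > 0L) {
    parts <- do.call(rbind, strsplit(body, ",", fixed = TRUE))
    tp <- as.integer(parts[, 1])
    births <- parse_val(parts[, 2])
    deaths <- parse_val(parts[, 3])
  } else {
    tp <- integer(0); births <- numeric(0); deaths <- numeric(0)
  }
  idx_path <- paste0(path, ".index.json")
  n_tp <- if (file.exists(idx_path)) {
    as.integer(jsonlite::read_json(idx_path)$n_timepoints)
  } else if (length(tp) > 0L) max(tp) + 1L else 0L
  lapply(seq_len(n_tp) - 1L, function(t) {
    sel <- tp == t
    persistence_diagram(births[sel], deaths[sel])
  })
}

#' Write study results as versioned JSON
#'
#' Serializes a [run_study()] result (or any compatible structure with
#' per-subject, per-cohort cluster results plus study-level consistency
#' summaries) deterministically. Every `(subject, cohort, pipeline)` cell
#' must carry a chosen `k` or a recorded failure.
#'
#' @param results A `tempoph_study` or compatible list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.list(results))
  if (is.null(results$schema_version)) results$schema_version <- "1.0"
  for (s in results$subjects) {
    for (p in s$pipelines) {
      for (cell in p$cohorts) {
        if (is.null(cell$chosen_k) && is.null(cell$error))
          stop_param("every (subject, cohort) cell needs chosen_k or error")
      }
    }
  }
  results <- unclass(results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read study results written by [write_results()]
#'
#' @param path JSON file path.
#' @return The deserialized structure (lists; no simplification).
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
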