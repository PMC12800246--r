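# TPS landmark file reader/writer and sliders definitions.
#
# Dialect: records start with "LM=<k>", followed by exactly k
# whitespace-separated coordinate rows, then key lines (ID=, IMAGE=,
# SCALE=) until the next LM=. ID= is preferred over IMAGE= as the
# specimen identifier; unknown key lines are ignored with a warning.
# SCALE= multiplies the record's coordinates (units per coordinate unit).
# y increases upward (tpsDig convention); nothing is flipped on read.

#' Read a TPS landmark file
#'
#' Parses 2D landmark configurations from a TPS file into a long tibble
#' (`specimen`, `point`, `x`, `y`). `SCALE=` is applied when present;
#' point order is preserved; the specimen id is taken from the `ID=` line,
#' falling back to `IMAGE=` (extension stripped), then to a positional
#' name.
#'
#' @param path Path to a TPS file.
#' @return A landmark tibble, one row per point.
#' @export
#' @seealso [write_tps()]
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  records <- list()
  i <- 1L
  rec_no <- 0L
  unknown_keys <- character()
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- lines[i]
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      abort(paste0("line ", i, ": expected an LM= record header, got '",
                   line, "'"))
    }
    rec_no <- rec_no + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 0) {
      abort(paste0("record ", rec_no, " (line ", i, "): malformed LM= count"))
    }
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > n_lines || lines[i] == "" ||
          grepl("^[A-Za-z]+\\s*=", lines[i])) {
        abort(paste0("record ", rec_no, ": LM=", k, " but only ", j - 1,
                     " coordinate row(s) found"))
      }
      parts <- strsplit(lines[i], "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        abort(paste0("record ", rec_no, " (line ", i,
                     "): non-numeric or malformed coordinate row '",
                     lines[i], "'"))
      }
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_
    image <- NA_character_
    scale <- NA_real_
    while (i <= n_lines && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      line <- lines[i]
      if (line == "") { i <- i + 1L; next }
      if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=\\s*", "", line, ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0) {
          abort(paste0("record ", rec_no, " (line ", i,
                       "): SCALE= must be a positive number"))
        }
      } else if (grepl("^[A-Za-z]+\\s*=", line)) {
        unknown_keys <- c(unknown_keys, sub("\\s*=.*$", "", line))
      } else {
        abort(paste0("record ", rec_no, " (line ", i,
                     "): unexpected extra coordinate row '", line,
                     "' after LM= count exhausted"))
      }
      i <- i + 1L
    }
    if (!is.na(scale)) coords <- coords * scale
    sid <- if (!is.na(id) && nzchar(id)) {
      id
    } else if (!is.na(image) && nzchar(image)) {
      sub("\\.[A-Za-z0-9]+$", "", image)
    } else {
      paste0("specimen_", rec_no)
    }
    records[[rec_no]] <- tibble(specimen = sid, point = seq_len(k),
                                x = coords[, 1], y = coords[, 2])
  }
  if (length(unknown_keys) > 0) {
    warn(paste0("ignored unknown TPS key line(s): ",
                paste(unique(unknown_keys), collapse = ", ")))
  }
  if (length(records) == 0) {
    return(tibble(specimen = character(), point = integer(),
                  x = double(), y = double()))
  }
  out <- dplyr::bind_rows(records)
  if (anyDuplicated(unique(out$specimen)) > 0) {
    abort("duplicated specimen ids in TPS file")
  }
  validate_landmarks(out)
}

#' Write landmark configurations to a TPS file
#'
#' Emits the standard `LM=` / coordinate-rows / `ID=` dialect. All
#' configurations must share the same landmark count; coordinates are
#' written at full double precision so a [read_tps()] round trip is
#' lossless to well below 1e-9. An empty table produces an empty file.
#'
#' @param landmarks A landmark tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  if (nrow(landmarks) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ks <- table(landmarks$specimen)
  if (length(unique(as.integer(ks))) > 1) {
    abort(paste0("cannot write TPS: configurations differ in k: ",
                 paste(names(ks), as.integer(ks), sep = "=",
                       collapse = ", ")))
  }
  landmarks <- validate_landmarks(landmarks)
  ids <- unique(landmarks$specimen)
  k <- as.integer(ks[1])
  blocks <- lapply(ids, function(id) {
    rec <- landmarks[landmarks$specimen == id, ]
    rec <- rec[order(rec$point), ]
    c(paste0("LM=", k),
      sprintf("%.12g %.12g", rec$x, rec$y),
      paste0("ID=", id))
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read or write a sliders definition
#'
#' A sliders file is a three-column CSV (`before`, `slider`, `after`) of
#' landmark indices: each `slider` point is a semi-landmark allowed to
#' slide along its outline, with `before`/`after` its curve neighbours.
#' Indices are 1-based by default (the R/geomorph convention); files
#' written by 0-based tools can be imported with `zero_based = TRUE`,
#' which adds 1 on read.
#'
#' @param path Path to the CSV file.
#' @param zero_based If `TRUE`, indices in the file are 0-based and are
#'   converted to 1-based on read.
#' @return A tibble with integer columns `before`, `slider`, `after`.
#' @export
read_sliders <- function(path, zero_based = FALSE) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           before = readr::col_integer(),
                           slider = readr::col_integer(),
                           after = readr::col_integer()
                         ))
  req <- c("before", "slider", "after")
  if (!all(req %in% names(tbl))) {
    abort("sliders file must have columns before, slider, after")
  }
  tbl <- tibble::as_tibble(tbl[, req])
  if (zero_based) tbl <- tibble::as_tibble(tbl + 1L)
  tbl
}

#' @rdname read_sliders
#' @param sliders A sliders tibble.
#' @export
write_sliders <- function(sliders, path) {
  readr::write_csv(sliders[, c("before", "slider", "after")], path)
  invisible(path)
}

#' Validate sliders against a landmark count
#'
#' Checks that all indices are within `1..k`, that no slider is its own
#' neighbour, and that no point is listed as a slider twice.
#'
#' @param sliders A sliders tibble (`before`, `slider`, `after`).
#' @param k Number of landmarks per configuration.
#' @return The validated sliders tibble.
#' @export
validate_sliders <- function(sliders, k) {
  if (nrow(sliders) == 0) return(sliders)
  idx <- c(sliders$before, sliders$slider, sliders$after)
  if (any(idx < 1 | idx > k)) {
    abort(paste0("slider indices must be in 1..", k))
  }
  if (any(sliders$before == sliders$slider |
            sliders$after == sliders$slider)) {
    abort("a semi-landmark cannot be its own curve neighbour")
  }
  if (anyDuplicated(sliders$slider)) {
    abort("each semi-landmark may appear only once in the sliders table")
  }
  sliders
}
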