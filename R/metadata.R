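# Species metadata schema: taxonomic group, aquatic habitat, optional
# precise palaeoenvironment, locality/formation, first/last occurrence
# ages (Ma), and an adult/juvenile marker.

#' Read and validate a species metadata table
#'
#' Reads a CSV with columns `species`, `group`, `habitat`,
#' `palaeoenvironment`, `locality`, `fad_ma`, `lad_ma`, `ontogeny`.
#' `group` and `habitat` are checked against closed vocabularies
#' ([sarc_groups()], [sarc_habitats()]); `palaeoenvironment` may be empty
#' (unknown) but otherwise must be one of [sarc_palaeoenvironments()].
#' Ages are in Ma and must satisfy `fad_ma >= lad_ma` (first occurrences
#' are older). Validation is all-or-nothing: every offending row is
#' reported, none is silently dropped.
#'
#' @param path Path to a CSV file.
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species = readr::col_character(),
                           group = readr::col_character(),
                           habitat = readr::col_character(),
                           palaeoenvironment = readr::col_character(),
                           locality = readr::col_character(),
                           fad_ma = readr::col_double(),
                           lad_ma = readr::col_double(),
                           ontogeny = readr::col_character()
                         ))
  validate_metadata(tbl)
}

#' @rdname read_metadata
#' @param metadata A data frame with the columns listed above.
#' @export
validate_metadata <- function(metadata) {
  req <- c("species", "group", "habitat", "palaeoenvironment", "locality",
           "fad_ma", "lad_ma", "ontogeny")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  metadata <- tibble::as_tibble(metadata)
  errors <- character()
  bad_group <- !metadata$group %in% sarc_groups()
  if (any(bad_group)) {
    errors <- c(errors, paste0(
      "unknown group for species ",
      paste0(metadata$species[bad_group], " ('",
             metadata$group[bad_group], "')", collapse = ", "),
      "; allowed: ", paste(sarc_groups(), collapse = ", ")))
  }
  bad_hab <- !metadata$habitat %in% sarc_habitats()
  if (any(bad_hab)) {
    errors <- c(errors, paste0(
      "unknown habitat for species ",
      paste0(metadata$species[bad_hab], " ('",
             metadata$habitat[bad_hab], "')", collapse = ", "),
      "; allowed: ", paste(sarc_habitats(), collapse = ", ")))
  }
  env <- metadata$palaeoenvironment
  bad_env <- !is.na(env) & env != "" & !env %in% sarc_palaeoenvironments()
  if (any(bad_env)) {
    errors <- c(errors, paste0(
      "unknown palaeoenvironment for species ",
      paste0(metadata$species[bad_env], " ('", env[bad_env], "')",
             collapse = ", ")))
  }
  bad_age <- is.na(metadata$fad_ma) | is.na(metadata$lad_ma) |
    metadata$fad_ma < metadata$lad_ma
  if (any(bad_age)) {
    errors <- c(errors, paste0(
      "invalid age range (need fad_ma >= lad_ma, ages in Ma) for species ",
      paste(metadata$species[bad_age], collapse = ", ")))
  }
  if (anyDuplicated(metadata$species)) {
    errors <- c(errors, paste0(
      "duplicated species: ",
      paste(unique(metadata$species[duplicated(metadata$species)]),
            collapse = ", ")))
  }
  if (length(errors) > 0) {
    abort(paste0("metadata validation failed (", nrow(metadata),
                 " rows read, 0 accepted):\n- ",
                 paste(errors, collapse = "\n- ")))
  }
  metadata$palaeoenvironment[!is.na(env) & env == ""] <- NA_character_
  metadata
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path, na = "")
  invisible(path)
}
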