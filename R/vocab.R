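# Closed vocabularies for species metadata and the built-in geological
# time scales (Ludfordian -> Gzhelian, ICS-style boundary ages).

#' Controlled vocabularies for early sarcopterygian metadata
#'
#' The metadata schema restricts the `group` and `habitat` columns to closed
#' vocabularies (eight early sarcopterygian clades; three salinity classes)
#' and `palaeoenvironment` to ten categories, which may also be missing when
#' no detailed information is available.
#'
#' @return A character vector of allowed tokens.
#' @export
#' @examples
#' sarc_groups()
sarc_groups <- function() {
  c("Onychodontida", "Actinistia", "Porolepiformes", "Dipnoi",
    "Rhizodontida", "Osteolepiformes", "Elpistostegalia", "Tetrapoda")
}

#' @rdname sarc_groups
#' @export
sarc_habitats <- function() {
  c("marine", "estuarine", "freshwater")
}

#' @rdname sarc_groups
#' @export
sarc_palaeoenvironments <- function() {
  c("reef", "coastal marine", "bay", "estuary", "lagoon", "fluvial delta",
    "alluvial plain", "oxbow lake and meandering river",
    "calm freshwater lake", "dynamic freshwater lake")
}

#' Built-in geological time scales (late Silurian to end-Carboniferous)
#'
#' Stage- and epoch-level interval tables spanning the Ludfordian
#' (425.6 Ma) to the end of the Gzhelian (298.9 Ma), with ICS-style
#' boundary ages. Ages are in Ma and decrease toward the present;
#' `start_ma` is the older boundary of each interval. The tables are also
#' shipped as CSV under `inst/extdata/` and any user-supplied table read
#' with [read_timescale()] can replace them.
#'
#' The exact boundary ages are pinned here so analyses are reproducible
#' against one declared chart version; they can be overridden wholesale by
#' supplying a different table.
#'
#' @return A timescale tibble with columns `interval`, `start_ma`, `end_ma`.
#' @seealso [equal_bins()], [read_timescale()]
#' @export
#' @examples
#' sarcopterygian_stages()
sarcopterygian_stages <- function() {
  tbl <- tibble::tribble(
    ~interval,      ~start_ma, ~end_ma,
    "Ludfordian",       425.6,   423.0,
    "Pridoli",          423.0,   419.2,
    "Lochkovian",       419.2,   410.8,
    "Pragian",          410.8,   407.6,
    "Emsian",           407.6,   393.3,
    "Eifelian",         393.3,   387.7,
    "Givetian",         387.7,   382.7,
    "Frasnian",         382.7,   372.2,
    "Famennian",        372.2,   358.9,
    "Tournaisian",      358.9,   346.7,
    "Visean",           346.7,   330.9,
    "Serpukhovian",     330.9,   323.2,
    "Bashkirian",       323.2,   315.2,
    "Moscovian",        315.2,   307.0,
    "Kasimovian",       307.0,   303.7,
    "Gzhelian",         303.7,   298.9
  )
  validate_timescale(tbl)
}

#' @rdname sarcopterygian_stages
#' @export
sarcopterygian_epochs <- function() {
  # Ludlow is truncated at the Ludfordian base, where the sampling begins.
  tbl <- tibble::tribble(
    ~interval,         ~start_ma, ~end_ma,
    "Ludlow",              425.6,   423.0,
    "Pridoli",             423.0,   419.2,
    "Lower Devonian",      419.2,   393.3,
    "Middle Devonian",     393.3,   382.7,
    "Upper Devonian",      382.7,   358.9,
    "Mississippian",       358.9,   323.2,
    "Pennsylvanian",       323.2,   298.9
  )
  validate_timescale(tbl)
}

#' Read a geological time scale from CSV
#'
#' Expects columns `interval`, `start_ma`, `end_ma` with contiguous,
#' non-overlapping intervals ordered old to young (`start_ma > end_ma`).
#'
#' @param path Path to a CSV file.
#' @return A validated timescale tibble.
#' @export
read_timescale <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           interval = readr::col_character(),
                           start_ma = readr::col_double(),
                           end_ma = readr::col_double()
                         ))
  validate_timescale(tbl)
}

validate_timescale <- function(tbl) {
  req <- c("interval", "start_ma", "end_ma")
  if (!all(req %in% names(tbl))) {
    abort(paste0("timescale must have columns ", paste(req, collapse = ", ")))
  }
  if (any(tbl$start_ma <= tbl$end_ma)) {
    abort("timescale intervals must have start_ma > end_ma (ages in Ma)")
  }
  if (nrow(tbl) > 1) {
    if (any(diff(tbl$start_ma) >= 0)) {
      abort("timescale intervals must be strictly ordered old to young")
    }
    gaps <- head(tbl$end_ma, -1) - tail(tbl$start_ma, -1)
    if (any(abs(gaps) > 1e-9)) {
      abort("timescale intervals must be contiguous (no gaps or overlaps)")
    }
  }
  if (anyDuplicated(tbl$interval)) abort("duplicated interval names in timescale")
  tibble::as_tibble(tbl[, req])
}
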