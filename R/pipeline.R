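# Orchestration: one run = align -> ordinate -> disparity by grouping
# variables -> disparity-through-time (epochs and equal bins) ->
# range-through richness, with an optional locality jackknife.
#
# All randomness flows from a single seed via fixed per-stage offsets
# (documented in run_analysis), so any stage is individually
# reproducible from the run log.

#' Build or read a run configuration
#'
#' A run configuration names the input files and the analysis settings.
#' `read_run_config()` reads the same fields from a YAML file.
#'
#' @param tps,sliders,metadata Paths to the landmark TPS file, sliders
#'   CSV (optional, `NULL` for none) and metadata CSV.
#' @param timescale Optional path to a stage-level timescale CSV;
#'   defaults to the built-in [sarcopterygian_stages()].
#' @param epochs Optional path to an epoch-level timescale CSV; defaults
#'   to [sarcopterygian_epochs()].
#' @param grouping Metadata columns to compute disparity tables for.
#' @param n_permutations Permutations for pairwise tests.
#' @param seed Integer seed (mandatory).
#' @param n_pcs_weighted PCs for the weighted hull area.
#' @param n_bins Number of equal-width time bins.
#' @param tangent Project to tangent space before PCA?
#' @param sliders_zero_based Are slider indices in the file 0-based?
#' @param jackknife_locality Locality to exclude in [jackknife_locality()]
#'   runs (optional).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(tps, sliders = NULL, metadata, timescale = NULL,
                       epochs = NULL,
                       grouping = c("group", "habitat",
                                    "palaeoenvironment"),
                       n_permutations = 999, seed,
                       n_pcs_weighted = 5, n_bins = 7, tangent = FALSE,
                       sliders_zero_based = FALSE,
                       jackknife_locality = NULL, out_dir) {
  if (missing(seed)) abort("run_config requires an explicit seed")
  structure(
    list(tps = tps, sliders = sliders, metadata = metadata,
         timescale = timescale, epochs = epochs, grouping = grouping,
         n_permutations = n_permutations, seed = as.integer(seed),
         n_pcs_weighted = n_pcs_weighted, n_bins = n_bins,
         tangent = tangent, sliders_zero_based = sliders_zero_based,
         jackknife_locality = jackknife_locality, out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML run configuration.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("run config must set a seed")
  run_config(
    tps = y$tps, sliders = y$sliders, metadata = y$metadata,
    timescale = y$timescale, epochs = y$epochs,
    grouping = y$grouping %||% c("group", "habitat",
                                 "palaeoenvironment"),
    n_permutations = y$n_permutations %||% 999,
    seed = y$seed,
    n_pcs_weighted = y$n_pcs_weighted %||% 5,
    n_bins = y$n_bins %||% 7,
    tangent = isTRUE(y$tangent),
    sliders_zero_based = isTRUE(y$sliders_zero_based),
    jackknife_locality = y$jackknife_locality,
    out_dir = y$out_dir %||% "paleodisp_output"
  )
}

#' Run the full disparity analysis
#'
#' Executes, in order: input reading and validation, GPA (with sliding
#' when a sliders file is given), shape PCA, one disparity table per
#' grouping variable, disparity-through-time on both the epoch scale
#' (Procrustes variance) and the equal-bin scale (sum of variances),
#' and range-through richness on the stage scale. Every artifact is
#' written as CSV under `config$out_dir`, along with a machine-readable
#' run log (`run_log.json`: input hashes, seed, settings, package
#' version) sufficient to reproduce the run. Any stage failure aborts
#' with the stage name.
#'
#' Stage seeds are derived as `seed + 101 * i` for grouping variable `i`
#' (all below 2^31).
#'
#' @param config A [run_config()].
#' @param write Write output files? (`FALSE` returns results only.)
#' @return Invisibly, a list with `fit`, `ordination`, `disparity` (one
#'   `disparity_table` per grouping variable), `dtt_epochs`, `dtt_bins`,
#'   `richness`, and `metadata`.
#' @export
run_analysis <- function(config, write = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  landmarks <- stage("read_landmarks", read_tps(config$tps))
  sliders <- stage("read_sliders", {
    if (is.null(config$sliders)) NULL
    else read_sliders(config$sliders,
                      zero_based = config$sliders_zero_based)
  })
  metadata <- stage("read_metadata", read_metadata(config$metadata))
  stage("validate_crossrefs", {
    missing <- setdiff(unique(landmarks$specimen), metadata$species)
    if (length(missing) > 0) {
      abort(paste0("specimens without metadata: ",
                   paste(missing, collapse = ", ")))
    }
  })
  stages_tbl <- stage("read_timescale", {
    if (is.null(config$timescale)) sarcopterygian_stages()
    else read_timescale(config$timescale)
  })
  epochs_tbl <- stage("read_epochs", {
    if (is.null(config$epochs)) sarcopterygian_epochs()
    else read_timescale(config$epochs)
  })
  fit <- stage("gpa", gpa(landmarks, sliders = sliders))
  ord <- stage("pca", shape_pca(fit, tangent = config$tangent))
  meta_used <- metadata[metadata$species %in% fit$specimens, ]
  disparity <- list()
  for (i in seq_along(config$grouping)) {
    gv <- config$grouping[i]
    disparity[[gv]] <- stage(paste0("disparity_", gv), {
      disparity_table(fit, ord, meta_used, group_col = gv,
                      n_pcs = config$n_pcs_weighted,
                      n_perm = config$n_permutations,
                      seed = config$seed + 101L * i)
    })
  }
  dtt_epochs <- stage("dtt_epochs", {
    disparity_through_time(fit, ord, meta_used, epochs_tbl,
                           metric = "procrustes_variance")
  })
  bins <- equal_bins(max(stages_tbl$start_ma), min(stages_tbl$end_ma),
                     config$n_bins)
  dtt_bins <- stage("dtt_bins", {
    disparity_through_time(fit, ord, meta_used, bins,
                           metric = "sum_of_variances")
  })
  richness <- stage("richness",
                    range_through_richness(metadata, stages_tbl))
  results <- list(fit = fit, ordination = ord, disparity = disparity,
                  dtt_epochs = dtt_epochs, dtt_bins = dtt_bins,
                  richness = richness, metadata = metadata)
  if (write) stage("write_outputs", write_results(results, config))
  invisible(results)
}

write_results <- function(results, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(results$fit), file.path(out, "aligned.csv"))
  cons <- results$fit$consensus
  readr::write_csv(tibble(point = seq_len(nrow(cons)),
                          x = cons[, 1], y = cons[, 2]),
                   file.path(out, "consensus.csv"))
  readr::write_csv(tidy(results$ordination),
                   file.path(out, "scores.csv"))
  readr::write_csv(
    tibble(axis = paste0("PC",
                         seq_along(results$ordination$eigenvalues)),
           eigenvalue = results$ordination$eigenvalues,
           prop_variance = results$ordination$prop_variance),
    file.path(out, "prop_variance.csv"))
  for (gv in names(results$disparity)) {
    dt <- results$disparity[[gv]]
    readr::write_csv(tidy(dt),
                     file.path(out, paste0("disparity_", gv, ".csv")))
    readr::write_csv(tidy(dt$pairwise),
                     file.path(out, paste0("pairwise_", gv, ".csv")))
  }
  readr::write_csv(results$dtt_epochs, file.path(out, "dtt_epochs.csv"))
  readr::write_csv(results$dtt_bins, file.path(out, "dtt_bins.csv"))
  readr::write_csv(results$richness, file.path(out, "richness.csv"))
  inputs <- c(tps = config$tps, sliders = config$sliders,
              metadata = config$metadata, timescale = config$timescale,
              epochs = config$epochs)
  log <- list(
    inputs = as.list(tools::md5sum(unlist(inputs[!vapply(inputs, is.null,
                                                         logical(1))]))),
    seed = config$seed,
    grouping = config$grouping,
    n_permutations = config$n_permutations,
    n_pcs_weighted = config$n_pcs_weighted,
    n_bins = config$n_bins,
    tangent = config$tangent,
    package_version = as.character(utils::packageVersion("paleodisp")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Locality jackknife (Lagerstaette effect)
#'
#' Re-runs the complete analysis excluding every species whose locality
#' matches, and pairs it with the baseline run. Superimposition is
#' repeated from scratch on the reduced sample — the consensus depends
#' on the sample, so subsetting aligned coordinates would not be the
#' same analysis. Comparing the two disparity-through-time curves shows
#' how much of an interval's disparity rides on the excluded deposit.
#'
#' @param config A [run_config()].
#' @param locality Locality to exclude; defaults to
#'   `config$jackknife_locality`.
#' @param write Write both result bundles (under `baseline/` and
#'   `excluded/`)?
#' @return Invisibly, a list with `baseline`, `excluded` (result
#'   bundles; `excluded` is `NULL` when the locality is absent) and
#'   `difference`: the epoch disparity curves joined with columns
#'   `disparity_baseline`, `disparity_excluded`, `drop_fraction`.
#' @export
jackknife_locality <- function(config, locality = NULL, write = TRUE) {
  locality <- locality %||% config$jackknife_locality
  if (is.null(locality)) abort("no locality given to jackknife")
  metadata <- read_metadata(config$metadata)
  base_cfg <- config
  base_cfg$out_dir <- file.path(config$out_dir, "baseline")
  baseline <- run_analysis(base_cfg, write = write)
  excluded_species <- metadata$species[metadata$locality == locality]
  if (length(excluded_species) == 0) {
    warn(paste0("locality '", locality,
                "' matches no species; jackknife is a no-op"))
    return(invisible(list(baseline = baseline, excluded = NULL,
                          difference = NULL)))
  }
  keep <- setdiff(unique(baseline$fit$specimens), excluded_species)
  if (length(keep) < 3) {
    abort(paste0("excluding locality '", locality,
                 "' leaves fewer than 3 species; aborting"))
  }
  landmarks <- read_tps(config$tps)
  tmp_tps <- file.path(tempdir(),
                       paste0("jackknife_", as.integer(config$seed),
                              ".tps"))
  write_tps(landmarks[landmarks$specimen %in% keep, ], tmp_tps)
  tmp_meta <- sub("\\.tps$", "_metadata.csv", tmp_tps)
  write_metadata(metadata[metadata$species %in% keep, ], tmp_meta)
  ex_cfg <- config
  ex_cfg$tps <- tmp_tps
  ex_cfg$metadata <- tmp_meta
  ex_cfg$out_dir <- file.path(config$out_dir, "excluded")
  excluded <- run_analysis(ex_cfg, write = write)
  difference <- dplyr::left_join(
    dplyr::rename(baseline$dtt_epochs, disparity_baseline = "disparity",
                  n_baseline = "n"),
    dplyr::select(dplyr::rename(excluded$dtt_epochs,
                                disparity_excluded = "disparity",
                                n_excluded = "n"),
                  "interval", "n_excluded", "disparity_excluded"),
    by = "interval")
  difference$drop_fraction <-
    1 - difference$disparity_excluded / difference$disparity_baseline
  if (write) {
    readr::write_csv(difference,
                     file.path(config$out_dir,
                               "jackknife_difference.csv"))
  }
  invisible(list(baseline = baseline, excluded = excluded,
                 difference = difference))
}
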