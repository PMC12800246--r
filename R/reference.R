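# Published reference values for external comparison.
#
# The published early-sarcopterygian disparity study reports headline
# numbers (PC variance proportions, group Procrustes variances,
# disparity shares) computed from its deposited landmark data. Those
# data are not shipped here; when a copy is available locally, the
# pipeline can be re-run on it and compared against this table.

#' Published reference values for the early sarcopterygian datasets
#'
#' Headline results reported for the three published landmark datasets
#' (body outline, cheek, skull roof): leading PC variance percentages,
#' cheek Procrustes variances for key groups/habitats, and disparity
#' shares. Reproducing them requires the study's deposited landmark
#' data, which this package does not bundle; point
#' `options(paleodisp.deposited_data = <dir>)` at a local copy to run
#' the comparison (see [replicate_reference()]).
#'
#' @return A tibble with columns `dataset`, `quantity`, `value`, `unit`.
#' @export
reference_values <- function() {
  path <- system.file("extdata", "published_reference_values.csv",
                      package = "paleodisp")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    dataset = readr::col_character(),
                    quantity = readr::col_character(),
                    value = readr::col_double(),
                    unit = readr::col_character()
                  ))
}

#' Re-run the analysis on a local copy of the deposited study data
#'
#' Expects `dir` to contain, per dataset `d` in `body`, `cheek`,
#' `skull_roof`: `<d>.tps` (landmarks), optionally `<d>_sliders.csv`,
#' and one shared `metadata.csv` in the package's metadata schema.
#' Runs GPA + PCA + group/habitat disparity and returns the computed
#' analogues of [reference_values()] joined with the published numbers.
#'
#' @param dir Directory with the deposited data, converted to the
#'   package's input formats.
#' @param n_perm Permutations for disparity tables.
#' @param seed Seed for the permutation tests.
#' @return A tibble `dataset`, `quantity`, `value`, `computed`.
#' @export
replicate_reference <- function(dir, n_perm = 999, seed = 1) {
  md <- read_metadata(file.path(dir, "metadata.csv"))
  rows <- list()
  for (ds in c("body", "cheek", "skull_roof")) {
    tps <- file.path(dir, paste0(ds, ".tps"))
    if (!file.exists(tps)) next
    lms <- read_tps(tps)
    sl_path <- file.path(dir, paste0(ds, "_sliders.csv"))
    sl <- if (file.exists(sl_path)) read_sliders(sl_path) else NULL
    fit <- gpa(lms, sliders = sl)
    ord <- shape_pca(fit)
    meta <- md[md$species %in% fit$specimens, ]
    pv_group <- procrustes_variance(fit, meta, group_col = "group")
    pv_hab <- procrustes_variance(fit, meta, group_col = "habitat")
    add <- function(quantity, value) {
      rows[[length(rows) + 1]] <<- tibble(dataset = ds,
                                          quantity = quantity,
                                          computed = value)
    }
    add("pc1_prop_variance", 100 * ord$prop_variance[1])
    add("pc2_prop_variance", 100 * ord$prop_variance[2])
    for (g in pv_group$group) {
      add(paste0("procrustes_variance_", g),
          pv_group$pv[pv_group$group == g])
      add(paste0("disparity_share_", g),
          100 * pv_group$share[pv_group$group == g])
    }
    for (h in pv_hab$group) {
      add(paste0("procrustes_variance_", h),
          pv_hab$pv[pv_hab$group == h])
      add(paste0("disparity_share_", h),
          100 * pv_hab$share[pv_hab$group == h])
    }
  }
  computed <- dplyr::bind_rows(rows)
  dplyr::inner_join(reference_values(), computed,
                    by = c("dataset", "quantity"))
}
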