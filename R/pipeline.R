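#' Run configuration for the phantom study pipeline
#'
#' Bundles the phantom parameters, the preprocessing design grid, the
#' cross-validation parameters, and the mandatory master seed. Every output
#' of [run_reproducibility()] and [run_classification()] is a pure function
#' of this object.
#'
#' @param params A [phantom_params()] object.
#' @param normalizations,resamplings,n_gray_levels The design grid (defaults:
#'   three normalization arms, two resampling schemes, six bin counts).
#' @param roi_kinds ROI kinds to extract, subset of
#'   c("noncystic", "entire_kidney").
#' @param n_kidneys Cohort size for the reproducibility study (observation
#'   units are kidneys, one per case).
#' @param n_per_class,n_sites Cohort layout for the classification study.
#' @param folds,repeats Cross-validation parameters.
#' @param seed Master seed (mandatory).
#' @param output_dir Directory for reports and manifests.
#' @param target_matrix Resize target in pixels.
#' @return A `run_config` list.
#' @export
run_config <- function(params = phantom_params(),
                       normalizations = c("original", "zscore", "reference"),
                       resamplings = c("up_1.0mm", "down_2.0mm"),
                       n_gray_levels = c(8L, 16L, 32L, 64L, 128L, 256L),
                       roi_kinds = c("noncystic", "entire_kidney"),
                       n_kidneys = 29L,
                       n_per_class = 68L,
                       n_sites = 7L,
                       folds = 5L,
                       repeats = 10L,
                       seed = NULL,
                       output_dir = tempfile("pkdradiomics_run_"),
                       target_matrix = 256L) {
  if (is.null(seed)) stop("run_config requires an explicit seed", call. = FALSE)
  structure(list(params = params, normalizations = normalizations,
                 resamplings = resamplings,
                 n_gray_levels = as.integer(n_gray_levels),
                 roi_kinds = roi_kinds, n_kidneys = as.integer(n_kidneys),
                 n_per_class = as.integer(n_per_class),
                 n_sites = as.integer(n_sites), folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 output_dir = output_dir,
                 target_matrix = as.integer(target_matrix)),
            class = "run_config")
}

#' Extract the wide feature store for a cohort over the design grid
#'
#' For every (normalization, resampling) arm the cohort is preprocessed,
#' the arm's cohort bin width is derived from the whole preprocessed images,
#' and the 93-feature vector is extracted per case, ROI kind, and bin
#' count.
#'
#' @param cohort List from [generate_cohort()].
#' @param normalizations,resamplings,n_gray_levels,roi_kinds The grid.
#' @param target_matrix Resize target in pixels.
#' @return Wide data frame (provenance columns + 93 feature columns); the
#'   per-arm discretization schemes are in the `"schemes"` attribute and
#'   per-row degenerate-feature counts in column `n_degenerate`.
#' @export
extract_feature_table <- function(cohort,
                                  normalizations = c("original", "zscore", "reference"),
                                  resamplings = c("up_1.0mm", "down_2.0mm"),
                                  n_gray_levels = c(8L, 16L, 32L, 64L, 128L, 256L),
                                  roi_kinds = c("noncystic", "entire_kidney"),
                                  target_matrix = 256L) {
  man <- cohort_manifest(cohort)
  feat_cols <- feature_name_manifest()$name
  vecs <- list()
  prov <- list()
  schemes <- list()
  for (norm in normalizations) {
    for (resamp in resamplings) {
      pre <- lapply(cohort, apply_preprocessing, normalization = norm,
                    resampling = resamp, target_matrix = target_matrix)
      scheme_ranges <- vapply(pre, function(p) diff(range(p$image)), numeric(1))
      for (nb in n_gray_levels) {
        scheme <- cohort_bin_width(NULL, nb, ranges = scheme_ranges)
        schemes[[paste(norm, resamp, nb, sep = "|")]] <-
          list(normalization = norm, resampling = resamp, n_bins = nb,
               range_mean = scheme$range_mean, bin_width = scheme$bin_width)
        for (ci in seq_len(nrow(man))) {
          for (roi in roi_kinds) {
            v <- extract_feature_vector(pre[[man$case_id[ci]]], roi, scheme)
            k <- length(vecs) + 1L
            vecs[[k]] <- unname(v)
            prov[[k]] <- data.frame(
              case_id = man$case_id[ci], class = man$class[ci],
              site = man$site[ci], roi_kind = roi, normalization = norm,
              resampling = resamp, n_gray_levels = as.integer(nb),
              n_degenerate = length(attr(v, "degenerate")),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  fm <- do.call(rbind, vecs)
  colnames(fm) <- feat_cols
  out <- cbind(do.call(rbind, prov),
               as.data.frame(fm, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "schemes") <- schemes
  out
}

#' Long-format view of a feature store
#'
#' @param feature_store Wide data frame from [extract_feature_table()].
#' @return Long data frame with columns case_id, class, site, roi_kind,
#'   normalization, resampling, n_gray_levels, feature, value.
#' @export
feature_table_long <- function(feature_store) {
  feat_cols <- feature_name_manifest()$name
  id_cols <- c("case_id", "class", "site", "roi_kind", "normalization",
               "resampling", "n_gray_levels")
  out <- do.call(rbind, lapply(feat_cols, function(f) {
    cbind(feature_store[, id_cols, drop = FALSE],
          data.frame(feature = f, value = feature_store[[f]],
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

subset_cohort <- function(cohort, case_ids) {
  man <- cohort_manifest(cohort)
  out <- cohort[case_ids]
  attr(out, "manifest") <- man[match(case_ids, man$case_id), , drop = FALSE]
  out
}

write_manifest <- function(config, extra, path) {
  man <- c(list(package = "pkdradiomics",
                seed = config$seed,
                normalizations = config$normalizations,
                resamplings = config$resamplings,
                n_gray_levels = config$n_gray_levels,
                roi_kinds = config$roi_kinds,
                folds = config$folds, repeats = config$repeats,
                target_matrix = config$target_matrix,
                interval = "95% normal-theory interval of the mean fold AUC"),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the reproducibility study on a phantom cohort
#'
#' Generates the reproducibility cohort (default 29 kidneys, one kidney per
#' case, single site), extracts the noncystic-parenchyma feature store over
#' the (normalization x resampling x gray-level) grid, and computes the ICC
#' report for the full rater set plus every pairwise normalization
#' comparison. Writes `icc_per_feature.csv`, `icc_fractions.csv`,
#' `icc_family_means.csv`, and `manifest_reproducibility.json` (which
#' records each arm's cohort bin width) under `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, list(cohort_manifest, feature_store, reports).
#' @export
run_reproducibility <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  full <- generate_cohort(config$params,
                          n_per_class = ceiling(config$n_kidneys / 2),
                          n_sites = 1L,
                          seed = derive_seed(config$seed, "repro_cohort"))
  keep <- cohort_manifest(full)$case_id[seq_len(config$n_kidneys)]
  cohort <- subset_cohort(full, keep)
  store <- extract_feature_table(cohort,
                                 normalizations = config$normalizations,
                                 resamplings = config$resamplings,
                                 n_gray_levels = config$n_gray_levels,
                                 roi_kinds = "noncystic",
                                 target_matrix = config$target_matrix)
  long <- feature_table_long(store)
  rater_sets <- c(list(config$normalizations),
                  if (length(config$normalizations) > 2L)
                    utils::combn(config$normalizations, 2L, simplify = FALSE))
  reports <- lapply(rater_sets, function(rs) reproducibility_study(long, rs))
  names(reports) <- vapply(rater_sets,
                           function(rs) paste(sort(rs), collapse = "+"),
                           character(1))
  per_feature <- do.call(rbind, lapply(reports, `[[`, "per_feature"))
  fractions <- do.call(rbind, lapply(reports, `[[`, "fractions"))
  fam_means <- do.call(rbind, lapply(reports, `[[`, "family_means"))
  rownames(per_feature) <- rownames(fractions) <- rownames(fam_means) <- NULL
  utils::write.csv(per_feature,
                   file.path(config$output_dir, "icc_per_feature.csv"),
                   row.names = FALSE)
  utils::write.csv(fractions,
                   file.path(config$output_dir, "icc_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(fam_means,
                   file.path(config$output_dir, "icc_family_means.csv"),
                   row.names = FALSE)
  write_manifest(config,
                 list(stage = "reproducibility",
                      n_kidneys = config$n_kidneys,
                      schemes = unname(attr(store, "schemes")),
                      n_degenerate_rows = sum(store$n_degenerate > 0)),
                 file.path(config$output_dir, "manifest_reproducibility.json"))
  invisible(list(cohort_manifest = cohort_manifest(cohort),
                 feature_store = store, reports = reports))
}

#' Run the genotype classification study on a phantom cohort
#'
#' Generates the classification cohort (default 136 subjects, 68 per class,
#' 7 sites), extracts the feature store for both ROI kinds over the grid,
#' and evaluates repeated cross-validated AUC per grid cell. Writes the
#' long grid (`auc_grid.csv`), shaped per-(ROI, resampling) tables with
#' rows = normalization and columns = gray levels
#' (`auc_table_<roi>_<resampling>.csv`), the per-cell selection frequencies
#' (`selection_counts.csv`), and `manifest_classification.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, list(cohort_manifest, feature_store, grid).
#' @export
run_classification <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$params, n_per_class = config$n_per_class,
                            n_sites = config$n_sites,
                            seed = derive_seed(config$seed, "class_cohort"))
  store <- extract_feature_table(cohort,
                                 normalizations = config$normalizations,
                                 resamplings = config$resamplings,
                                 n_gray_levels = config$n_gray_levels,
                                 roi_kinds = config$roi_kinds,
                                 target_matrix = config$target_matrix)
  expected <- expand.grid(roi_kind = config$roi_kinds,
                          normalization = config$normalizations,
                          resampling = config$resamplings,
                          n_gray_levels = config$n_gray_levels,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- auc_grid(store, folds = config$folds, repeats = config$repeats,
                   seed = derive_seed(config$seed, "cv"), expected = expected)
  utils::write.csv(grid, file.path(config$output_dir, "auc_grid.csv"),
                   row.names = FALSE)
  for (roi in unique(grid$roi_kind)) {
    for (resamp in unique(grid$resampling)) {
      sub <- grid[grid$roi_kind == roi & grid$resampling == resamp, ]
      tab <- tapply(sprintf("%.2f [%.2f, %.2f]", sub$mean_auc, sub$auc_low,
                            sub$auc_high),
                    list(sub$normalization, sub$n_gray_levels), identity)
      df <- data.frame(normalization = rownames(tab), tab, check.names = FALSE)
      utils::write.csv(df,
                       file.path(config$output_dir,
                                 sprintf("auc_table_%s_%s.csv", roi, resamp)),
                       row.names = FALSE)
    }
  }
  cv_results <- attr(grid, "cv_results")
  sel <- do.call(rbind, lapply(names(cv_results), function(key) {
    counts <- cv_results[[key]]$selection_counts
    data.frame(cell = key, feature = names(counts), count = as.integer(counts),
               stringsAsFactors = FALSE)
  }))
  sel <- sel[sel$count > 0, , drop = FALSE]
  rownames(sel) <- NULL
  utils::write.csv(sel, file.path(config$output_dir, "selection_counts.csv"),
                   row.names = FALSE)
  write_manifest(config,
                 list(stage = "classification",
                      n_per_class = config$n_per_class,
                      n_sites = config$n_sites,
                      schemes = unname(attr(store, "schemes"))),
                 file.path(config$output_dir, "manifest_classification.json"))
  invisible(list(cohort_manifest = cohort_manifest(cohort),
                 feature_store = store, grid = grid))
}

#' Validate a written phantom cohort directory
#'
#' Checks image/mask congruence, pixel-spacing sidecars, the mask subset and
#' disjointness invariants, and label balance, returning a machine-readable
#' problem list (zero rows when the directory is intact).
#'
#' @param dir Directory written by [write_cohort()].
#' @return Data frame with columns `case_id`, `problem`.
#' @export
validate_inputs <- function(dir) {
  problems <- list()
  note <- function(case_id, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      case_id = case_id, problem = problem, stringsAsFactors = FALSE)
  }
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    note("<cohort>", "manifest.csv is missing")
    return(do.call(rbind, problems))
  }
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    id <- man$case_id[i]
    stems <- paste0(id, c("_image.nii.gz", "_kidney.nii.gz", "_cyst.nii.gz",
                          "_psoas.nii.gz", ".json"))
    missing <- stems[!file.exists(file.path(dir, stems))]
    if (length(missing) > 0L) {
      note(id, paste("missing file(s):", paste(missing, collapse = ", ")))
      next
    }
    case <- tryCatch(read_phantom_case(dir, id), error = function(e) NULL)
    if (is.null(case)) {
      note(id, "unreadable case files")
      next
    }
    sp <- tryCatch(pixel_spacing(case$image), error = function(e) NA_real_)
    if (!is.finite(sp) || sp <= 0) note(id, "missing or invalid pixel spacing")
    for (mk in c("kidney_mask", "cyst_mask", "psoas_mask")) {
      if (!identical(dim(case[[mk]]), dim(case$image))) {
        note(id, sprintf("%s shape differs from image", mk))
      }
    }
    if (identical(dim(case$cyst_mask), dim(case$kidney_mask)) &&
        any(case$cyst_mask & !case$kidney_mask)) {
      note(id, "cyst mask extends outside kidney mask")
    }
    if (identical(dim(case$psoas_mask), dim(case$kidney_mask)) &&
        any(case$psoas_mask & case$kidney_mask)) {
      note(id, "psoas mask overlaps kidney mask")
    }
    if (!any(case$psoas_mask)) {
      note(id, "psoas mask is empty (reference normalization impossible)")
    }
    if (identical(dim(case$cyst_mask), dim(case$kidney_mask)) &&
        !any(case$kidney_mask & !case$cyst_mask)) {
      note(id, "noncystic ROI is empty")
    }
  }
  counts <- table(man$class)
  if (length(counts) == 2L && counts[1] != counts[2]) {
    note("<cohort>", sprintf("class imbalance: %s", paste(counts, collapse = " vs ")))
  }
  if (length(problems) == 0L) {
    return(data.frame(case_id = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  rownames(out) <- NULL
  out
}
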