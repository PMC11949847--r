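# End-to-end orchestration of the four-experiment design (product x
# modality x feature selection x classifier), plus file I/O helpers so a
# run can be persisted and reproduced from its configuration and seed.

#' Run the full grading pipeline on a synthetic dataset
#'
#' Simulates the dataset, extracts the e-nose (54-column) and image
#' (52-column) feature tables, fuses them (106 columns), and evaluates
#' every combination of modality (`enose`, `image`, `fused`), feature
#' selection (all features vs. CFS best-first subset), and classifier
#' specification, under the stratified 70/30 + 10-fold cross-validation
#' protocol.
#'
#' @param config A [synthetic_config()].
#' @param specs Named list of [classifier_spec()]s; defaults to one
#'   representative of each family (PUK-kernel SVM, K2 Bayesian network,
#'   reduced-error-pruned tree).
#' @param use_cfs Evaluate CFS-selected subsets in addition to the full
#'   tables (default `TRUE`).
#' @param split_seed Seed for the split/fold RNG (default `config$seed`).
#' @param out_dir Optional directory; when given, feature tables, the
#'   summary and the CFS selections are written there as CSV/JSON.
#' @return A list with `summary` (tibble: one row per modality x selection
#'   x classifier), `tables` (the three feature tables), `selections`
#'   (CFS results per modality), and `reports` (the evaluation reports).
#' @export
run_pipeline <- function(config, specs = NULL, use_cfs = TRUE,
                         split_seed = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  split_seed <- split_seed %||% config$seed
  specs <- specs %||% list(
    svm = classifier_spec("svm", kernel = "puk"),
    bayes_net = classifier_spec("bayes_net", bn_search = "k2"),
    tree = classifier_spec("tree", pruning = "reduced_error"))

  ds <- simulate_dataset(config)
  tab_enose <- enose_feature_table(ds$recordings, labels = ds$labels)
  tab_image <- image_feature_table(ds$images, labels = ds$labels)
  tab_fused <- fuse_features(tab_enose, tab_image)
  tables <- list(enose = tab_enose, image = tab_image, fused = tab_fused)

  selections <- if (use_cfs) lapply(tables, best_first_select) else NULL

  rows <- list()
  reports <- list()
  for (mod in names(tables)) {
    variants <- list(none = tables[[mod]])
    if (use_cfs) variants$cfs <- apply_selection(tables[[mod]], selections[[mod]])
    for (sel in names(variants)) {
      tab <- variants[[sel]]
      for (sp in names(specs)) {
        rep_ <- evaluate_classifier(specs[[sp]], tab, split_seed = split_seed)
        key <- paste(mod, sel, sp, sep = ".")
        reports[[key]] <- rep_
        rows[[key]] <- bind_cols(
          tibble(modality = mod,
                 selection = sel,
                 n_features = length(feature_names(tab))),
          glance(rep_))
      }
    }
  }
  summary <- bind_rows(rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mod in names(tables)) {
      utils::write.csv(tables[[mod]],
                       file.path(out_dir, paste0("features_", mod, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (use_cfs) {
      jsonlite::write_json(
        lapply(selections, function(s) {
          list(selected = s$selected, merit = s$merit,
               stop_reason = s$stop_reason)
        }),
        file.path(out_dir, "cfs_selections.json"), auto_unbox = TRUE)
    }
    jsonlite::write_json(
      list(seed = config$seed, split_seed = split_seed,
           product = config$product,
           n_samples_per_grade = config$n_samples_per_grade,
           noise_sd = config$noise_sd,
           n_features = vapply(tables, function(t) length(feature_names(t)),
                               integer(1))),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  }

  list(summary = summary, tables = tables, selections = selections,
       reports = reports)
}

# File I/O ------------------------------------------------------------------

#' Write a simulated dataset to disk
#'
#' Recordings are written as CSV (`time` column plus one column per
#' sensor), images as PNG (requires the `png` package), and a manifest CSV
#' (`sample_id, grade, recording_path, image_path`) ties them together.
#'
#' @param dataset A dataset from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  has_png <- requireNamespace("png", quietly = TRUE)
  if (!has_png) warn("Package `png` not installed; skipping image files.")
  n <- nrow(dataset$labels)
  rec_paths <- character(n)
  img_paths <- character(n)
  for (i in seq_len(n)) {
    id <- dataset$labels$sample_id[i]
    rec_paths[i] <- file.path(dir, paste0(id, "_enose.csv"))
    utils::write.csv(as.data.frame(dataset$recordings[[i]]), rec_paths[i],
                     row.names = FALSE)
    if (has_png) {
      img_paths[i] <- file.path(dir, paste0(id, ".png"))
      png::writePNG(unclass(dataset$images[[i]]), img_paths[i])
    } else {
      img_paths[i] <- NA_character_
    }
  }
  manifest <- bind_cols(dataset$labels,
                        tibble(recording_path = rec_paths,
                               image_path = img_paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an e-nose recording CSV
#'
#' Expects the dialect written by [write_dataset()]: a `time` column in
#' seconds plus one voltage column per sensor.
#'
#' @param path CSV path.
#' @param grade Optional grade label to attach.
#' @param phase_boundaries End times (seconds) of the baseline, injection
#'   and recovery phases (default `c(200, 240, 300)`).
#' @return An `enose_recording` tibble.
#' @export
read_enose_csv <- function(path, grade = NULL,
                           phase_boundaries = c(200, 240, 300)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) abort("Recording CSV must have a `time` column.")
  out <- as_tibble(df)
  structure(out,
            class = c("enose_recording", class(out)),
            grade = grade,
            phase_boundaries = phase_boundaries,
            sensors = setdiff(names(out), "time"))
}
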