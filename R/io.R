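#' Write spectra as per-spectrum delimited text files
#'
#' One tab-delimited file per spectrum with columns `channel`,
#' `wavenumber_cm-1`, `intensity`, plus a `labels.csv` with the
#' per-spectrum metadata.
#'
#' @param x A spectra tibble.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_spectra_txt <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- unstack_spectra(x)
  for (i in seq_along(u$ids)) {
    d <- data.frame(channel = u$channel,
                    `wavenumber_cm-1` = u$wavenumber,
                    intensity = u$X[i, ], check.names = FALSE)
    write.table(d, file.path(dir, paste0(u$ids[i], ".txt")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.csv(u$meta, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write spectra as a single matrix bundle
#'
#' A compact serialized container holding the axis, the intensity
#' matrix, and the metadata table; the fast counterpart of the
#' per-spectrum text format.
#'
#' @param x A spectra tibble.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_spectra_bundle <- function(x, path) {
  saveRDS(unstack_spectra(x), path, version = 3)
  invisible(path)
}

#' Read spectra from a bundle or a directory of delimited text files
#'
#' Accepts either a matrix bundle written by [write_spectra_bundle()] or
#' a directory of per-spectrum text files with a `labels.csv`, as written
#' by [write_spectra_txt()]. Axes are validated (equal length, strictly
#' increasing); non-numeric cells and ragged files raise errors naming
#' the offending file, row and column.
#'
#' @param path Bundle file or directory.
#' @return A spectra tibble.
#' @export
read_spectra <- function(path) {
  if (dir.exists(path)) return(read_spectra_dir(path))
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  u <- readRDS(path)
  out <- restack_spectra(u)
  validate_spectra(out)
  out
}

read_spectra_dir <- function(path) {
  label_file <- file.path(path, "labels.csv")
  if (!file.exists(label_file)) {
    abort("missing labels: no `labels.csv` in the spectra directory.")
  }
  meta <- as_tibble(read.csv(label_file, check.names = FALSE))
  if (!"id" %in% names(meta)) abort("labels.csv must have an `id` column.")
  files <- file.path(path, paste0(meta$id, ".txt"))
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(paste0("missing spectrum file(s): ",
                 paste(basename(files[missing]), collapse = ", ")))
  }
  parts <- lapply(seq_along(files), function(i) {
    d <- read.table(files[i], header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
    num <- suppressWarnings(vapply(d, as.numeric, numeric(nrow(d))))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      abort(paste0("non-numeric cell in ", basename(files[i]), " at row ",
                   bad[1], ", column `", colnames(num)[bad[2]], "`."))
    }
    tibble(id = meta$id[i], channel = as.integer(num[, "channel"]),
           wavenumber = num[, "wavenumber_cm-1"],
           intensity = num[, "intensity"])
  })
  out <- dplyr::bind_rows(parts)
  out <- dplyr::left_join(out, meta, by = "id")
  validate_spectra(out)
  out
}

#' Workflow configuration
#'
#' Bundles the per-stage parameters of the full analysis; all stage
#' seeds are derived from one master seed by stable hashing, so the
#' whole run is reproducible while stages stay independent.
#'
#' @param master_seed Master seed.
#' @param n_per_class Spectra per class per batch.
#' @param classes Class profiles ([default_class_profiles()] by default).
#' @param axis Wavenumber axis.
#' @param pipeline A [pipeline_config()].
#' @param n_pbs PBS reference acquisitions per batch.
#' @param dra_bin_size DRA bin width (cm^-1).
#' @param n_lv PLSDA latent variables.
#' @param cv_splits Venetian-blinds folds.
#' @param btem_targets BTEM band targets.
#' @param btem_restarts Simulated-annealing restarts per target.
#' @param sa Simulated-annealing schedule ([sa_config()]).
#' @return A `run_config` list.
#' @export
run_config <- function(master_seed = 1, n_per_class = 100,
                       classes = default_class_profiles(),
                       axis = wavenumber_axis(),
                       pipeline = pipeline_config(),
                       n_pbs = 200, dra_bin_size = 50, n_lv = 3,
                       cv_splits = 10,
                       btem_targets = default_band_targets(),
                       btem_restarts = 10, sa = sa_config()) {
  structure(list(master_seed = as.integer(master_seed),
                 n_per_class = n_per_class, classes = classes, axis = axis,
                 pipeline = pipeline, n_pbs = n_pbs,
                 dra_bin_size = dra_bin_size, n_lv = n_lv,
                 cv_splits = cv_splits, btem_targets = btem_targets,
                 btem_restarts = btem_restarts, sa = sa),
            class = "run_config")
}

# Stable config fingerprint for provenance lines in output files.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 3)
  unname(tools::md5sum(tmp))
}

#' Read / write a workflow configuration as YAML
#'
#' Scalar stage parameters round-trip through YAML; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("master_seed", "n_per_class", "n_pbs", "dra_bin_size",
             "n_lv", "cv_splits", "btem_restarts", "n_channels",
             "axis_range", "classes")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  axis <- wavenumber_axis(raw$n_channels %||% 1024,
                          raw$axis_range %||% c(600, 1800))
  classes <- if (is.null(raw$classes)) default_class_profiles() else {
    lapply(raw$classes, function(cl) {
      class_profile(cl$name, unlist(cl$mean_weights),
                    cl$weight_dispersion %||% 1000,
                    cl$snr %||% 25, cl$spike_rate %||% 0.05)
    })
  }
  run_config(master_seed = raw$master_seed %||% 1,
             n_per_class = raw$n_per_class %||% 100,
             classes = classes, axis = axis,
             n_pbs = raw$n_pbs %||% 200,
             dra_bin_size = raw$dra_bin_size %||% 50,
             n_lv = raw$n_lv %||% 3, cv_splits = raw$cv_splits %||% 10,
             btem_restarts = raw$btem_restarts %||% 10)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    master_seed = config$master_seed, n_per_class = config$n_per_class,
    n_pbs = config$n_pbs, dra_bin_size = config$dra_bin_size,
    n_lv = config$n_lv, cv_splits = config$cv_splits,
    btem_restarts = config$btem_restarts,
    n_channels = nrow(config$axis),
    axis_range = as.numeric(range(config$axis$wavenumber)),
    classes = lapply(config$classes, function(cl) list(
      name = cl$class_name, mean_weights = as.list(cl$mean_weights),
      weight_dispersion = cl$weight_dispersion, snr = cl$snr,
      spike_rate = cl$spike_rate))
  ), path)
  invisible(path)
}

#' Run the full analysis workflow
#'
#' Simulate two isolation batches plus PBS references and a response
#' curve; preprocess; build the class-mean DRA; cross-validate a PLSDA
#' model on batch I and predict batch II; recover the four pure
#' biomolecular components by BTEM from the pooled batch-I spectra; and
#' estimate convex-mixing abundances with a class-level summary. All
#' tabular artifacts are written as CSV/JSON under `out_dir`, each
#' carrying the configuration hash for provenance, together with a
#' line-oriented `run.log`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results
#'   (`data_i`, `data_ii`, `dra`, `cv`, `prediction`, `components`,
#'   `abundances`, `summary`).
#' @export
run_workflow <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$pipeline$pbs_fraction) && config$n_pbs < 1) {
    abort("configuration error: PBS subtraction enabled but no PBS references.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", file = logf, append = TRUE, sep = "")
  cat("config_hash: ", hash, "\n", file = logf, sep = "")

  stage_seed <- function(stage) derive_seed(config$master_seed, stage)
  write_artifact <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }

  curve <- synthetic_response_curve(config$axis$wavenumber)
  sim_batch <- function(batch) {
    cfg <- sim_config(config$classes, config$axis, config$n_per_class,
                      seed = stage_seed(paste0("simulate_", batch)),
                      batch = batch)
    generate_dataset(cfg)
  }
  log_line("stage simulate: seed_I=", stage_seed("simulate_I"),
           " seed_II=", stage_seed("simulate_II"))
  data_i <- sim_batch("I")
  data_ii <- sim_batch("II")
  pbs_i <- generate_pbs_reference(config$axis, config$n_pbs,
                                  seed = stage_seed("pbs_I"))
  pbs_ii <- generate_pbs_reference(config$axis, config$n_pbs,
                                   seed = stage_seed("pbs_II"))

  log_line("stage preprocess")
  proc_i <- preprocess_pipeline(data_i, pbs_i, curve, config$pipeline)
  proc_ii <- preprocess_pipeline(data_ii, pbs_ii, curve, config$pipeline)

  log_line("stage dra: bin=", config$dra_bin_size)
  dra <- build_dra(proc_i, bin_size = config$dra_bin_size, rows = "class")
  write_dra_csv(dra, file.path(out_dir, "dra.csv"))

  log_line("stage plsda: n_lv=", config$n_lv, " splits=", config$cv_splits)
  cv <- cross_validate(proc_i, n_lv = config$n_lv,
                       splits = config$cv_splits)
  model <- fit_plsda(proc_i, n_lv = config$n_lv)
  pred <- predict(model, proc_ii)
  write_artifact(cv$report$metrics, "cv_report.csv")
  write_artifact(pred$report$metrics, "prediction_report.csv")

  log_line("stage btem: restarts=", config$btem_restarts)
  btem_cfg <- pipeline_config(sg_frame = NULL, normalize = FALSE)
  btem_in <- preprocess_pipeline(data_i, pbs_i, curve, btem_cfg)
  comps <- recover_components(btem_in, config$btem_targets,
                              seed = stage_seed("btem"),
                              n_restarts = config$btem_restarts,
                              control = config$sa)
  write_artifact(dplyr::bind_rows(lapply(comps, tidy.pure_component)),
                 "components.csv")

  log_line("stage abundance")
  ab <- fit_abundances(btem_in, comps)
  summ <- summarize_composition(ab)
  write_artifact(ab, "abundances.csv")
  write_artifact(summ$means, "composition_means.csv")

  jsonlite::write_json(
    list(config_hash = hash, master_seed = config$master_seed,
         stages = c("simulate", "preprocess", "dra", "plsda", "btem",
                    "abundance"),
         artifact_md5 = {
           files <- list.files(out_dir, pattern = "\\.csv$",
                               full.names = TRUE)
           setNames(as.list(unname(tools::md5sum(files))), basename(files))
         }),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(list(data_i = data_i, data_ii = data_ii, dra = dra, cv = cv,
                 prediction = pred, components = comps, abundances = ab,
                 summary = summ))
}
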