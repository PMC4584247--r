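# End-to-end study orchestration: generate -> preprocess -> partition ->
# random frog -> fit -> map, from one config with a single master seed and
# a machine-readable manifest.

#' Default pipeline configuration
#'
#' Returns the full study configuration as a nested list; every field can
#' be overridden by the `...` arguments (shallow merge per section) or by
#' loading a YAML file with [load_pipeline_config()]. The defaults run the
#' production-scale study: 310 samples, a 512-band 380-1030 nm grid
#' cropped to 420-1000 nm, a 235:75 SPXY split, Random Frog at T
#' iterations with Q = 50, and PLSR / LS-SVM models on the full band set
#' and on each SP cut-off subset.
#'
#' @param ... named sections (`samples`, `grid`, `crop`, `mask`, `split`,
#'   `frog`, `models`, `cutoffs`, `map`, `seed`) overriding the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    samples = list(n_samples = 310L, blobs_per_capture = 6L,
                   rows = 96L, cols = 96L, blob_radius = 7L),
    grid = list(n_bands = 512L, lo_nm = 380, hi_nm = 1030),
    crop = list(lo_nm = 420, hi_nm = 1000),
    mask = list(band_a_nm = 893, band_b_nm = 569, threshold = 0.4),
    split = list(n_calibration = 235L),
    frog = list(T = 10000L, Q = 50L, theta = 0.3, omega = 3, eta = 0.1,
                n_lv_max = 10L, cv_folds = 5L),
    cutoffs = c(0.7, 0.85),
    models = list(lv_max = 20L, families = c("plsr", "lssvm-linear", "lssvm-rbf"),
                  gamma_grid = 10^seq(0, 9, length.out = 13),
                  sigma2_grid = 10^seq(-2, 6, length.out = 17)),
    map = list(denoise = TRUE, range = c(3, 11))
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   sections.
#' @return a `pipeline_config` list (defaults filled in for absent keys).
#' @export
load_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the end-to-end study
#'
#' Executes every stage on seeded synthetic data and writes all artifacts
#' under `out_dir`: the spectra table (`spectra.csv`), split indices
#' (`split.csv`), selection probabilities (`sp.csv`), the selected
#' wavelengths per cut-off (`selected_cutoff_*.csv`), fitted-model
#' summaries with the calibration / cross-validation / prediction metrics
#' table (`metrics.csv`, one row per model like a model-comparison table),
#' serialized models (`model_*.json`), one chemical map with statistics
#' (`map_sample_stats.csv`, `map.png`), and `manifest.json` recording
#' package version, seeds and all parameters.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with the run artifacts: the spectra table,
#'   split, frog result, selected sets, fitted models, metrics data.frame
#'   and the manifest, plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("hsitss_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- generate + preprocess ---------------------------------------------
  grid <- make_wavelength_grid(config$grid$n_bands, config$grid$lo_nm,
                               config$grid$hi_nm)
  geometry <- capture_geometry(rows = config$samples$rows,
                               cols = config$samples$cols,
                               blob_radius = config$samples$blob_radius,
                               n_blobs = config$samples$blobs_per_capture)
  table <- stage("generate", simulate_spectra_table(
    n_samples = config$samples$n_samples, grid = grid, seed = seeds[1],
    blobs_per_capture = config$samples$blobs_per_capture,
    geometry = geometry, crop = c(config$crop$lo_nm, config$crop$hi_nm)))
  write_num_csv(data.frame(sample_id = table$sample_ids,
                           tss_brix = table$y), file.path(out_dir, "tss.csv"))
  spectra_df <- data.frame(sample_id = table$sample_ids, table$X)
  names(spectra_df)[-1] <- sprintf("nm%.2f", table$grid)
  write_num_csv(spectra_df, file.path(out_dir, "spectra.csv"))

  # -- partition ----------------------------------------------------------
  split <- stage("partition", spxy_split(table, config$split$n_calibration))
  write_num_csv(data.frame(
    sample_id = table$sample_ids,
    set = ifelse(seq_along(table$y) %in% split$calibration,
                 "calibration", "prediction")),
    file.path(out_dir, "split.csv"))
  cal <- subset_table(table, split$calibration)
  prd <- subset_table(table, split$prediction)

  # -- random frog ---------------------------------------------------------
  fp <- frog_params(T = config$frog$T, Q = config$frog$Q,
                    theta = config$frog$theta, omega = config$frog$omega,
                    eta = config$frog$eta, n_lv_max = config$frog$n_lv_max,
                    cv_folds = config$frog$cv_folds, seed = seeds[2])
  frog <- stage("random_frog", run_random_frog(cal, fp))
  write_num_csv(data.frame(wavelength = frog$wavelength, sp = frog$sp),
                file.path(out_dir, "sp.csv"))
  selected <- lapply(config$cutoffs, function(co) select_by_cutoff(frog, cutoff = co))
  names(selected) <- sprintf("cutoff_%g", config$cutoffs)
  for (nm in names(selected)) {
    write_num_csv(selected[[nm]], file.path(out_dir, sprintf("selected_%s.csv", nm)))
  }

  # -- models ---------------------------------------------------------------
  band_sets <- c(list(full = seq_along(table$grid)),
                 lapply(selected, function(s) sort(s$band)))
  band_sets <- Filter(function(b) length(b) >= 1, band_sets)
  models <- list()
  metrics <- NULL
  for (set_name in names(band_sets)) {
    bands <- band_sets[[set_name]]
    Xc <- cal$X[, bands, drop = FALSE]
    Xp <- prd$X[, bands, drop = FALSE]
    wl <- table$grid[bands]
    for (family in config$models$families) {
      key <- sprintf("%s_%s", family, set_name)
      fit <- stage(key, {
        if (family == "plsr") {
          lv <- select_plsr_lv(Xc, cal$y, lv_max = config$models$lv_max)
          m <- fit_plsr(Xc, cal$y, n_lv = lv$n_lv, wavelengths = wl)
          list(model = m, cv_pred = lv$predictions,
               extra = data.frame(n_lv = lv$n_lv, gamma = NA, sigma2 = NA))
        } else {
          kernel <- if (family == "lssvm-rbf") "rbf" else "linear"
          gs <- grid_search_lssvm(Xc, cal$y, kernel = kernel,
                                  gamma_grid = config$models$gamma_grid,
                                  sigma2_grid = config$models$sigma2_grid)
          m <- fit_lssvm(Xc, cal$y, kernel = kernel, gamma = gs$gamma,
                         sigma2 = gs$sigma2, wavelengths = wl)
          cv <- loo_cv(Xc, cal$y, function(X, y) {
            fit_lssvm(X, y, kernel = kernel, gamma = gs$gamma,
                      sigma2 = gs$sigma2)
          })
          list(model = m, cv_pred = cv$predictions,
               extra = data.frame(n_lv = NA, gamma = gs$gamma,
                                  sigma2 = if (is.null(gs$sigma2)) NA else gs$sigma2))
        }
      })
      rep_ <- metrics_report(fit$model, Xc, cal$y, Xp, prd$y, fit$cv_pred)
      models[[key]] <- fit$model
      metrics <- rbind(metrics, cbind(
        data.frame(model = family, bands = set_name,
                   n_wavelengths = length(bands)),
        fit$extra, as.data.frame(rep_)))
      serialize_model(fit$model, file.path(out_dir, sprintf("model_%s.json", key)))
    }
  }
  write_num_csv(metrics, file.path(out_dir, "metrics.csv"))

  # -- chemical map of a fresh capture --------------------------------------
  map_tss <- draw_tss_values(config$samples$blobs_per_capture, seeds[3])
  capture <- stage("map_capture", render_capture(
    map_tss, grid, geometry, seed = seeds[4]))
  refl <- crop_bands(calibrate_reflectance(capture$raw, capture$white,
                                           capture$dark),
                     config$crop$lo_nm, config$crop$hi_nm)
  mask <- build_mask(refl, config$mask$band_a_nm, config$mask$band_b_nm,
                     config$mask$threshold)
  map_model_key <- sprintf("plsr_%s",
                           if (length(band_sets) > 1) names(band_sets)[2] else "full")
  map_model <- models[[map_model_key]]
  if (is.null(map_model)) map_model <- models[[1]]
  sat <- saturation_flags(capture$raw, capture$full_scale,
                          map_model$wavelengths)
  map <- stage("map", predict_map(refl, mask, map_model,
                                  denoise = config$map$denoise,
                                  saturated = sat))
  stats_df <- do.call(rbind, lapply(seq_along(capture$footprints), function(i) {
    s <- map_stats(map, capture$footprints[[i]])
    data.frame(sample = i, truth_tss = capture$truth_tss[i],
               mean = s[["mean"]], min = s[["min"]], max = s[["max"]],
               n_pixels = s[["n_pixels"]])
  }))
  write_num_csv(stats_df, file.path(out_dir, "map_sample_stats.csv"))
  rgb <- render_pseudocolour(map, config$map$range[1], config$map$range[2])
  write_image_png(rgb, file.path(out_dir, "map.png"))

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "hsitss",
    version = as.character(utils::packageVersion("hsitss")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$seed,
    stage_seeds = list(generate = seeds[1], frog = seeds[2],
                       map_tss = seeds[3], map_capture = seeds[4]),
    config = unclass(config),
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(table = table, split = split, frog = frog,
                 selected = selected, models = models, metrics = metrics,
                 map = map, manifest = manifest, out_dir = out_dir))
}

#' Serialize a fitted model to JSON
#'
#' PLSR and multilinear models serialize as coefficient vector + intercept
#' + wavelengths; LS-SVM models as dual coefficients, bias, kernel spec
#' and support inputs.
#'
#' @param model a `plsr_model`, `lssvm_model` or `multilinear_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  obj <- if (inherits(model, "plsr_model")) {
    list(type = "plsr", n_lv = model$n_lv,
         intercept = model$intercept, coefficients = model$coefficients,
         wavelengths = model$wavelengths)
  } else if (inherits(model, "lssvm_model")) {
    list(type = "lssvm", kernel = model$kernel, gamma = model$gamma,
         sigma2 = model$sigma2, b = model$b, alpha = model$alpha,
         support_inputs = model$X, wavelengths = model$wavelengths)
  } else if (inherits(model, "multilinear_model")) {
    list(type = "multilinear", intercept = model$intercept,
         coefficients = model$coefficients, wavelengths = model$wavelengths)
  } else stop_invalid("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a model written by [serialize_model()]
#'
#' @param path JSON file.
#' @return the reconstructed model object (prediction-capable; PLSR models
#'   reload as plain multilinear predictors).
#' @export
deserialize_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    plsr = ,
    multilinear = structure(
      list(intercept = obj$intercept,
           coefficients = as.numeric(obj$coefficients),
           wavelengths = obj$wavelengths),
      class = "multilinear_model"),
    lssvm = structure(
      list(alpha = as.numeric(obj$alpha), b = obj$b, kernel = obj$kernel,
           gamma = obj$gamma, sigma2 = obj$sigma2,
           X = as.matrix(obj$support_inputs), y = NULL,
           wavelengths = obj$wavelengths),
      class = "lssvm_model"),
    stop_invalid("unknown model type '%s'", obj$type))
}
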