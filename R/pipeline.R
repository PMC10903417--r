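# End-to-end orchestration: simulate -> train -> predict -> evaluate ->
# profile -> report, with a manifest recording seeds, versions and the
# configuration hash.

run_config_schema <- function() {
  list(
    phantom = names(formals(phantom_params)),
    generator = names(formals(generator_config)),
    discriminator = names(formals(discriminator_config)),
    train = names(formals(train_config)),
    profiling = names(formals(profiling_params)),
    data = c("n_train", "n_val"),
    output = c("dir", "write_predictions")
  )
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Each section is passed to the
#' corresponding constructor ([phantom_params()], [generator_config()],
#' [discriminator_config()], [train_config()], [profiling_params()]);
#' unknown sections or keys are rejected before any computation. The
#' defaults are a demonstration scale (small fields, few epochs) that runs
#' in minutes on one CPU.
#'
#' @param ... named sections overriding the defaults, e.g.
#'   `train = list(epochs = 50)`.
#' @return validated nested configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  config <- list(
    phantom = list(field_size = 64L, n_cells = 1L, cell_radius = 22,
                   nucleus_radius = 7, droplets_per_cell = 5L,
                   r_large_median = 8, seed = 1L),
    generator = list(),
    discriminator = list(),
    train = list(epochs = 30L, val_every = 5L, seed = 1L),
    profiling = list(),
    data = list(n_train = 24L, n_val = 6L),
    output = list(dir = "virtualstain-run", write_predictions = TRUE)
  )
  schema <- run_config_schema()
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(schema)) {
      stop("unknown config section: ", sec, call. = FALSE)
    }
    for (key in names(over[[sec]])) {
      if (!key %in% schema[[sec]]) {
        stop(sprintf("unknown key '%s' in config section '%s'", key, sec),
             call. = FALSE)
      }
      config[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  structure(config, class = "run_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose top-level structure mirrors [run_config()].
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  message(sprintf("[%s] started", name))
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done (%.1f s)", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full virtual-staining pipeline
#'
#' Executes simulate, train, predict, evaluate, profile and report on a
#' synthetic phantom dataset, writing every intermediate artifact (paired
#' TIFFs, training history, predicted stainings, metric and feature
#' tables, comparison report) plus a manifest into the output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the fitted model, the metric report and
#'   the comparison report; artifacts under `config$output$dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  pp <- do.call(phantom_params, config$phantom)
  message(sprintf("pipeline start: seed %s, config %s",
                  format(pp$seed), cfg_hash))

  data_dir <- file.path(out_dir, "data")
  n_total <- config$data$n_train + config$data$n_val
  index <- stage("simulate", {
    make_dataset(n_total, pp, data_dir,
                 val_fraction = config$data$n_val / n_total)
  })
  train_pairs <- stage("load", load_split(data_dir, "train"))
  val_pairs <- load_split(data_dir, "val")

  gen_cfg <- do.call(generator_config, c(
    list(in_channels = pp$n_slices), config$generator))
  disc_cfg <- do.call(discriminator_config, c(
    list(in_channels = pp$n_slices + gen_cfg$out_channels),
    config$discriminator))
  tr_cfg <- do.call(train_config, config$train)
  fit <- stage("train", fit_cgan(train_pairs, val_pairs, gen_cfg, disc_cfg,
                                 tr_cfg))
  write.csv(fit$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  write.csv(fit$val_history, file.path(out_dir, "val_history.csv"),
            row.names = FALSE)
  save_model(fit, file.path(out_dir, "cgan.rds"))

  preds <- stage("predict", lapply(val_pairs, function(p) predict(fit, p)))
  if (isTRUE(config$output$write_predictions)) {
    for (i in seq_along(preds)) {
      write_stack_tiff(round(preds[[i]] * 65535),
                       file.path(out_dir, sprintf("pred_%04d.tif", i)))
    }
  }

  metrics <- stage("evaluate", {
    evaluate_set(preds, lapply(val_pairs, `[[`, "y"))
  })
  write.csv(metrics$per_image, file.path(out_dir, "metrics_per_image.csv"),
            row.names = FALSE)
  write.csv(metrics$summary, file.path(out_dir, "metrics_summary.csv"),
            row.names = FALSE)

  prof_par <- do.call(profiling_params, config$profiling)
  feats <- stage("profile", {
    ft <- do.call(rbind, lapply(seq_along(val_pairs), function(i) {
      profile_image(val_pairs[[i]]$y, prof_par,
                    image_id = val_pairs[[i]]$id)$features
    }))
    fp <- do.call(rbind, lapply(seq_along(preds), function(i) {
      profile_image(preds[[i]], prof_par,
                    image_id = val_pairs[[i]]$id)$features
    }))
    list(target = ft, pred = fp)
  })
  write.csv(feats$target, file.path(out_dir, "features_target.csv"),
            row.names = FALSE)
  write.csv(feats$pred, file.path(out_dir, "features_pred.csv"),
            row.names = FALSE)

  report <- stage("report", {
    suppressWarnings(build_report(feats$pred, feats$target))
  })
  write.csv(report$table, file.path(out_dir, "report.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$table, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- list.files(out_dir, recursive = TRUE)
  manifest <- list(
    package = "virtualstain",
    package_version = as.character(utils::packageVersion("virtualstain")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = pp$seed,
    config_hash = cfg_hash,
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, metrics = metrics, report = report,
                 index = index))
}
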