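# Seeded end-to-end orchestration: simulate -> preprocess (censor) ->
# train/evaluate (LOSO) -> LR baseline -> saliency quantification -> report.

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations under one master seed. Any stage can
#' be toggled; later stages require earlier ones (or their cached outputs).
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param out_dir output directory (created on demand); `NULL` disables all
#'   file output and caching.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param net an [eegnet_config()].
#' @param train a [train_config()]; its seed is overridden by `seed`.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "train", "baseline", "saliency")`.
#' @param electrode,window_width,window_step,statistic saliency analysis
#'   options.
#' @param feature_window LR baseline feature window (ms).
#' @param resume reuse cached stage outputs when config hash matches?
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       sim = sim_config(),
                       net = eegnet_config(),
                       train = train_config(),
                       stages = c("simulate", "preprocess", "train",
                                  "baseline", "saliency"),
                       electrode = "Pz", window_width = 100, window_step = 5,
                       statistic = "mean", feature_window = c(350, 400),
                       resume = TRUE) {
  sim$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 net = net, train = train, stages = stages,
                 electrode = electrode, window_width = window_width,
                 window_step = window_step, statistic = statistic,
                 feature_window = feature_window, resume = resume),
            class = "run_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

cache_path <- function(cfg, stage, hash) {
  if (is.null(cfg$out_dir)) return(NULL)
  file.path(cfg$out_dir, "cache", paste0(stage, "-", hash, ".rds"))
}

run_stage <- function(cfg, stage, hash, fun) {
  path <- cache_path(cfg, stage, hash)
  if (!is.null(path) && cfg$resume && file.exists(path)) {
    message(sprintf("[%s] reusing cached output", stage))
    return(readRDS(path))
  }
  t0 <- Sys.time()
  out <- fun()
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    saveRDS(out, path, version = 2)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and assembles a run report with the
#' evaluation tables (network and baseline LOSO metrics, their comparison),
#' the saliency quantifications (spatial/temporal profiles, per-session
#' most-varied intervals, session trends per scenario), the Pz ERP component
#' statistics, and provenance (config hash, seed). Identical config + seed
#' reproduce identical reports.
#'
#' @param cfg a [run_config()].
#' @return an object of class `run_report` (a list of tables); if
#'   `cfg$out_dir` is set, tables are also written as TSV and the report as
#'   JSON.
#' @export
run_pipeline <- function(cfg = run_config()) {
  hash <- config_hash(cfg[setdiff(names(cfg), c("out_dir", "resume"))])
  report <- list(provenance = list(
    seed = cfg$seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("p300net")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  stages <- cfg$stages

  need <- function(stage, value)
    if (is.null(value)) stopf("stage '%s' needs an upstream artifact that is missing (enable the earlier stage or provide a cache)", stage)

  raw <- NULL
  if ("simulate" %in% stages)
    raw <- run_stage(cfg, "simulate", hash, function() generate_dataset(cfg$sim))

  ds <- NULL
  if ("preprocess" %in% stages) {
    need("preprocess", raw)
    ds <- run_stage(cfg, "preprocess", hash, function() censor_adjacent(raw))
  }

  loso <- NULL
  if ("train" %in% stages) {
    need("train", ds)
    loso <- run_stage(cfg, "train", hash, function()
      evaluate_loso(ds, cfg$net, cfg$train))
    report$cnn_per_cell <- loso$per_cell
    report$cnn_per_subject <- loso$per_subject
    for (sc in unique(loso$per_cell$scenario))
      report[[paste0("cnn_table_", gsub("[^a-z]", "_", sc))]] <-
        accuracy_table(loso$per_cell, sc)
  }

  if ("baseline" %in% stages) {
    need("baseline", ds)
    lr <- run_stage(cfg, "baseline", hash, function()
      lr_evaluate_loso(ds, cfg$feature_window))
    report$lr_per_cell <- lr$per_cell
    report$lr_per_subject <- lr$per_subject
    if (!is.null(loso)) {
      cmp <- compare_models(loso$per_subject$accuracy, lr$per_subject$accuracy)
      report$model_comparison <- data.frame(
        t = cmp$t, df = cmp$df, p = cmp$p,
        cnn_mean = cmp$mean_a, lr_mean = cmp$mean_b)
    }
  }

  if ("saliency" %in% stages) {
    need("saliency", loso)
    sal <- run_stage(cfg, "saliency", hash, function() {
      subjects <- sort(unique(ds$meta$subject))
      maps <- list(); ivs <- list()
      for (s in subjects) {
        model <- loso$models[[as.character(s)]]
        held <- epochs_subset(ds, ds$meta$subject == s & ds$labels == 1L)
        maps[[length(maps) + 1L]] <- compute_saliency(model, held)
        ivs[[length(ivs) + 1L]] <- cbind(
          subject = s,
          session_intervals(model, epochs_subset(ds, ds$meta$subject == s),
                            cfg$electrode, cfg$window_width, cfg$window_step,
                            cfg$statistic))
      }
      list(grand = average_maps(maps), intervals = do.call(rbind, ivs))
    })
    grand <- sal$grand
    report$spatial_profile <- data.frame(
      electrode = grand$layout$names, value = unname(spatial_profile(grand)))
    report$temporal_profile <- temporal_profile(grand)
    agg <- aggregate(center ~ scenario + session, sal$intervals, mean)
    report$session_intervals <- sal$intervals
    trends <- lapply(split(agg, agg$scenario), function(d) {
      if (nrow(d) < 3 || sd(d$center) == 0)   # trend undefined: flagged NA
        return(data.frame(scenario = d$scenario[1], r = NA_real_,
                          p = NA_real_, n = nrow(d)))
      tr <- latency_trend(d$center[order(d$session)], sort(d$session))
      data.frame(scenario = d$scenario[1], r = tr$r, p = tr$p, n = tr$n)
    })
    report$latency_trends <- do.call(rbind, trends)

    # conventional ERP check at the analysis electrode
    erp_rows <- list()
    for (sc in unique(ds$meta$scenario)) {
      for (lab in c(1L, 0L)) {
        ga <- grand_average(ds, cfg$electrode,
                            ds$meta$scenario == sc & ds$labels == lab)
        for (comp in c("P200", "P300")) {
          cm <- component_amplitude(ga, comp)
          erp_rows[[length(erp_rows) + 1L]] <- data.frame(
            scenario = sc, condition = if (lab == 1L) "target" else "standard",
            component = comp, value = cm$value, latency = cm$latency,
            n = attr(ga, "n_trials"))
        }
      }
    }
    report$erp_components <- do.call(rbind, erp_rows)
  }

  report$checks <- pipeline_checks(raw, ds, report)
  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

pipeline_checks <- function(raw, ds, report) {
  checks <- list()
  if (!is.null(raw)) {
    tab <- table(raw$labels)
    checks$label_ratio_1_to_7 <- unname(tab["0"] / tab["1"]) == 7
    checks$epoch_shape_8x201 <- all(dim(raw$data)[2:3] == c(8L, 201L))
  }
  if (!is.null(ds))
    checks$censoring_kept_targets <-
      sum(ds$labels == 1L) == (if (!is.null(raw)) sum(raw$labels == 1L) else NA)
  if (!is.null(report$cnn_per_subject))
    checks$metrics_in_range <-
      all(report$cnn_per_subject$accuracy >= 0 & report$cnn_per_subject$accuracy <= 100)
  checks
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$provenance$timestamp,
      "seed", x$provenance$seed, "\n")
  if (!is.null(x$cnn_per_subject)) {
    cat(sprintf("  network mean accuracy: %.1f%%\n",
                mean(x$cnn_per_subject$accuracy)))
  }
  if (!is.null(x$lr_per_subject))
    cat(sprintf("  baseline mean accuracy: %.1f%%\n",
                mean(x$lr_per_subject$accuracy)))
  if (!is.null(x$latency_trends)) {
    for (i in seq_len(nrow(x$latency_trends)))
      cat(sprintf("  latency trend [%s]: r = %.3f, p = %.4f\n",
                  x$latency_trends$scenario[i], x$latency_trends$r[i],
                  x$latency_trends$p[i]))
  }
  ok <- unlist(x$checks)
  cat("  sanity checks:", sum(ok, na.rm = TRUE), "of", length(ok), "passed\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]))
      write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(out_dir)
}
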