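# End-to-end pipeline: simulate -> counts -> annotate/filter -> features ->
# d-prime ranking -> tune + LOSO classifier, with provenance-stamped outputs.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory for intermediate and final files.
#' @param seed Integer master seed for every stage.
#' @param n_subjects Number of simulated participants (default 21).
#' @param site Analysis site, `"hip"` (default) or `"wrist"`.
#' @param window_s Feature window length in seconds.
#' @param params Simulation parameters, see [default_sim_params()].
#' @param grid Classifier tuning grid, see [default_rf_grid()].
#' @param tune_folds CV folds for tuning (default 10).
#' @param labels_file Optional path to an external label CSV replacing the
#'   simulated annotations (must exist).
#' @param write_raw Also write the (large) raw-signal CSVs (default FALSE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("toddleracc_"), seed = 1,
                            n_subjects = 21, site = c("hip", "wrist"),
                            window_s = 5, params = default_sim_params(),
                            grid = default_rf_grid(), tune_folds = 10,
                            labels_file = NULL, write_raw = FALSE) {
  structure(
    list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
         site = match.arg(site), window_s = window_s, params = params,
         grid = grid, tune_folds = tune_folds, labels_file = labels_file,
         write_raw = write_raw),
    class = "pipeline_config"
  )
}

.config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

.provenance <- function(config) {
  c(sprintf("toddleracc %s",
            as.character(utils::packageVersion("toddleracc"))),
    sprintf("seed=%d", config$seed),
    sprintf("config_hash=%s", .config_hash(config)))
}

.write_table <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a raw-signal CSV
#'
#' Raw traces are stored as `timestamp,axis1,axis2,axis3` rows (timestamps
#' in session seconds) under a `#`-prefixed preamble recording site and
#' sample rate.
#'
#' @param trace An [accel_trace()].
#' @param path File path.
#' @param provenance Optional extra `#` header lines.
#' @return `read_trace()` returns an [accel_trace()].
#' @export
write_trace <- function(trace, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(provenance,
                            sprintf("site=%s", trace$site),
                            sprintf("sample_rate=%g", trace$sample_rate))),
             con)
  df <- data.frame(
    timestamp = trace$start_time +
      (seq_len(nrow(trace$samples)) - 1) / trace$sample_rate,
    trace$samples
  )
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "# ")]
  get_field <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1L]) else default
  }
  df <- read.csv(path, comment.char = "#")
  accel_trace(as.matrix(df[c("axis1", "axis2", "axis3")]),
              sample_rate = as.numeric(get_field("sample_rate", "30")),
              site = get_field("site", "hip"),
              start_time = df$timestamp[1L])
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> counts -> label filtering -> behavior count rates
#' and summaries -> window features -> d-prime ranking -> grid-search
#' tuning -> LOSO evaluation, writing provenance-stamped CSV/JSON outputs
#' to `config$out_dir`. Byte-identical outputs for identical configurations
#' and seeds.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `rates`, `count_summary`, `features`
#'   (78-feature table), `ranking`, `tuning`, `report`
#'   (a `classifier_report`), and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$labels_file) && !file.exists(config$labels_file)) {
    stop("labels file not found: ", config$labels_file)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  # -- simulate ----------------------------------------------------------
  t_start <- proc.time()[["elapsed"]]
  subjects <- sprintf("p%02d", seq_len(config$n_subjects))
  sessions <- lapply(seq_along(subjects), function(i) {
    sched <- default_schedule(subjects[i], seed = sub_seed(config$seed, i))
    simulate_session(sched, config$params,
                     seed = sub_seed(config$seed, 1000L + i))
  })
  names(sessions) <- subjects
  say("simulate: %d subjects, %.0f s of signal [%.1f s]", length(subjects),
      sum(vapply(sessions, function(s) trace_duration(s$hip), 0)),
      proc.time()[["elapsed"]] - t_start)

  all_labels <- do.call(rbind, lapply(sessions, function(s) {
    as.data.frame(s$labels)
  }))
  labels_path <- file.path(config$out_dir, "labels.csv")
  .write_table(all_labels, labels_path, prov)

  # -- counts and per-behavior rates ------------------------------------
  t0 <- proc.time()[["elapsed"]]
  rates <- do.call(rbind, lapply(subjects, function(p) {
    s <- sessions[[p]]
    kept <- filter_labels(s$labels)
    if (!nrow(kept)) return(NULL)
    do.call(rbind, lapply(c("hip", "wrist"), function(site) {
      r <- behavior_count_rate(compute_counts(s[[site]], 1), kept)
      if (nrow(r)) cbind(site = site, r) else NULL
    }))
  }))
  rownames(rates) <- NULL
  count_summary <- summarize_counts(rates)
  .write_table(rates, file.path(config$out_dir, "behavior_rates.csv"), prov)
  .write_table(count_summary,
               file.path(config$out_dir, "count_summary.csv"), prov)
  say("counts: %d rate rows [%.1f s]", nrow(rates),
      proc.time()[["elapsed"]] - t0)

  # -- features ----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  windows <- unlist(lapply(subjects, function(p) {
    s <- sessions[[p]]
    segment_windows(s[[config$site]], filter_labels(s$labels),
                    window_s = config$window_s)
  }), recursive = FALSE)
  features <- extract_features(windows,
                               sample_rate = config$params$sample_rate)
  .write_table(features, file.path(config$out_dir, "features.csv"), prov)
  say("features: %d windows x %d features [%.1f s]", nrow(features),
      length(feature_names()), proc.time()[["elapsed"]] - t0)
  if (!nrow(features)) stop("feature extraction produced no windows")

  # -- d-prime ranking ---------------------------------------------------
  y <- binarize_behavior(features$behavior)
  ranking <- rank_features(features[feature_names()], y)
  .write_table(as.data.frame(ranking),
               file.path(config$out_dir, "dprime_ranking.csv"), prov)

  # -- classifier --------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  tuning <- tune_rf(features[feature_names()], y, grid = config$grid,
                    folds = config$tune_folds, seed = sub_seed(config$seed, 2))
  report <- loso_evaluate(features[feature_names()], y,
                          features$participant,
                          hyper = tuning[c("num_trees", "max_depth", "min_node")],
                          seed = sub_seed(config$seed, 3))
  say("classifier: tuned (%d trees, depth %s) LOSO accuracy %.3f [%.1f s]",
      tuning$num_trees, tuning$max_depth, report$accuracy,
      proc.time()[["elapsed"]] - t0)

  report_path <- file.path(config$out_dir, "classifier_report.json")
  jsonlite::write_json(
    list(provenance = prov,
         confusion = as.data.frame(report$confusion),
         accuracy = report$accuracy,
         precision = as.list(report$precision),
         recall = as.list(report$recall),
         macro_precision = report$macro_precision,
         macro_recall = report$macro_recall,
         f1 = report$f1,
         tuning = tuning[c("num_trees", "max_depth", "min_node",
                           "cv_accuracy")],
         per_fold = report$per_fold,
         importance = head(report$importance, 20L)),
    report_path, auto_unbox = TRUE, digits = NA)

  files <- c(labels = labels_path,
             rates = file.path(config$out_dir, "behavior_rates.csv"),
             summary = file.path(config$out_dir, "count_summary.csv"),
             features = file.path(config$out_dir, "features.csv"),
             ranking = file.path(config$out_dir, "dprime_ranking.csv"),
             report = report_path)
  if (isTRUE(config$write_raw)) {
    for (p in subjects) {
      for (site in c("hip", "wrist")) {
        f <- file.path(config$out_dir, sprintf("raw_%s_%s.csv", p, site))
        write_trace(sessions[[p]][[site]], f, prov)
        files[sprintf("raw_%s_%s", p, site)] <- f
      }
    }
  }
  invisible(list(rates = rates, count_summary = count_summary,
                 features = features, ranking = ranking, tuning = tuning,
                 report = report, files = files, config = config))
}
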