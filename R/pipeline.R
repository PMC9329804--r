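#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis run:
#' which stages to execute and their parameters. Unknown keys are rejected.
#' `yaml` may name a YAML file whose top-level keys override the defaults
#' (nested `session:` keys are passed to [session_config()]).
#'
#' @param session a [session_config()] (or list of its arguments).
#' @param stages character subset of
#'   `c("erd", "fatigue", "entropy", "plv", "cnn")`.
#' @param erd_channel,erd_band,erd_windows ERD quantification settings.
#' @param fatigue_threshold channel-selection correlation threshold.
#' @param plv_band PLV narrowband (Hz).
#' @param cnn list: `epochs`, `batch`, `lr`, `split_ratio`.
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir report directory or `NULL` for no files.
#' @param yaml optional YAML file of overrides.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(session = session_config(),
                            stages = c("erd", "fatigue", "entropy", "plv", "cnn"),
                            erd_channel = "C3",
                            erd_band = c(8, 13),
                            erd_windows = list(c(0, 1), c(1, 2.5)),
                            fatigue_threshold = 0.75,
                            plv_band = c(8, 13),
                            cnn = list(epochs = 10, batch = 64, lr = 1e-3,
                                       split_ratio = 0.8),
                            seed = 1L,
                            out_dir = NULL,
                            yaml = NULL) {
  cfg <- list(session = session, stages = stages, erd_channel = erd_channel,
              erd_band = erd_band, erd_windows = erd_windows,
              fatigue_threshold = fatigue_threshold, plv_band = plv_band,
              cnn = cnn, seed = as.integer(seed), out_dir = out_dir)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(ov$session)) {
      cfg$session <- do.call(session_config, ov$session)
      ov$session <- NULL
    }
    cfg <- utils::modifyList(cfg, ov)
  }
  if (!inherits(cfg$session, "session_config"))
    cfg$session <- do.call(session_config, cfg$session)
  bad <- setdiff(cfg$stages, c("erd", "fatigue", "entropy", "plv", "cnn"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

# Hash of the scientific configuration; the output location is volatile
# bookkeeping and deliberately excluded.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulate -> preprocess -> (ERD, fatigue, rhythm entropy, PLV, CNN) with
#' per-stage JSON reports and a combined summary, all stamped with the
#' configuration hash and seed. Deterministic given the seed: running twice
#' writes byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list of stage results plus `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stamp <- list(seed = config$seed, config_hash = config_hash(config),
                package_version = as.character(utils::packageVersion("mifatigue")))
  out <- list()
  scfg <- config$session
  scfg$seed <- config$seed
  rec <- with_stage("simulate", generate_session(scfg))
  # Analysis stages run on the 512 Hz branch; the classification branch
  # consumes epochs at the original rate (its decimation-by-4 is itself the
  # downsampling step).
  pp <- with_stage("preprocess", {
    filt <- eeg_bandpass(rec)
    list(analysis = eeg_epoch(eeg_resample(filt, min(512, rec$fs))),
         cnn = eeg_epoch(filt))
  })
  epochs <- pp$analysis

  if ("erd" %in% config$stages) {
    out$erd <- with_stage("erd", {
      tfr <- tf_morlet(epochs, config$erd_channel, class = "right")
      purrr::map_dfr(config$erd_windows, function(w)
        erd_quantify(tfr, config$erd_band, w))
    })
  }
  if ("fatigue" %in% config$stages) {
    out$fatigue <- with_stage("fatigue", {
      fs <- fatigue_timecourse(epochs)
      select_sensitive_channels(fs, config$fatigue_threshold)
    })
  }
  if ("entropy" %in% config$stages) {
    out$entropy <- with_stage("entropy", awake_fatigue_summary(epochs))
  }
  if ("plv" %in% config$stages) {
    out$plv <- with_stage("plv", {
      hub <- unique(config$session$coupled_pairs$parietal)[1]
      plv_panel(epochs, hub, band = config$plv_band)
    })
  }
  if ("cnn" %in% config$stages) {
    out$cnn <- with_stage("cnn", {
      ep32 <- rearrange_channels(pp$cnn)
      samples <- augment_sliding(ep32)
      sp <- split_train_test(samples, config$cnn$split_ratio,
                             seed = config$seed)
      model <- build_mi_cnn(seed = config$seed)
      model <- train_mi_cnn(model, sp$train, sp$test,
                            epochs = config$cnn$epochs,
                            batch = config$cnn$batch, lr = config$cnn$lr,
                            seed = config$seed)
      list(model = model, history = model$history,
           accuracy = evaluate_mi_cnn(model, sp$test),
           n_train = dim(sp$train$x)[3], n_test = dim(sp$test$x)[3])
    })
  }

  summary <- c(stamp, list(
    stages = config$stages,
    erd = if (!is.null(out$erd)) as.list(stats::setNames(out$erd$erd,
      paste0("window_", out$erd$t0, "_", out$erd$t1))),
    fatigue = if (!is.null(out$fatigue))
      list(session_mean = out$fatigue$session_mean,
           selected = as.list(out$fatigue$selected)),
    entropy = if (!is.null(out$entropy))
      list(awake = out$entropy$awake_mean, fatigue = out$entropy$fatigue_mean,
           delta = out$entropy$delta),
    plv = if (!is.null(out$plv)) list(mean = mean(out$plv$plv)),
    cnn = if (!is.null(out$cnn))
      list(accuracy = out$cnn$accuracy, n_train = out$cnn$n_train,
           n_test = out$cnn$n_test)))
  out$summary <- summary

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name)
      jsonlite::write_json(x, file.path(config$out_dir, name),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(out$erd)) wr(out$erd, "erd.json")
    if (!is.null(out$fatigue))
      wr(list(correlations = out$fatigue$correlations,
              index = out$fatigue$index,
              session_mean = out$fatigue$session_mean,
              selected = out$fatigue$selected), "fatigue.json")
    if (!is.null(out$entropy))
      wr(summary$entropy, "entropy.json")
    if (!is.null(out$plv)) wr(out$plv, "plv.json")
    if (!is.null(out$cnn))
      wr(list(history = out$cnn$history, accuracy = out$cnn$accuracy,
              n_train = out$cnn$n_train, n_test = out$cnn$n_test),
         "cnn.json")
    wr(summary, "summary.json")
  }
  invisible(out)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
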