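# Pipeline orchestration: one nested configuration drives
# generate -> simulate -> corrupt -> train -> predict -> evaluate, with
# deterministic seed fan-out, config-keyed caching and a summary of
# detection metrics per noise condition.

#' Build a run configuration
#'
#' Nested configuration for [run_pipeline()]. Cross-module parameters
#' (grid, antenna count, frequency) are defined once here and consumed
#' consistently by every stage. `overrides` is a nested list merged over
#' the defaults; configurations round-trip through YAML unchanged.
#'
#' @param overrides nested list of overrides (same shape as the defaults).
#' @param file optional YAML file to read (applied before `overrides`).
#' @return an `mwt_run_config` (nested named list).
#' @export
run_config <- function(overrides = list(), file = NULL) {
  defaults <- list(
    seed = 1L,
    phantoms = list(n_pixels = 108L, side_length = 15, n_per_cell = 25L,
                    split = list(train = 0.8, val = 0.1, test = 0.1)),
    geometry = list(n_antennas = 30L, ring_radius = 12, frequency = 1e9,
                    background_eps = 15, background_sigma = 0),
    solver = list(tol = 1e-6, method = "direct", precision = "double"),
    noise = list(snr_db = list("Inf", 30)),
    detector = list(n_conv_layers = 10L, features_per_layer = 32L,
                    learning_rate = 5e-5, epochs = 100L, batch_size = 128L,
                    threshold = 0.5, augment = FALSE),
    metrics = list(threshold = 0.5),
    paths = list(out_dir = NULL)
  )
  if (!is.null(file)) defaults <- modify_list_deep(defaults, yaml::read_yaml(file))
  cfg <- modify_list_deep(defaults, overrides)
  structure(cfg, class = "mwt_run_config")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.null(new[[nm]])) next  # NULL leaves (YAML "~") keep the defaults
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && length(new[[nm]]) == 0) {
      # empty lists (e.g. YAML-dropped NULL leaves) keep the defaults
    } else if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
               !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param config an `mwt_run_config`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

# stable FNV-1a hash of a config (for artifact keying / idempotence)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE)[-(1:14)]) # skip header
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

snr_values <- function(config) {
  vapply(config$noise$snr_db, function(s) {
    if (is.character(s)) as.numeric(s) else as.numeric(s)
  }, 0)
}

snr_tag <- function(s) if (is.infinite(s)) "noisefree" else sprintf("snr%02.0fdB", s)

#' Run the full detection pipeline
#'
#' Executes, in order: `generate` (phantom database), `simulate`
#' (scattering matrices), then per noise condition `corrupt`, `train`
#' (matched-SNR training on the train/val splits) and `evaluate` (ROC,
#' AUR, EER and threshold metrics on the test split). Every stage draws
#' its randomness from a sub-seed fanned out from `config$seed`, and each
#' stage's artifact is cached (in memory, and on disk when
#' `config$paths$out_dir` is set, keyed by the hash of the config subset
#' it depends on) so rerunning an unchanged configuration is a no-op.
#'
#' @param config an [run_config()].
#' @param stages subset of `c("generate", "simulate", "corrupt", "train",
#'   "evaluate")`; later stages require the earlier artifacts, either from
#'   this call or from `state`/disk cache.
#' @param state optional artifact list from a previous call (for stage
#'   subsets).
#' @param verbose print stage progress.
#' @return an `mwt_pipeline_result`: list with `dataset`, `scattering`,
#'   `models`, `predictions`, `summary` (tibble of AUR/EER/accuracy/
#'   sensitivity/specificity per SNR condition), `config`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("generate", "simulate", "corrupt",
                                    "train", "evaluate"),
                         state = NULL, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  st <- state %||% list()
  out_dir <- config$paths$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cache <- function(key, depends, producer) {
    h <- config_hash(depends)
    slot <- paste0(key, "_", h)
    if (!is.null(st[[slot]])) return(st[[slot]])
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0(slot, ".rds"))
      if (file.exists(f)) return(readRDS(f))
    }
    val <- producer()
    if (!is.null(out_dir)) saveRDS(val, file.path(out_dir, paste0(slot, ".rds")))
    val
  }
  need <- function(key, what) {
    hit <- st[[grep(paste0("^", key, "_"), names(st), value = TRUE)[1] %||% ""]]
    if (is.null(hit))
      abort(sprintf("stage needs the '%s' artifact; run the '%s' stage first.",
                    key, what), class = "mwtomo_missing_dependency")
    hit
  }
  keep <- function(key, depends, val) st[[paste0(key, "_", config_hash(depends))]] <<- val

  pc <- config$phantoms
  gen_cfg <- generator_config(grid = grid_spec(pc$side_length, pc$n_pixels))
  geometry <- do.call(acquisition_geometry, config$geometry)

  if ("generate" %in% stages) {
    dep <- list(config$seed, config$phantoms)
    ds <- cache("dataset", dep, function() {
      if (verbose) message("generate: ", 8L * pc$n_per_cell, " phantoms")
      generate_dataset(gen_cfg, n_per_cell = pc$n_per_cell,
                       split = unlist(pc$split),
                       seed = derive_seed(config$seed, "generate"))
    })
    keep("dataset", dep, ds)
  }

  if ("simulate" %in% stages) {
    ds <- need("dataset", "generate")
    dep <- list(config$seed, config$phantoms, config$geometry, config$solver)
    sc <- cache("scattering", dep, function() {
      if (verbose) message("simulate: ", length(ds$phantoms), " profiles")
      simulate_dataset(ds, geometry, tol = config$solver$tol,
                       solver = config$solver$method, progress = verbose,
                       precision = config$solver$precision %||% "double")
    })
    keep("scattering", dep, sc)
  }

  snrs <- snr_values(config)
  if (any(c("corrupt", "train", "evaluate") %in% stages)) {
    ds <- need("dataset", "generate")
    sc <- need("scattering", "simulate")
    man <- ds$manifest
  }

  if ("corrupt" %in% stages) {
    for (s in snrs) {
      dep <- list(config$seed, config$phantoms, config$geometry, config$solver, s)
      noisy <- cache(paste0("noisy_", snr_tag(s)), dep, function() {
        if (verbose) message("corrupt: ", snr_tag(s))
        corrupt_dataset(sc, s, seed = derive_seed(config$seed, snr_tag(s)))
      })
      keep(paste0("noisy_", snr_tag(s)), dep, noisy)
    }
  }

  if ("train" %in% stages) {
    for (s in snrs) {
      noisy <- need(paste0("noisy_", snr_tag(s)), "corrupt")
      dep <- list(config$seed, config$phantoms, config$geometry, config$solver,
                  s, config$detector)
      fit <- cache(paste0("model_", snr_tag(s)), dep, function() {
        if (verbose) message("train: ", snr_tag(s))
        tr <- which(man$split == "train"); va <- which(man$split == "val")
        aug <- isTRUE(config$detector$augment)
        stats <- encoding_stats(noisy[tr],
                                by = if (aug) "diagonal" else "element")
        dcfg <- detector_config(
          n_conv_layers = config$detector$n_conv_layers,
          features_per_layer = config$detector$features_per_layer,
          learning_rate = config$detector$learning_rate,
          epochs = config$detector$epochs,
          batch_size = config$detector$batch_size,
          threshold = config$detector$threshold,
          head = config$detector$head %||% "gap",
          seed = derive_seed(config$seed, paste0("train/", snr_tag(s))))
        model <- build_detector(dcfg, img_side = geometry$n_antennas)
        S_tr <- lapply(noisy[tr], function(s) if (inherits(s, "mwt_scattering")) s$S else s)
        ckf <- if (!is.null(out_dir))
          file.path(out_dir, paste0("ck_", snr_tag(s), "_", config_hash(dep), ".rds"))
        train_detector(model, S_tr, as.numeric(man$pathological[tr]),
                       noisy[va], as.numeric(man$pathological[va]), stats,
                       augment = aug, checkpoint_file = ckf)
      })
      keep(paste0("model_", snr_tag(s)), dep, fit)
    }
  }

  summary_tbl <- NULL
  predictions <- list()
  if ("evaluate" %in% stages) {
    rows <- list()
    for (s in snrs) {
      noisy <- need(paste0("noisy_", snr_tag(s)), "corrupt")
      fit <- need(paste0("model_", snr_tag(s)), "train")
      te <- which(man$split == "test")
      pred <- predict(fit, noisy[te], threshold = config$metrics$threshold)
      pred$id <- man$id[te]; pred$pathological <- man$pathological[te]
      predictions[[snr_tag(s)]] <- pred
      roc <- roc_curve(pred$score, pred$pathological)
      tm <- threshold_metrics(pred$score, pred$pathological,
                              config$metrics$threshold)
      rows[[snr_tag(s)]] <- tibble::tibble(
        snr_db = s, aur = roc$aur, eer = roc$eer, accuracy = tm$accuracy,
        sensitivity = tm$sensitivity, specificity = tm$specificity,
        n_test = length(te))
    }
    summary_tbl <- dplyr::bind_rows(rows)
    if (!is.null(out_dir))
      jsonlite::write_json(summary_tbl, file.path(out_dir, "report.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  structure(list(
    dataset = st[[grep("^dataset_", names(st), value = TRUE)[1] %||% ""]],
    scattering = st[[grep("^scattering_", names(st), value = TRUE)[1] %||% ""]],
    models = st[grep("^model_", names(st))],
    predictions = predictions, summary = summary_tbl,
    config = config, state = st),
    class = "mwt_pipeline_result")
}

#' @export
print.mwt_pipeline_result <- function(x, ...) {
  cat("<mwt_pipeline_result>\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
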