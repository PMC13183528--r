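# End-to-end orchestration: one configuration drives synthesis (or an
# existing manifest), preprocessing, optimizer-driven segmentation, CNN
# training and evaluation, and writes per-stage artifacts plus a
# reproducibility manifest into a run directory.

default_pipeline_config <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = 1L,
    out_dir = "dermwolf_run",
    synth = list(enabled = TRUE, n_images = 250L, imbalance = 0.1,
                 n_patients = 50L, image_size = 32L, hair_prob = 0.25),
    manifest = NULL, # path to an existing manifest when synth is disabled
    split = list(train = 0.70, val = 0.15, test = 0.15),
    # the closing element must stay small relative to the lesion: 3 px at
    # the desk 32-px scale, 7 px at the paper 225-px scale
    preprocess = list(enabled = TRUE, denoise_sigma = 0.5,
                      hair_element = 3L, hair_threshold = 10,
                      contrast = TRUE),
    segment = list(enabled = TRUE, n_images = 5L, classes = 2L,
                   repeats = 5L, pop_size = 20L, max_iter = 60L,
                   variant = "igwo", compare_variants = FALSE),
    train = list(enabled = TRUE, filters = c(32L, 64L, 128L),
                 dropout = 0.5, dense_units = 128L, learning_rate = 0.005,
                 epochs = 10L, batch_size = 32L, patience = 10L,
                 class_weighted = TRUE)
  )
  if (profile == "paper") {
    cfg$synth$image_size <- 225L
    cfg$preprocess$hair_element <- 7L
    cfg$segment$repeats <- 25L
    cfg$segment$pop_size <- 30L
    cfg$segment$max_iter <- 200L
    cfg$train$learning_rate <- 0.001
    cfg$train$epochs <- 50L
  }
  cfg
}

check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]])) {
      check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Assemble a pipeline configuration
#'
#' Starts from the profile defaults (`"desk"`: 32 px images, short
#' training, small optimizer budgets; `"paper"`: 225 px input, 50 epochs,
#' 30 agents, 200 iterations, 25 threshold repeats) and overrides them
#' with the supplied values. Unknown keys are rejected.
#'
#' @param ... Named overrides (nested lists per section: `synth`, `split`,
#'   `preprocess`, `segment`, `train`, plus `seed`, `out_dir`,
#'   `manifest`).
#' @param profile `"desk"` (default) or `"paper"`.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  base <- default_pipeline_config(profile)
  over <- list(...)
  check_keys(over, base)
  cfg <- utils::modifyList(base, over)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the sections of [pipeline_config()];
#'   unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "desk"
  raw$profile <- NULL
  do.call(pipeline_config, c(raw, list(profile = profile)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data synthesis (or manifest loading), patient-wise
#' stratified splitting, image preprocessing, optimizer-driven lesion
#' segmentation on a subset (with IoU against ground truth when masks are
#' available), CNN training, and test-set evaluation. Each stage's
#' artifacts land under `cfg$out_dir`; a `run_info.json` records the
#' configuration, seed and package version so a run can be reproduced
#' exactly. Any stage failure aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report`: the split table, per-stage
#'   summaries, the trained model, and the test-set [metrics_report()].
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  completed <- character(0)
  report <- list(config = unclass(cfg))
  stage <- function(name, expr) {
    say("stage: ", name)
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (completed: %s)",
                   name, conditionMessage(e),
                   paste(completed, collapse = ", ")), call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  manifest <- stage("data", {
    if (isTRUE(cfg$synth$enabled)) {
      make_dataset(cfg$synth$n_images, cfg$synth$imbalance,
                   cfg$synth$n_patients, file.path(cfg$out_dir, "data"),
                   image_size = cfg$synth$image_size,
                   hair_prob = cfg$synth$hair_prob, seed = cfg$seed)
    } else {
      if (is.null(cfg$manifest)) stop("no synth section and no manifest path")
      read_manifest(cfg$manifest)
    }
  })

  manifest <- stage("split", {
    m <- split_dataset(manifest, unlist(cfg$split), seed = cfg$seed)
    write_manifest(m, file.path(cfg$out_dir, "manifest_split.csv"))
    m
  })
  report$split <- table(manifest$split, manifest$label)

  base_dir <- attr(manifest, "base_dir") %||% "."
  dat <- stage("load", load_images(manifest, base_dir = base_dir))

  if (isTRUE(cfg$preprocess$enabled)) {
    dat <- stage("preprocess", {
      pp <- cfg$preprocess
      for (i in seq_len(dim(dat$x)[4L])) {
        dat$x[, , , i] <- preprocess_image(
          dat$x[, , , i], denoise_sigma = pp$denoise_sigma,
          hair_element = pp$hair_element,
          hair_threshold = pp$hair_threshold, contrast = pp$contrast)
      }
      dat
    })
  }

  if (isTRUE(cfg$segment$enabled)) {
    report$segmentation <- stage("segment", {
      sg <- cfg$segment
      n <- min(sg$n_images, nrow(manifest))
      idx <- seq_len(n)
      variants <- if (isTRUE(sg$compare_variants)) c("igwo", "gwo") else
        sg$variant
      out <- list()
      for (v in variants) {
        ious <- rep(NA_real_, n)
        for (j in idx) {
          opt <- igwo_config(pop_size = sg$pop_size, max_iter = sg$max_iter,
                             seed = derive_seed(cfg$seed, j))
          mask <- segment_lesion(dat$x[, , , j], m = sg$classes, opt = opt,
                                 repeats = sg$repeats, variant = v)
          write_image(mask, file.path(cfg$out_dir,
                                      sprintf("segmask_%s_%03d.png", v, j)))
          if (!is.null(manifest$mask_path)) {
            truth <- read_mask(file.path(base_dir, manifest$mask_path[j]))
            ious[j] <- mask_iou(mask, truth)
          }
        }
        out[[v]] <- data.frame(image = idx, variant = v, iou = ious)
      }
      df <- do.call(rbind, out)
      utils::write.csv(df, file.path(cfg$out_dir, "segmentation_iou.csv"),
                       row.names = FALSE)
      df
    })
  }

  model <- NULL
  if (isTRUE(cfg$train$enabled)) {
    model <- stage("train", {
      tc <- cfg$train
      arch <- build_cnn(
        cnn_hyperparams(tc$filters[1L], tc$filters[2L], tc$filters[3L],
                        tc$dropout),
        input_size = c(dim(dat$x)[1:2], 3L), dense_units = tc$dense_units)
      tr <- manifest$split == "train"
      va <- manifest$split == "val"
      m <- train_cnn(arch, dat$x[, , , tr, drop = FALSE], dat$y[tr],
                     dat$x[, , , va, drop = FALSE], dat$y[va],
                     config = train_config(
                       learning_rate = tc$learning_rate, epochs = tc$epochs,
                       batch_size = tc$batch_size, patience = tc$patience,
                       class_weighted = tc$class_weighted,
                       seed = derive_seed(cfg$seed, 777L)))
      utils::write.csv(m$history,
                       file.path(cfg$out_dir, "training_history.csv"),
                       row.names = FALSE)
      m
    })
    report$metrics <- stage("evaluate", {
      te <- manifest$split == "test"
      pb <- predict_cnn(model, dat$x[, , , te, drop = FALSE])
      rep_ <- metrics_report(pb$labels, dat$y[te],
                             pb$scores[, "malignant"])
      pred_df <- data.frame(image_path = manifest$image_path[te],
                            score_malignant = pb$scores[, "malignant"],
                            pred_label = pb$labels)
      utils::write.csv(pred_df, file.path(cfg$out_dir, "predictions.csv"),
                       row.names = FALSE)
      json <- c(list(counts = unclass(rep_$counts)),
                rep_[setdiff(names(rep_), "counts")])
      jsonlite::write_json(json, file.path(cfg$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      rep_
    })
  }

  stage("run_info", {
    cfg_file <- file.path(cfg$out_dir, "config.yaml")
    yaml::write_yaml(unclass(cfg), cfg_file)
    info <- list(
      package_version = as.character(utils::packageVersion("dermwolf")),
      r_version = R.version.string,
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      completed_stages = completed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(info, file.path(cfg$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
    info
  })

  report$model <- model
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$split)) {
    cat("split:\n"); print(x$split)
  }
  if (!is.null(x$segmentation)) {
    ok <- stats::aggregate(iou ~ variant, x$segmentation, stats::median)
    cat("segmentation median IoU:\n"); print(ok)
  }
  if (!is.null(x$metrics)) {
    cat("test metrics:\n"); print(x$metrics)
  }
  invisible(x)
}
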