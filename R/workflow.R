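# YAML-configured orchestration of the pipeline stages:
# simulate -> filter -> train2d/predict2d -> train3d/predict3d ->
# postprocess -> evaluate, with artifacts and a manifest written to a run
# directory.  Stages communicate in memory and via the written artifacts.

#' Run a configured pipeline
#'
#' Executes the enabled stages in dependency order.  The configuration is a
#' YAML file (or equivalent list) with a `stages` vector and one parameter
#' block per enabled stage; every artifact (MRC volumes, particle CSVs,
#' model containers, metrics JSON) is written to the run directory together
#' with the resolved configuration and a manifest (config checksum, package
#' version, seed).  Reruns with the same configuration and seed reproduce
#' the CSV and metric outputs.
#'
#' @param config path to a YAML configuration or a named list.
#' @param out_dir run directory (overrides `config$output_dir`).
#' @return Invisibly, a list with the run directory, the metrics (if the
#'   evaluate stage ran) and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir <- out_dir %||% cfg$output_dir
  if (is.null(dir)) stopf("configuration error: no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% character()
  known <- c("simulate", "filter", "train2d", "predict2d", "train3d",
             "predict3d", "postprocess", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("configuration error: unknown stage(s) %s",
                         paste(bad, collapse = ", "))
  seed <- cfg$seed %||% 1L
  st <- new.env(parent = emptyenv())   # shared pipeline state
  st$volumes <- list()                 # list of tomograms (current inputs)
  st$bundles <- list()                 # phantom bundles (if simulated)
  st$probs <- list()
  st$artifacts <- character()

  log_msg <- function(fmt, ...) message(sprintf(paste0("[tomopict] ", fmt), ...))
  put <- function(path) { st$artifacts <- c(st$artifacts, path); path }

  for (stage in intersect(known, stages)) {
    log_msg("stage %s", stage)
    switch(stage,
      simulate = stage_simulate(cfg, st, dir, seed, put),
      filter = stage_filter(cfg, st, dir, put),
      train2d = stage_train2d(cfg, st, dir, seed, put),
      predict2d = stage_predict2d(cfg, st, dir, put),
      train3d = stage_train3d(cfg, st, dir, seed, put),
      predict3d = stage_predict3d(cfg, st, dir, put),
      postprocess = stage_postprocess(cfg, st, dir, put),
      evaluate = stage_evaluate(cfg, st, dir, put))
  }

  resolved <- file.path(dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, resolved)
  manifest <- list(
    package = "tomopict",
    version = as.character(utils::packageVersion("tomopict")),
    seed = seed,
    config_md5 = unname(tools::md5sum(resolved)),
    stages = stages,
    artifacts = basename(st$artifacts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, metrics = st$metrics, manifest = manifest))
}

stage_simulate <- function(cfg, st, dir, seed, put) {
  sc <- cfg$simulate %||% list()
  n <- sc$n_tomograms %||% 1L
  sc$n_tomograms <- NULL
  spec_args <- sc[intersect(names(sc), names(formals(phantom_spec)))]
  for (i in seq_len(n)) {
    spec_args$seed <- derive_seed(seed, paste0("simulate", i))
    ph <- generate_phantom(do.call(phantom_spec, spec_args))
    st$bundles[[i]] <- ph
    st$volumes[[i]] <- ph$tomogram
    write_mrc(ph$tomogram, put(file.path(dir, sprintf("tomo_%02d.mrc", i))))
    for (nm in names(ph$masks))
      write_mrc(ph$masks[[nm]],
                put(file.path(dir, sprintf("mask_%s_%02d.mrc", nm, i))))
    write_particles(ph$particles$dense,
                    put(file.path(dir, sprintf("particles_dense_%02d.csv", i))))
  }
}

stage_filter <- function(cfg, st, dir, put) {
  fc <- cfg$filter %||% list()
  if (!length(st$volumes)) {
    if (is.null(fc$inputs))
      stopf("dependency error: stage 'filter' has no input volumes; enable 'simulate' or set filter$inputs")
    st$volumes <- lapply(fc$inputs, read_mrc)
  }
  lp <- if (isFALSE(fc$lowpass)) NULL else
    lowpass_spec(cutoff_fraction = fc$cutoff %||% 0.5,
                 steepness = fc$steepness %||% 0.03)
  for (i in seq_along(st$volumes)) {
    v <- standardize(st$volumes[[i]])
    target <- if (!is.null(fc$target_spectrum))
      read_spectrum(fc$target_spectrum)
    else default_target_spectrum(dim(v$data))
    st$volumes[[i]] <- match_spectrum(v, target, lowpass = lp)
    write_mrc(st$volumes[[i]],
              put(file.path(dir, sprintf("filtered_%02d.mrc", i))))
  }
}

mask_for_class <- function(st, class, i) {
  if (!is.null(st$bundles[[i]]) && !is.null(st$bundles[[i]]$masks[[class]]))
    return(st$bundles[[i]]$masks[[class]])
  stopf("dependency error: no '%s' mask available for volume %d", class, i)
}

stage_train3d <- function(cfg, st, dir, seed, put) {
  tc <- cfg$train3d %||% list()
  if (!length(st$volumes))
    stopf("dependency error: stage 'train3d' needs input volumes")
  class <- tc$class %||% "dense"
  train_idx <- tc$train_on %||% seq_along(st$volumes)
  masks <- lapply(train_idx, function(i) mask_for_class(st, class, i))
  config <- unet3d_config(D = tc$D %||% 2, IF = tc$IF %||% 4,
                          BN = tc$BN %||% TRUE, ED = tc$ED %||% 0,
                          DD = tc$DD %||% 0,
                          patch_size = tc$patch_size %||% 32,
                          overlap = tc$overlap %||% 8)
  spec <- train_spec(learning_rate = tc$learning_rate %||% 3e-3,
                     batch_size = tc$batch_size %||% 2,
                     max_epochs = tc$max_epochs %||% 28,
                     loss = tc$loss %||% "dice",
                     patience = tc$patience %||% 28,
                     seed = derive_seed(seed, "train3d"))
  model <- suppressWarnings(train_unet3d(
    st$volumes[train_idx], masks, config, spec,
    patches_per_epoch = tc$patches_per_epoch %||% 24,
    n_val_patches = tc$n_val_patches %||% 6))
  st$model3d <- model
  save_unet(model, put(file.path(dir, "model3d.rds")))
}

stage_predict3d <- function(cfg, st, dir, put) {
  pc <- cfg$predict3d %||% list()
  model <- if (!is.null(pc$model)) load_unet(pc$model) else st$model3d
  if (is.null(model))
    stopf("dependency error: stage 'predict3d' needs a model; enable 'train3d' or set predict3d$model")
  idx <- pc$predict_on %||% seq_along(st$volumes)
  for (i in idx) {
    pm <- predict(model, st$volumes[[i]])
    st$probs[[i]] <- pm
    write_mrc(tomogram(pm$data, st$volumes[[i]]$voxel_size_A, "prob"),
              put(file.path(dir, sprintf("prob3d_%02d.mrc", i))))
  }
}

stage_train2d <- function(cfg, st, dir, seed, put) {
  tc <- cfg$train2d %||% list()
  if (!length(st$volumes))
    stopf("dependency error: stage 'train2d' needs input volumes")
  class <- tc$class %||% "cytosol"
  train_idx <- tc$train_on %||% seq_along(st$volumes)
  masks <- lapply(train_idx, function(i) mask_for_class(st, class, i))
  tile <- tc$tile_size %||% 64
  config <- unet2d_config(depth = tc$depth %||% 3,
                          initial_features = tc$initial_features %||% 8,
                          tile_size = tile, core_size = tile - 2 * (tc$pad %||% 8),
                          pad = tc$pad %||% 8, crop = tc$crop %||% 8)
  spec <- train_spec(learning_rate = tc$learning_rate %||% 1e-3,
                     batch_size = tc$batch_size %||% 8,
                     max_epochs = tc$max_epochs %||% 10,
                     patience = tc$patience %||% 10,
                     seed = derive_seed(seed, "train2d"))
  model <- train_unet2d(st$volumes[train_idx], masks, config, spec,
                        slices = tc$slices)
  st$model2d <- model
  save_unet(model, put(file.path(dir, "model2d.rds")))
}

stage_predict2d <- function(cfg, st, dir, put) {
  pc <- cfg$predict2d %||% list()
  model <- if (!is.null(pc$model)) load_unet(pc$model) else st$model2d
  if (is.null(model))
    stopf("dependency error: stage 'predict2d' needs a model; enable 'train2d' or set predict2d$model")
  idx <- pc$predict_on %||% seq_along(st$volumes)
  st$region2d <- list()
  for (i in idx) {
    pm <- predict(model, st$volumes[[i]])
    st$region2d[[i]] <- zsmooth_threshold(pm, sigma = pc$sigma %||% 1,
                                          threshold = pc$threshold %||% 0.75)
    write_mrc(tomogram(pm$data, st$volumes[[i]]$voxel_size_A, "prob2d"),
              put(file.path(dir, sprintf("prob2d_%02d.mrc", i))))
  }
}

stage_postprocess <- function(cfg, st, dir, put) {
  pc <- cfg$postprocess %||% list()
  idx <- pc$process %||% {
    have <- which(!vapply(st$probs, is.null, logical(1)))
    if (length(have)) have else seq_along(st$volumes)
  }
  if (!length(idx))
    stopf("dependency error: stage 'postprocess' has nothing to process; enable 'simulate'/'predict3d' or set postprocess$prob")
  st$pred_particles <- list()
  for (i in idx) {
    pm <- if (!is.null(pc$prob)) {
      if (startsWith(pc$prob, "gt:")) {
        m <- mask_for_class(st, sub("^gt:", "", pc$prob), i)
        prob_map(m$data + 0)
      } else prob_map(pmin(pmax(read_mrc(pc$prob)$data, 0), 1))
    } else if (length(st$probs) >= i && !is.null(st$probs[[i]])) {
      st$probs[[i]]
    } else {
      stopf("dependency error: stage 'postprocess' has no probability map for volume %d; enable 'predict3d' or set postprocess$prob", i)
    }
    cl <- threshold_cluster(pm, threshold = pc$threshold %||% 0.5,
                            min_size = pc$min_size %||% 1,
                            max_size = pc$max_size %||% Inf)
    if (!is.null(pc$region)) {
      region <- if (identical(pc$region, "2d")) {
        if (length(st$region2d) < i || is.null(st$region2d[[i]]))
          stopf("dependency error: postprocess$region = '2d' needs stage 'predict2d'")
        st$region2d[[i]]
      } else if (file.exists(pc$region)) {
        label_mask((read_mrc(pc$region)$data > 0.5) + 0L)
      } else mask_for_class(st, pc$region, i)
      cl <- apply_region_mask(cl, region,
                              region_mode(pc$mode %||% "intersection",
                                          pc$dilation %||% 1,
                                          pc$overlap_fraction %||% 0.5))
    }
    ps <- centroids(cl)
    st$pred_particles[[i]] <- ps
    write_particles(ps, put(file.path(dir, sprintf("particles_%02d.csv", i))))
  }
}

stage_evaluate <- function(cfg, st, dir, put) {
  ec <- cfg$evaluate %||% list()
  if (is.null(st$pred_particles))
    stopf("dependency error: stage 'evaluate' needs particle predictions; enable 'postprocess'")
  idx <- which(!vapply(st$pred_particles, is.null, logical(1)))
  per_vol <- lapply(idx, function(i) {
    gt <- if (!is.null(ec$gt)) read_particles(ec$gt) else {
      if (is.null(st$bundles[[i]]))
        stopf("dependency error: stage 'evaluate' has no ground truth; set evaluate$gt or enable 'simulate'")
      st$bundles[[i]]$particles[[ec$class %||% "dense"]]
    }
    m <- match_particles(st$pred_particles[[i]], gt,
                         tolerance_voxels = ec$tolerance %||% 10)
    c(list(volume = i, TP = m$TP, FP = m$FP, FN = m$FN), detection_f1(m))
  })
  metrics <- list(per_volume = per_vol,
                  mean_f1 = mean(vapply(per_vol, `[[`, numeric(1), "f1")))
  st$metrics <- metrics
  jsonlite::write_json(metrics, put(file.path(dir, "metrics.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
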