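#' Pipeline configuration
#'
#' Bundles geometry, simulation regime, reconstruction settings, network
#' preset and seeds into one validated object. Regime-consistent defaults:
#' the dense simulated-sphere regime (`"table1"`) uses `alpha = 100`, no
#' channel selection and the mismatched assumed properties
#' `mua_x = 0.0089, mua_m = 0.0062, mus'_x = 1.314, mus'_m = 1.274` mm^-1;
#' the sparse camera regime (`"table2"`) uses `alpha = 1`, the 0.8-sd
#' channel selection and assumed `mua = 0.0005`, `mus' = 0.1` mm^-1.
#'
#' @param regime `"table1"` or `"table2"`.
#' @param dims Reconstruction grid dims (default `c(48, 48, 56)`; use
#'   smaller for desk-scale runs).
#' @param radius,height Vessel geometry (mm; defaults 65 and 150).
#' @param n_sources,n_detectors Optode counts (defaults 64 and 56).
#' @param source_pattern,detector_pattern Ring patterns (see
#'   [place_optodes()]).
#' @param max_separation_mm Channel separation bound (default 70).
#' @param n_total,split Dataset size and train/val/test split (defaults
#'   2500 and `c(2048, 352, 100)`).
#' @param net_preset `"full"` or `"scaled"` (see [net_config()]).
#' @param max_epochs,batch_size,patience,lr Training protocol (defaults
#'   200, 16, 5, 1e-3).
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(regime = c("table1", "table2"),
                            dims = c(48L, 48L, 56L),
                            radius = 65, height = 150,
                            n_sources = 64L, n_detectors = 56L,
                            source_pattern = c(8L, 8L),
                            detector_pattern = c(7L, 8L),
                            max_separation_mm = 70,
                            n_total = 2500L, split = c(2048L, 352L, 100L),
                            net_preset = "full",
                            max_epochs = 200L, batch_size = 16L,
                            patience = 5L, lr = 1e-3,
                            seed = 1L, out_dir = tempdir()) {
  regime <- match.arg(regime)
  if (sum(split) != n_total) stop("split must sum to n_total")
  sim <- if (regime == "table1") sim_config_table1() else sim_config_table2()
  if (regime == "table1") {
    assumed <- optical_props(0.0089, 0.0062, 1.314, 1.274)
    alpha <- 100; selection <- "none"
  } else {
    assumed <- optical_props(0.0005, 0.0005, 0.1, 0.1)
    alpha <- 1; selection <- "std"
  }
  structure(list(regime = regime, dims = as.integer(dims),
                 radius = radius, height = height,
                 n_sources = as.integer(n_sources),
                 n_detectors = as.integer(n_detectors),
                 source_pattern = as.integer(source_pattern),
                 detector_pattern = as.integer(detector_pattern),
                 max_separation_mm = max_separation_mm,
                 n_total = as.integer(n_total), split = as.integer(split),
                 sim = sim, assumed = assumed, alpha = alpha,
                 selection = selection, net_preset = net_preset,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), lr = lr,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_geometry <- function(config) {
  domain <- cyl_domain(config$radius, config$height)
  grid <- build_voxel_grid(domain, config$dims)
  layout <- place_optodes(domain, config$n_sources, config$n_detectors,
                          config$source_pattern, config$detector_pattern)
  layout <- form_channels(layout, config$max_separation_mm)
  list(domain = domain, grid = grid, layout = layout)
}

#' Run a pipeline command
#'
#' Ties the modules into reproducible stages. Commands:
#' * `"simulate"` — generate the paired dataset, write the JSON manifest.
#' * `"train"` — train the denoiser on a dataset (generating it first if
#'   not supplied), write the training-curve CSV and JSON checkpoint.
#' * `"denoise"` — apply a trained network to the test split.
#' * `"evaluate"` — IoU comparison classic vs denoised on the test split.
#' * `"fit-optics"` — demonstrate the TPSF fitter on synthetic traces.
#' * `"unwrap"` — run the camera chain on the synthetic fixture.
#'
#' Every stage is deterministic given the same config and seed; artifacts
#' are written under `config$out_dir` with a JSON provenance sidecar.
#'
#' @param command One of the commands above.
#' @param config A [pipeline_config()].
#' @param state Optional list carrying results of earlier stages (e.g.
#'   `dataset`, `trained`).
#' @param verbose Print progress.
#' @return The updated `state` list, invisibly for disk-only stages.
#' @export
run_pipeline <- function(command = c("simulate", "train", "denoise",
                                     "evaluate", "fit-optics", "unwrap"),
                         config, state = list(), verbose = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geo <- state$geo %||% pipeline_geometry(config)
  state$geo <- geo
  t0 <- proc.time()[3]
  if (command == "simulate") {
    rc <- recon_config(config$alpha, config$assumed, config$selection,
                       if (config$selection == "std") list(factor = 0.8)
                       else list())
    state$dataset <- generate_dataset(
      config$sim, geo$domain, geo$grid, geo$layout, config$n_total,
      config$split, rc, config$seed, verbose = verbose)
    write_manifest_json(state$dataset,
                        file.path(config$out_dir, "manifest.json"))
  } else if (command == "train") {
    if (is.null(state$dataset))
      state <- run_pipeline("simulate", config, state, verbose)
    ds <- state$dataset
    prep <- prepare_training_pairs(ds)
    net <- build_network(net_config(config$dims, preset = config$net_preset),
                         seed = config$seed)
    tc <- train_config(config$batch_size, config$max_epochs,
                       config$patience, config$lr, config$seed)
    state$trained <- train_denoiser(net, prep$inputs, prep$targets,
                                    ds$grid$mask,
                                    which(ds$split == "train"),
                                    which(ds$split == "val"),
                                    tc, verbose = verbose)
    utils::write.csv(state$trained$history,
                     file.path(config$out_dir, "training_history.csv"),
                     row.names = FALSE)
    save_network_json(state$trained$net,
                      file.path(config$out_dir, "network.json"))
  } else if (command == "denoise") {
    if (is.null(state$trained)) stop("run the train stage first")
    prep <- state$prep %||% prepare_training_pairs(state$dataset)
    test_idx <- which(state$dataset$split == "test")
    state$denoised <- lapply(prep$inputs[test_idx], function(v)
      denoise(state$trained$net, v, state$dataset$grid$mask))
    state$prep <- prep
  } else if (command == "evaluate") {
    if (is.null(state$denoised))
      state <- run_pipeline("denoise", config, state, verbose)
    ds <- state$dataset
    test_idx <- which(ds$split == "test")
    prep <- state$prep
    # network outputs are already in the normalized units of their targets,
    # so the IoU threshold of 1 applies to them directly
    state$evaluation <- evaluate_dataset(
      prep$inputs[test_idx],
      state$denoised,
      lapply(ds$cases[test_idx], `[[`, "truth"),
      ds$grid)
    utils::write.csv(state$evaluation$iou,
                     file.path(config$out_dir, "iou_test.csv"),
                     row.names = FALSE)
  } else if (command == "fit-optics") {
    set.seed(config$seed)
    irf <- gaussian_irf()
    distances <- c(13.8, 18.4, 23.0, 27.6)
    truth <- list(mua = 4e-4, musp = 0.11)
    t_grid <- seq(0.01, 10, by = 0.01)
    feats <- lapply(distances, function(r)
      model_features(truth$mua, truth$musp, r, irf, t_grid))
    fit <- grid_search_fit(list(ipeak = vapply(feats, `[[`, 1, "ipeak"),
                                tmean = vapply(feats, `[[`, 1, "tmean")),
                           irf, distances = distances)
    state$optics_fit <- fit
    jsonlite::write_json(list(mua = fit$mua, musp = fit$musp),
                         file.path(config$out_dir, "optics_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (command == "unwrap") {
    fx <- synth_camera_fixture(seed = config$seed)
    secs <- lapply(1:3, function(s) {
      nu <- nrow(fx$truth); nv <- length(fx$sections[[s]])
      unwrap_section(fx$raw[[s]], fx$maps[[s]],
                     list(u = c(1, nu), v = c(1, nv)), pitch = 1)
    })
    pano <- stitch_sections(secs)
    img <- pano$values
    img[is.na(img)] <- 0
    img <- remove_spots(img, threshold = 1.4)
    img <- median_smooth(img, 7)
    state$unwrapped <- img
  }
  if (verbose)
    message(sprintf("[%s] done in %.1f s", command, proc.time()[3] - t0))
  prov <- list(command = command, seed = config$seed,
               regime = config$regime, dims = config$dims,
               elapsed_s = round(proc.time()[3] - t0, 2))
  jsonlite::write_json(prov, file.path(config$out_dir,
                                       paste0(command, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Std-normalize a dataset's volume pairs for training
#'
#' @param dataset An `fdot_dataset`.
#' @return List `inputs` (normalized classic volumes) and `targets`
#'   (normalized truth volumes).
#' @export
prepare_training_pairs <- function(dataset) {
  mask <- dataset$grid$mask
  list(inputs = lapply(dataset$cases, function(cs)
         normalize_volume(cs$classic, mask)),
       targets = lapply(dataset$cases, function(cs)
         normalize_volume(cs$truth, mask)))
}

#' Export a volume as NIfTI (when RNifti is installed)
#'
#' @param values Array (e.g. a reconstruction).
#' @param grid The `voxel_grid` (provides the voxel spacing).
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(values, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is not installed")
  img <- RNifti::asNifti(values, reference = NULL)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
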