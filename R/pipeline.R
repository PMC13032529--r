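#' End-to-end pipeline driver
#'
#' Reproduces the study workflow on synthetic data: simulate the full
#' design, preprocess each bulk modality, quantify marker-band
#' trajectories, average replicates, run multiblock consensus PCA on the
#' infrared and Raman blocks, then simulate an imaging scene and run pixel
#' quality control, binning, basis-spectrum unmixing and the
#' single-wavenumber lipid map. Every output is reproducible from the
#' configuration plus the seed alone.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param seed integer run seed
#' @param media,timepoints,replicates design parameters (see
#'   [default_design()])
#' @param recipes named character: recipe per bulk modality
#' @param trajectory_overrides named list of [trajectory_params()]
#'   overrides
#' @param cpca_ncomp global components for the consensus analysis
#' @param scene_shape imaging scene size in pixels
#' @param scene_medium,scene_t_hours imaging scene condition
#' @param image_axis_range wavenumber range simulated for the image (a
#'   restriction of the modality grid keeps cubes small)
#' @param basis_k number of unmixing components
#' @param out_dir output directory (created if missing); NULL = no files
#' @return list of class \code{run_config}
#' @export
run_config <- function(seed = 1,
                       media = media_table()$medium,
                       timepoints = c(8, 14, 24, 36, 60, 120),
                       replicates = 3L,
                       recipes = c(HTSFTIR = "htsftir_mva",
                                   FTRaman = "ftraman_mva"),
                       trajectory_overrides = list(),
                       cpca_ncomp = 5,
                       scene_shape = c(128, 128),
                       scene_medium = "iGlu1:Gly7", scene_t_hours = 120,
                       image_axis_range = c(900, 1900),
                       basis_k = 3, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Save / load a run configuration (YAML)
#' @param config run_config
#' @param path file path
#' @return \code{read_run_config} returns a run_config
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$recipes <- as.list(obj$recipes)  # keep modality names through YAML
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- do.call(run_config, list())
  for (nm in names(obj)) cfg[[nm]] <- obj[[nm]]
  cfg$recipes <- unlist(cfg$recipes)
  cfg$scene_shape <- unlist(cfg$scene_shape)
  cfg$image_axis_range <- unlist(cfg$image_axis_range)
  cfg
}

#' Run the full pipeline
#'
#' @param config run_config from [run_config()]
#' @return list of class \code{run_report}: simulated datasets,
#'   preprocessed blocks, trajectory tables, the CPCA model, the imaging
#'   results, and a run log (config, seed, recipe steps, package version)
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  all_recipes <- packaged_recipes()
  for (r in config$recipes) {
    if (!r %in% names(all_recipes)) stop("unknown recipe name: ", r)
  }
  params <- do.call(trajectory_params, config$trajectory_overrides)
  design <- default_design(media = config$media,
                           timepoints = config$timepoints,
                           replicates = config$replicates)

  sim <- stage("simulate", simulate_design_dataset(design, seed = config$seed,
                                                   params = params))

  pre <- stage("preprocess", lapply(stats::setNames(names(sim), names(sim)),
    function(mod) apply_recipe(sim[[mod]], config$recipes[[mod]])))

  traj <- stage("band_metrics", {
    ftir2 <- apply_recipe(sim$HTSFTIR, "htsftir_bandratio")
    raman2 <- apply_recipe(sim$FTRaman, "ftraman_bandratio")
    list(HTSFTIR = metabolite_trajectories(ftir2),
         FTRaman = metabolite_trajectories(raman2))
  })

  cpca <- stage("cpca", {
    blocks <- lapply(pre, function(ds) average_replicates(ds)$intensity)
    cpca_fit(blocks, ncomp = config$cpca_ncomp)
  })

  imaging <- stage("imaging", {
    scene <- make_scene(shape = config$scene_shape,
                        medium = config$scene_medium,
                        t_hours = config$scene_t_hours,
                        seed = config$seed, params = params)
    axis <- default_axis("FTIRMicro")
    axis <- axis[axis >= config$image_axis_range[1] &
                 axis <= config$image_axis_range[2]]
    img <- simulate_hyperspectral_image(scene, "FTIRMicro",
                                        seed = config$seed, axis = axis)
    img$valid_mask <- remove_empty_pixels(img)
    binned <- bin_image(img)
    basis <- derive_basis(img, k = config$basis_k, seed = config$seed)
    fit <- basis_fit(img, basis, valid_only = TRUE)
    list(image = img, binned = binned, basis = basis, fit = fit,
         lipid_map = absorbance_map(img, 1745))
  })

  log <- list(
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "out_dir")]),
    recipes = lapply(config$recipes, function(r) all_recipes[[r]]$steps),
    package_version = as.character(utils::packageVersion("isoflux")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  report <- structure(list(sim = sim, preprocessed = pre,
                           trajectories = traj, cpca = cpca,
                           imaging = imaging, log = log),
                      class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    for (mod in names(sim)) {
      write_wide_csv(sim[[mod]], file.path(od, paste0("raw_", mod, ".csv")))
      write_wide_csv(pre[[mod]], file.path(od, paste0("pre_", mod, ".csv")))
      write_trajectories(traj[[mod]],
                         file.path(od, paste0("trajectories_", mod, ".tsv")))
    }
    utils::write.table(
      data.frame(sample = seq_len(nrow(cpca$global_scores)),
                 cpca$global_scores),
      file.path(od, "cpca_global_scores.tsv"), sep = "\t", row.names = FALSE)
    write_cube(imaging$image, file.path(od, "image_cube.f64"))
    log_noconfigfun <- log
    jsonlite::write_json(log_noconfigfun, file.path(od, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  bulk modalities: %s (%d spectra each)\n",
              paste(names(x$sim), collapse = ", "), n_spectra(x$sim[[1]])))
  cat(sprintf("  CPCA: %d blocks, %d components; global %%var: %s\n",
              length(x$cpca$block_loadings), x$cpca$ncomp,
              paste(sprintf("%.1f", x$cpca$pct_variance_global), collapse = ", ")))
  cat(sprintf("  imaging: %d x %d pixels, %d blocks binned, %d basis components\n",
              dim(x$imaging$image$cube)[1], dim(x$imaging$image$cube)[2],
              n_spectra(x$imaging$binned), dim(x$imaging$fit$factors)[3]))
  invisible(x)
}
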