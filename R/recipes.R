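#' Packaged preprocessing recipes
#'
#' The seven named per-modality procedures, each an ordered list of steps
#' with the exact published parameters:
#' \describe{
#'   \item{htsftir_bandratio}{truncate 1800-800; linear baseline; band-area
#'     normalise 1670-1600 (amide I); SG(poly 2, window 15, deriv 2). For
#'     amide-I-relative estimates of the lipid ester C=O (1746/1700) and
#'     polyphosphate P=O (1263) band intensities.}
#'   \item{htsftir_mva}{SG(2, 11, 2); truncate 3200-2600 and 2000-600; MSC.
#'     For PCA/CPCA.}
#'   \item{ftraman_bandratio}{SG(2, 15, 2); truncate 3200-2500 and
#'     1800-600; MSC. For CH2 (2855) and carotenoid C=C (1525) estimates.}
#'   \item{ftraman_mva}{rubberband; SG(2, 11, 2); truncate 1800-400; vector
#'     normalise. For PCA/CPCA.}
#'   \item{ftraman_plsr}{SG smoothing (2, 15, deriv 0); rubberband;
#'     truncate 3200-2400 and 1900-500; EMSC degree 3. For PLSR
#'     calibration.}
#'   \item{ramanmicro_point}{cosmic ray removal; rubberband; truncate
#'     1800-400; area normalise.}
#'   \item{ramanmicro_image}{cosmic ray removal; polynomial baseline;
#'     truncate 1800-400.}
#'   \item{ftirmicro_mva}{SG(2, 9, 2); EMSC degree 2 with the mean of all
#'     block spectra as reference. Applied to binned block spectra after
#'     pixel quality control ([remove_empty_pixels()] and [bin_image()],
#'     which operate on the image, not the dataset).}
#' }
#'
#' @return named list of recipes; each recipe is a list with \code{name}
#'   and \code{steps} (ordered list of \code{list(step, ...params)})
#' @export
packaged_recipes <- function() {
  r <- list(
    htsftir_bandratio = list(
      list(step = "truncate", regions = list(c(800, 1800))),
      list(step = "linear_baseline"),
      list(step = "band_area_normalize", region = c(1600, 1670)),
      list(step = "savgol", window = 15, polyorder = 2, deriv = 2)
    ),
    htsftir_mva = list(
      list(step = "savgol", window = 11, polyorder = 2, deriv = 2),
      list(step = "truncate", regions = list(c(2600, 3200), c(600, 2000))),
      list(step = "msc", reference = "mean")
    ),
    ftraman_bandratio = list(
      list(step = "savgol", window = 15, polyorder = 2, deriv = 2),
      list(step = "truncate", regions = list(c(2500, 3200), c(600, 1800))),
      list(step = "msc", reference = "mean")
    ),
    ftraman_mva = list(
      list(step = "rubberband"),
      list(step = "savgol", window = 11, polyorder = 2, deriv = 2),
      list(step = "truncate", regions = list(c(400, 1800))),
      list(step = "vector_normalize")
    ),
    ftraman_plsr = list(
      list(step = "savgol", window = 15, polyorder = 2, deriv = 0),
      list(step = "rubberband"),
      list(step = "truncate", regions = list(c(2400, 3200), c(500, 1900))),
      list(step = "emsc", poly_degree = 3, reference = "mean")
    ),
    ramanmicro_point = list(
      list(step = "cosmic_ray"),
      list(step = "rubberband"),
      list(step = "truncate", regions = list(c(400, 1800))),
      list(step = "area_normalize")
    ),
    ramanmicro_image = list(
      list(step = "cosmic_ray"),
      list(step = "polynomial_baseline", degree = 3),
      list(step = "truncate", regions = list(c(400, 1800)))
    ),
    ftirmicro_mva = list(
      list(step = "savgol", window = 9, polyorder = 2, deriv = 2),
      list(step = "emsc", poly_degree = 2, reference = "mean")
    )
  )
  lapply(stats::setNames(names(r), names(r)),
         function(nm) structure(list(name = nm, steps = r[[nm]]),
                                class = "preprocess_recipe"))
}

step_registry <- function() {
  list(
    truncate = function(ds, regions) truncate_regions(ds, regions),
    linear_baseline = function(ds) linear_baseline(ds),
    rubberband = function(ds) rubberband_baseline(ds),
    polynomial_baseline = function(ds, degree = 3) polynomial_baseline(ds, degree),
    savgol = function(ds, window, polyorder, deriv) savgol(ds, window, polyorder, deriv),
    msc = function(ds, reference = "mean") msc(ds, reference),
    emsc = function(ds, poly_degree = 2, reference = "mean") emsc(ds, reference, poly_degree),
    vector_normalize = function(ds) vector_normalize(ds),
    area_normalize = function(ds) area_normalize(ds),
    band_area_normalize = function(ds, region = c(1600, 1670)) band_area_normalize(ds, region),
    cosmic_ray = function(ds, z_thresh = 8) cosmic_ray_remove(ds, z_thresh)
  )
}

#' Apply a named preprocessing recipe to a dataset
#'
#' Steps are applied strictly in the recipe's printed order. The input must
#' be raw (derivative order 0): re-applying a derivative recipe to an
#' already-derived dataset is rejected.
#'
#' @param x spectrum or spectral_dataset
#' @param recipe recipe name (see [packaged_recipes()]) or a recipe object
#' @return preprocessed object; attribute \code{recipe} records the name
#' @export
#' @examples
#' sim <- simulate_design_dataset(default_design(media = "nGlu",
#'   modalities = "HTSFTIR"), seed = 1)
#' out <- apply_recipe(sim$HTSFTIR, "htsftir_bandratio")
#' range(out$wavenumber); out$derivative_order
apply_recipe <- function(x, recipe) {
  if (is.character(recipe)) {
    all <- packaged_recipes()
    if (!recipe %in% names(all)) stop("unknown recipe: ", recipe)
    recipe <- all[[recipe]]
  }
  stopifnot(inherits(recipe, "preprocess_recipe"))
  reg <- step_registry()
  run <- function(ds) {
    if (ds$derivative_order != 0) {
      stop("recipe '", recipe$name,
           "' expects raw spectra (derivative order 0), got order ",
           ds$derivative_order)
    }
    for (st in recipe$steps) {
      fn <- reg[[st$step]]
      if (is.null(fn)) stop("unknown step '", st$step, "' in recipe ", recipe$name)
      args <- st[names(st) != "step"]
      ds <- tryCatch(do.call(fn, c(list(ds), args)),
                     error = function(e) stop("recipe '", recipe$name,
                                              "', step '", st$step, "': ",
                                              conditionMessage(e), call. = FALSE))
    }
    attr(ds, "recipe") <- recipe$name
    ds
  }
  dispatch_spectral(x, run)
}

#' Serialize / restore a recipe as a text configuration
#'
#' @param recipe recipe object
#' @param path file to write (YAML)
#' @return \code{read_recipe} returns a recipe object
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "preprocess_recipe"))
  yaml::write_yaml(list(name = recipe$name, steps = recipe$steps), path)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  obj <- yaml::read_yaml(path)
  steps <- lapply(obj$steps, function(st) {
    if (!is.null(st[["regions"]])) st[["regions"]] <- lapply(st[["regions"]], unlist)
    if (!is.null(st[["region"]])) st[["region"]] <- unlist(st[["region"]])
    st
  })
  structure(list(name = obj$name, steps = steps), class = "preprocess_recipe")
}
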