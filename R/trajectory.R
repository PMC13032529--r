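#' Fermentation-timeline composition model
#'
#' Encodes the qualitative carbon-utilisation timeline of a nitrogen-limited
#' Mucor circinelloides fermentation as a parametric forward model that maps
#' (medium, time) to a biomass composition with per-metabolite 13C
#' fractions:
#' \itemize{
#'   \item protein and carbohydrate (from the 12C yeast extract plus early
#'     glucose consumption) dominate the first 8 h;
#'   \item carotenoids pulse between 8 and 14 h and then decline; in media
#'     combining 13C glucose with a large glycerol surplus the carotenoid
#'     pool is isotopically mixed and its 13C fraction is drawn from a
#'     continuum (the single carotenoid band then sits anywhere between the
#'     pure-isotope positions);
#'   \item TAG lipids grow with available glucose (saturating in the
#'     glucose concentration), are depleted after glucose exhaustion when
#'     glucose is scarce, and grow again from glycerol after ~36 h only when
#'     glycerol is in large surplus alongside some glucose;
#'   \item polyphosphates rise and then decline, peaking around 24 h on
#'     glycerol-only medium, around 60 h under a glycerol surplus, and
#'     accumulating to the end of fermentation when glucose is plentiful;
#'   \item glycerol-only medium accumulates a negligible amount of TAG.
#' }
#' All rate constants live in [trajectory_params()] and are overridable; the
#' published timeline is qualitative, so the defaults are model choices, not
#' measured values.
#'
#' @name trajectory-model
NULL

#' Default trajectory parameters
#'
#' @param ... named overrides of the defaults
#' @return named list of parameters. Times in hours, concentrations in g/L,
#'   weights unitless relative to protein = 1.
#' @export
trajectory_params <- function(...) {
  p <- list(
    protein_base = 1.0,       # protein weight (the normalisation reference)
    carb_base = 0.8,          # carbohydrate weight
    lipid_amp = 2.5,          # max TAG weight at glucose saturation
    lipid_onset_h = 8,        # lipogenesis start
    lipid_tau_h = 20,         # lipid accumulation time constant
    lipid_sat_K = 10,         # glucose half-saturation (g/L) for TAG capacity
    gluc_scarce_gpl = 10,     # glucose <= this is exhausted mid-run
    gluc_exhaust_h = 24,      # exhaustion time for scarce glucose
    lipid_decay_tau_h = 15,   # TAG depletion time constant after exhaustion
    glyc_surplus_gpl = 30,    # glycerol >= this counts as large surplus
    glyc_lipid_amp = 0.6,     # max TAG weight from glycerol under surplus
    glyc_lipid_onset_h = 36,  # glycerol lipogenesis start
    glyc_lipid_tau_h = 25,
    gly_only_lipid_amp = 0.01,# TAG ceiling on glycerol-only medium
    negligible_lipid = 0.02,
    yeast_lipid = 0.005,      # residual 12C TAG from yeast extract
    caro_amp = 0.12,
    caro_onset_h = 8, caro_rise_tau_h = 3, caro_decay_tau_h = 40,
    caro_mix_lo = 0.15, caro_mix_hi = 0.85, # mixed-isotope continuum bounds
    caro_f13_max = 0.9,       # yeast-extract 12C dilution of carotenoids
    polyp_amp_rich = 0.5,     # polyP plateau, glucose-rich media
    polyp_amp_limited = 0.9,  # polyP plateau when glucose is limited/absent
    polyp_onset_h = 8, polyp_rise_tau_h = 10,
    polyp_peak_gly_h = 24, polyp_peak_surplus_h = 60,
    polyp_decay_tau_h = 30,
    prot_f13_frac = 0.25, carb_f13_frac = 0.5, # late 13C incorporation caps
    f13_tau_h = 30
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown trajectory parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

ramp <- function(t, t0, tau) ifelse(t <= t0, 0, 1 - exp(-(t - t0) / tau))
decay_after <- function(t, t0, tau) ifelse(t <= t0, 1, exp(-(t - t0) / tau))

#' Composition of the biomass at a given fermentation time
#'
#' @param medium medium name from [media_table()]
#' @param t_hours time since inoculation (h), >= 0
#' @param params trajectory parameters ([trajectory_params()])
#' @return object of class \code{composition}: list with \code{weight}
#'   (named numeric, metabolite weights relative to protein) and \code{f13}
#'   (named numeric, per-metabolite 13C fraction). For media combining 13C
#'   glucose with a large glycerol surplus the carotenoid f13 is drawn from
#'   a uniform mixing continuum using the current RNG stream.
#' @export
#' @examples
#' composition_trajectory("nGlu", 60)
composition_trajectory <- function(medium, t_hours,
                                   params = trajectory_params()) {
  stopifnot(t_hours >= 0)
  m <- medium_spec(medium)
  p <- params
  G <- m$glucose12 + m$glucose13
  share13 <- if (G > 0) m$glucose13 / G else 0
  surplus <- m$glycerol >= p$glyc_surplus_gpl && G > 0
  gly_only <- G == 0 && m$glycerol > 0

  ## --- TAG pools (12C and 13C tracked separately) ---
  if (gly_only) {
    glu_pool <- 0
    gly_pool <- p$gly_only_lipid_amp * ramp(t_hours, p$lipid_onset_h, p$lipid_tau_h)
  } else {
    amp <- p$lipid_amp * G / (G + p$lipid_sat_K)
    rise <- ramp(pmin(t_hours, if (G <= p$gluc_scarce_gpl) p$gluc_exhaust_h else Inf),
                 p$lipid_onset_h, p$lipid_tau_h)
    dep <- if (G <= p$gluc_scarce_gpl) {
      decay_after(t_hours, p$gluc_exhaust_h, p$lipid_decay_tau_h)
    } else 1
    glu_pool <- amp * rise * dep
    gly_pool <- if (surplus) {
      p$glyc_lipid_amp * (m$glycerol / 40) *
        ramp(t_hours, p$glyc_lipid_onset_h, p$glyc_lipid_tau_h)
    } else 0
  }
  yeast_pool <- p$yeast_lipid * ramp(t_hours, p$lipid_onset_h, p$lipid_tau_h)
  tag12 <- glu_pool * (1 - share13) + gly_pool + yeast_pool
  tag13 <- glu_pool * share13
  tag_w <- tag12 + tag13
  tag_f13 <- if (tag_w > 0) tag13 / tag_w else 0

  ## --- carotenoids ---
  caro_w <- p$caro_amp * ramp(t_hours, p$caro_onset_h, p$caro_rise_tau_h) *
    decay_after(t_hours, p$caro_onset_h + 2 * p$caro_rise_tau_h,
                p$caro_decay_tau_h)
  caro_f13 <- if (surplus && m$glucose13 > 0) {
    stats::runif(1, p$caro_mix_lo, p$caro_mix_hi)
  } else {
    p$caro_f13_max * share13
  }

  ## --- polyphosphates ---
  peak_h <- if (gly_only) p$polyp_peak_gly_h
            else if (surplus) p$polyp_peak_surplus_h
            else Inf
  polyp_amp <- if (G >= 2 * p$gluc_scarce_gpl) p$polyp_amp_rich else p$polyp_amp_limited
  polyp_w <- polyp_amp * ramp(t_hours, p$polyp_onset_h, p$polyp_rise_tau_h) *
    decay_after(t_hours, peak_h, p$polyp_decay_tau_h)

  ## --- protein and carbohydrate (dominant early, 12C yeast extract) ---
  late <- ramp(t_hours, p$lipid_onset_h, p$f13_tau_h)
  prot_f13 <- p$prot_f13_frac * share13 * late
  carb_f13 <- p$carb_f13_frac * share13 * late

  structure(list(
    weight = c(protein = p$protein_base, carbohydrate = p$carb_base,
               TAG = tag_w, polyphosphate = polyp_w, carotenoid = caro_w),
    f13 = c(protein = prot_f13, carbohydrate = carb_f13, TAG = tag_f13,
            polyphosphate = 0, carotenoid = caro_f13),
    medium = medium, t_hours = t_hours
  ), class = "composition")
}

#' Construct a composition directly
#'
#' @param weight named nonnegative metabolite weights (at least one > 0)
#' @param f13 named 13C fractions in [0, 1]; missing metabolites default 0
#' @return composition object
#' @export
composition <- function(weight, f13 = NULL) {
  weight <- unlist(weight)
  if (any(weight < 0)) stop("weights must be nonnegative")
  if (!any(weight > 0)) stop("at least one weight must be positive")
  out <- stats::setNames(numeric(length(weight)), names(weight))
  if (!is.null(f13)) {
    f13 <- unlist(f13)
    if (any(f13 < 0 | f13 > 1)) stop("f13 must lie in [0, 1]")
    out[names(f13)] <- f13
  }
  structure(list(weight = weight, f13 = out), class = "composition")
}
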