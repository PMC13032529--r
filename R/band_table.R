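#' Default band table: metabolite marker bands with 12C and 13C positions
#'
#' Returns the packaged assignment table of vibrational marker bands for the
#' principal constituents of oleaginous fungal biomass: triacylglycerol
#' storage lipids (TAG), proteins, cell-wall carbohydrates, polyphosphates
#' and carotenoids. Each row gives the band centre for biomass built from
#' standard carbon (\code{center12}) and, where resolvable, the red-shifted
#' centre for fully 13C-labelled material (\code{center13}).  Polyphosphate
#' bands carry no carbon and therefore have no 13C partner; their intensity
#' is isotope-insensitive.  Carotenoids are only observable by Raman (their
#' concentration in fungal biomass is too low for infrared detection), and
#' carry the \code{interpolate_position} isotope mode: a mixed-isotope
#' carotenoid population produces a single band that slides continuously
#' between the 12C and 13C positions rather than a two-band mixture.
#'
#' The densely overlapped C-H stretching/deformation multiplets are only
#' partially encoded: positions whose 12C/13C pairing could not be resolved
#' unambiguously from the published assignment table are omitted, except the
#' Raman CH2 stretch at 2855 cm^-1 (the standard lipid marker), which is
#' paired with 2846 cm^-1.  Band widths and relative intensities are not
#' published; the defaults are typical condensed-phase values (FWHM
#' 10-25 cm^-1 by band class) and may be overridden by editing the returned
#' data frame.
#'
#' @return data frame with columns \code{metabolite}, \code{modality_class}
#'   (\code{"raman"} or \code{"ir"}), \code{vibration}, \code{center12},
#'   \code{center13} (NA when no 13C partner), \code{fwhm},
#'   \code{rel_intensity}, \code{shape}, \code{eta} (pseudo-Voigt Lorentzian
#'   fraction), \code{isotope_mode}
#' @export
#' @examples
#' bt <- default_band_table()
#' band_lookup(bt, "TAG", "HTSFTIR")
default_band_table <- function() {
  row <- function(met, cls, vib, c12, c13, fwhm, rel,
                  mode = "two_bands") {
    data.frame(metabolite = met, modality_class = cls, vibration = vib,
               center12 = c12, center13 = c13, fwhm = fwhm,
               rel_intensity = rel, shape = "pseudo_voigt", eta = 0.7,
               isotope_mode = mode, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    ## TAG lipids -- Raman
    row("TAG", "raman", "=C-H stretching",            3010, 2995, 20, 0.30),
    row("TAG", "raman", "C-H stretching CH3/CH2",     2930, 2918, 22, 1.00),
    row("TAG", "raman", "C-H stretching CH2 (sym)",   2900, 2886, 22, 0.50),
    row("TAG", "raman", "CH2 stretching",             2855, 2846, 20, 0.90),
    row("TAG", "raman", "C=O stretching esters",      1747, 1705, 14, 0.55),
    row("TAG", "raman", "C=C stretching",             1656, 1598, 14, 0.45),
    row("TAG", "raman", "C-C and C-O stretching",     1081, 1055, 14, 0.25),
    ## TAG lipids -- IR
    row("TAG", "ir", "=C-H stretching",               3010, 2994, 20, 0.10),
    row("TAG", "ir", "C-H stretching CH3/CH2",        2925, 2915, 22, 0.80),
    row("TAG", "ir", "C-H stretching (asym CH3)",     2958, 2948, 20, 0.40),
    row("TAG", "ir", "C=O stretching esters",         1745, 1701, 15, 1.00),
    row("TAG", "ir", "C-O-C stretching",              1155, 1135, 16, 0.30),
    row("TAG", "ir", "C-O-C stretching (2)",          1066, 1040, 16, 0.20),
    ## Proteins -- Raman
    row("protein", "raman", "amide I C=O stretching", 1660, 1624, 22, 0.35),
    row("protein", "raman", "C=C phenyl ring",        1605, 1565, 12, 0.15),
    row("protein", "raman", "phenyl ring deformation",1005,  966, 10, 0.30),
    row("protein", "raman", "C-H stretching",         2930, 2918, 25, 0.40),
    ## Proteins -- IR
    row("protein", "ir", "amide I C=O stretching",    1640, 1615, 25, 1.00),
    row("protein", "ir", "amide II N-H/C-N",          1550, 1540, 22, 0.60),
    row("protein", "ir", "C-H stretching",            2925, 2915, 25, 0.30),
    ## Cell wall carbohydrates -- Raman
    row("carbohydrate", "raman", "C-C/C-O/C-O-C comb",1127, 1095, 20, 0.60),
    row("carbohydrate", "raman", "amide I (chitin)",  1650, 1625, 20, 0.30),
    row("carbohydrate", "raman", "C=O esters (glucuronans)", 1745, 1705, 14, 0.10),
    row("carbohydrate", "raman", "C-H stretching",    2930, 2918, 25, 0.40),
    ## Cell wall carbohydrates -- IR
    row("carbohydrate", "ir", "C-O stretching",       1080, 1051, 20, 0.80),
    row("carbohydrate", "ir", "C-O-C/COH deformation",1036, 1013, 18, 0.60),
    row("carbohydrate", "ir", "C-O-C stretching",     1155, 1135, 18, 0.40),
    row("carbohydrate", "ir", "amide I (chitin)",     1650, 1615, 22, 0.50),
    row("carbohydrate", "ir", "C=O esters (glucuronans)", 1745, 1705, 15, 0.10),
    ## Polyphosphates (no carbon: no 13C partner, isotope-insensitive)
    row("polyphosphate", "raman", "P=O stretching",    1170, NA, 18, 1.00),
    row("polyphosphate", "raman", "P-O-P stretching",   700, NA, 20, 0.40),
    row("polyphosphate", "ir", "P=O stretching",       1268, NA, 18, 1.00),
    row("polyphosphate", "ir", "P-O stretching",       1084, NA, 18, 0.80),
    row("polyphosphate", "ir", "P-O-P stretching",      886, NA, 20, 0.50),
    ## Carotenoids -- Raman only ("not detectable" by IR); the mixed-isotope
    ## population slides continuously between the 12C and 13C positions.
    row("carotenoid", "raman", "-C=C- stretching",     1523, 1490, 14, 1.00,
        mode = "interpolate_position"),
    row("carotenoid", "raman", "-C-C- stretching/CH def", 1157, 1124, 14, 0.60,
        mode = "interpolate_position")
  )
  class(tab) <- c("band_table", "data.frame")
  tab
}

#' Position aliases used in figure captions
#'
#' A few marker positions are quoted in the literature at slightly different
#' wavenumbers than the assignment table (carotenoid 1525 vs 1523,
#' polyphosphate P=O 1263 vs 1268, TAG ester 1746/1700 vs 1745/1701). The
#' canonical table positions are used by the generator; these aliases are
#' accepted by [band_lookup()] when searching by position.
#' @return data frame with columns \code{alias}, \code{canonical}
#' @export
band_position_aliases <- function() {
  data.frame(alias = c(1525, 1263, 1746, 1700),
             canonical = c(1523, 1268, 1745, 1701))
}

modality_class <- function(modality) {
  modality <- match_modality(modality)
  if (modality %in% c("FTRaman", "RamanMicro")) "raman" else "ir"
}

#' Look up the bands of a metabolite for a modality
#'
#' @param band_table band table as from [default_band_table()]
#' @param metabolite one of TAG, protein, carbohydrate, polyphosphate,
#'   carotenoid
#' @param modality instrument modality (see [modalities()]); mapped to its
#'   Raman/IR band class
#' @param position optional wavenumber: restrict to the band whose
#'   \code{center12} matches (aliases of [band_position_aliases()] accepted)
#' @return data frame of matching bands (possibly empty, e.g. carotenoid
#'   bands under an infrared modality)
#' @export
band_lookup <- function(band_table, metabolite, modality, position = NULL) {
  cls <- modality_class(modality)
  hit <- band_table[band_table$metabolite == metabolite &
                    band_table$modality_class == cls, , drop = FALSE]
  if (!is.null(position)) {
    al <- band_position_aliases()
    j <- match(position, al$alias)
    if (!is.na(j)) position <- al$canonical[j]
    hit <- hit[abs(hit$center12 - position) < 0.5, , drop = FALSE]
  }
  rownames(hit) <- NULL
  hit
}

#' Validate a band table
#'
#' Checks the red-shift rule (13C centre strictly below the 12C centre) and
#' positive widths/intensities.
#' @param band_table data frame in the [default_band_table()] layout
#' @return invisible TRUE, or an error
#' @export
validate_band_table <- function(band_table) {
  paired <- !is.na(band_table$center13)
  if (any(band_table$center13[paired] >= band_table$center12[paired])) {
    stop("13C band centres must be red-shifted below the 12C centres")
  }
  if (any(band_table$fwhm <= 0)) stop("band widths must be positive")
  if (any(band_table$rel_intensity < 0)) stop("relative intensities must be >= 0")
  if (any(band_table$eta < 0 | band_table$eta > 1)) stop("eta must lie in [0,1]")
  invisible(TRUE)
}
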