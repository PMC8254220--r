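#' DNS xylanase assay geometry
#'
#' The reducing-sugar end-point assay layout used for volumetric xylanase
#' activities: 175 uL xylan substrate suspension plus 25 uL cell-free
#' supernatant (200 uL total), incubated 30 min at 30 degC; one unit (U) is
#' the enzyme releasing 1 umol of reducing sugar per minute.
#'
#' @param substrate_volume_uL,sample_volume_uL,incubation_time_min,temperature_C
#'   assay geometry; defaults as above.
#' @return list of class `assay_config`; `total_volume_uL` is the sum of the
#'   two volumes.
#' @export
assay_config <- function(substrate_volume_uL = 175, sample_volume_uL = 25,
                         incubation_time_min = 30, temperature_C = 30) {
  stopifnot(substrate_volume_uL > 0, sample_volume_uL > 0,
            incubation_time_min > 0)
  structure(list(
    substrate_volume_uL = substrate_volume_uL,
    sample_volume_uL = sample_volume_uL,
    total_volume_uL = substrate_volume_uL + sample_volume_uL,
    incubation_time_min = incubation_time_min,
    temperature_C = temperature_C
  ), class = "assay_config")
}

#' Fit a DNS standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through the calibration points.
#'
#' @param concentration_mM,absorbance calibration points (>= 2 distinct
#'   concentrations).
#' @return list of class `standard_curve` with `slope` (absorbance per mM),
#'   `intercept` (absorbance) and `r_squared`.
#' @export
fit_standard_curve <- function(concentration_mM, absorbance) {
  stopifnot(length(concentration_mM) == length(absorbance))
  if (length(concentration_mM) < 2L || length(unique(concentration_mM)) < 2L) {
    stop("need at least 2 points with distinct concentrations")
  }
  fit <- lm(absorbance ~ concentration_mM)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  ), class = "standard_curve")
}

#' Reducing-sugar concentration from absorbance
#'
#' Inverts the standard curve: `(absorbance - blank - intercept) / slope`,
#' floored at 0 with a warning when the blank-corrected absorbance falls
#' below the intercept.
#'
#' @param absorbance measured absorbance(s).
#' @param curve a [fit_standard_curve()] object.
#' @param blank_absorbance blank to subtract (default 0).
#' @return reducing-sugar concentration in mM.
#' @export
reducing_sugar_mM <- function(absorbance, curve, blank_absorbance = 0) {
  stopifnot(inherits(curve, "standard_curve"), curve$slope > 0)
  conc <- (absorbance - blank_absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative concentration(s) floored at 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Volumetric enzyme activity from reducing-sugar concentration
#'
#' Converts mM reducing sugar released in the assay to volumetric activity:
#' multiply by the total assay volume (L), divide by the assay time (min),
#' then divide by the sample volume (L). Dimensionally
#' mmol/L * L / min / L = umol / min / mL = U/mL.
#'
#' @param conc_mM reducing sugar released (mM).
#' @param total_volume_L total assay volume in litres.
#' @param time_min assay time in minutes.
#' @param sample_volume_L sample volume in litres.
#' @return activity in U per mL.
#' @examples
#' volumetric_activity(1, 200e-6, 30, 25e-6)  # 0.2667 U/mL
#' @export
volumetric_activity <- function(conc_mM, total_volume_L, time_min,
                                sample_volume_L) {
  if (total_volume_L <= 0 || time_min <= 0 || sample_volume_L <= 0) {
    stop("volumes and time must be positive")
  }
  stopifnot(all(conc_mM >= 0))
  conc_mM * total_volume_L / time_min / sample_volume_L
}

#' Classify growth from optical density
#'
#' A culture counts as growing iff its OD600 reaches the threshold
#' (inclusive at 0.2 by default).
#'
#' @param od600 optical density value(s), >= 0.
#' @param threshold growth threshold (default 0.2).
#' @return logical vector.
#' @export
classify_growth <- function(od600, threshold = 0.2) {
  stopifnot(threshold > 0)
  if (any(od600 < 0)) stop("negative OD600")
  od600 >= threshold
}

# Average (isotope-abundance-weighted) residue masses in Da, Expasy-style;
# residue = amino acid minus water. Protein mass adds one water per chain.
RESIDUE_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.0153

#' Protein length in residues
#'
#' @param sequence amino-acid string over the 20 canonical letters plus
#'   X/B/Z/U.
#' @return integer residue count; empty or invalid sequences are errors.
#' @export
protein_length <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad) > 0L) {
    stop("invalid amino-acid character '", chars[bad[1]], "' at position ",
         bad[1])
  }
  length(chars)
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). Ambiguity
#' codes (X/B/Z/U) have no defined average mass and are errors.
#'
#' @param sequence amino-acid string over the 20 canonical letters.
#' @return mass in Da.
#' @examples
#' protein_average_mass("G")  # 75.07 Da
#' @export
protein_average_mass <- function(sequence) {
  n <- protein_length(sequence)
  chars <- strsplit(toupper(sequence), "")[[1]]
  amb <- which(chars %in% AA_AMBIGUOUS)
  if (length(amb) > 0L) {
    stop("mass undefined for ambiguity code '", chars[amb[1]],
         "' at position ", amb[1])
  }
  sum(RESIDUE_AVG_MASS[chars]) + WATER_AVG_MASS
}

#' Volumetric activities for a plate of absorbances
#'
#' Convenience wrapper: blank-correct, invert the standard curve and convert
#' to U/mL under the given assay geometry.
#'
#' @param absorbance absorbance values.
#' @param curve a `standard_curve`.
#' @param config an [assay_config()].
#' @param blank_absorbance blank absorbance (default 0).
#' @return data frame `absorbance`, `conc_mM`, `activity_U_per_mL`.
#' @export
plate_activities <- function(absorbance, curve, config = assay_config(),
                             blank_absorbance = 0) {
  conc <- reducing_sugar_mM(absorbance, curve, blank_absorbance)
  act <- volumetric_activity(conc, config$total_volume_uL * 1e-6,
                             config$incubation_time_min,
                             config$sample_volume_uL * 1e-6)
  data.frame(absorbance = absorbance, conc_mM = conc,
             activity_U_per_mL = act)
}
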