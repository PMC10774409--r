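# Amino-sugar biomarker accounting: muramic acid is uniquely bacterial,
# glucosamine mostly fungal (corrected for the bacterial share as 2x the
# molar muramic acid). Conversion constants follow the standard biomarker
# calibration: 45 (muramic acid mass -> bacterial residue C), 179.2 g mol-1
# (glucosamine molar mass), 9 (fungal glucosamine -> fungal residue C).

MURAMIC_MOLAR_MASS <- 251.2  # g mol-1, mass <-> mol bridge (configurable)

#' Assemble amino-sugar profiles
#'
#' One row per sample. Muramic acid is carried in both representations:
#' `muramic_acid_mass` (ug g-1 soil, the bacterial-equation input) and
#' `muramic_acid_mmol` (mmol g-1 soil, the fungal-equation input). If only
#' one is supplied the other is derived through `muramic_molar_mass`
#' (ug g-1 = mmol g-1 x molar mass x 1000).
#'
#' @param df data.frame with `sample_id`, `glucosamine` (mmol g-1),
#'   optionally `galactosamine` (mmol g-1, stored for QC only), and at least
#'   one muramic-acid column.
#' @param muramic_molar_mass g mol-1 used for the unit bridge.
#' @return validated data.frame of class `amino_sugar_profile`, with a
#'   logical `fungal_valid` column flagging rows where
#'   glucosamine >= 2 x muramic (mmol).
#' @export
amino_sugar_profile <- function(df, muramic_molar_mass = MURAMIC_MOLAR_MASS) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "glucosamine") %in% names(df)))
    ws_stop("amino-sugar profile needs sample_id and glucosamine columns")
  has_mass <- "muramic_acid_mass" %in% names(df)
  has_mmol <- "muramic_acid_mmol" %in% names(df)
  if (!has_mass && !has_mmol)
    ws_stop("supply muramic_acid_mass (ug g-1) and/or muramic_acid_mmol (mmol g-1)")
  if (!has_mmol)
    df$muramic_acid_mmol <- df$muramic_acid_mass / (muramic_molar_mass * 1000)
  if (!has_mass)
    df$muramic_acid_mass <- df$muramic_acid_mmol * muramic_molar_mass * 1000
  if (is.null(df$galactosamine)) df$galactosamine <- NA_real_
  num <- c("glucosamine", "galactosamine", "muramic_acid_mass",
           "muramic_acid_mmol")
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  neg <- c("glucosamine", "muramic_acid_mass", "muramic_acid_mmol")
  for (v in neg) if (any(df[[v]] < 0, na.rm = TRUE))
    ws_stop(sprintf("negative %s concentration", v))
  df$fungal_valid <- df$glucosamine >= 2 * df$muramic_acid_mmol - 1e-15
  class(df) <- c("amino_sugar_profile", "data.frame")
  df
}

#' Bacterial residue (necromass) carbon
#'
#' Bacterial residue C = muramic acid x 45, with muramic acid as mass
#' concentration.
#'
#' @param muramic_acid_mass ug g-1 soil.
#' @return ug C g-1 soil.
#' @export
bacterial_residue_c <- function(muramic_acid_mass) {
  if (any(muramic_acid_mass < 0)) ws_stop("muramic acid must be non-negative")
  muramic_acid_mass * 45
}

#' Fungal residue (necromass) carbon
#'
#' Fungal residue C = (mmol glucosamine - 2 x mmol muramic acid) x 179.2 x 9.
#' With inputs in mmol g-1 soil the product is in mg C g-1 soil (179.2 mg
#' mmol-1 x dimensionless 9). Negative glucosamine excess is physically
#' meaningless: the default (strict) mode errors; `clamp = TRUE` clamps to
#' zero with a warning reporting the count.
#'
#' @param glucosamine,muramic_acid_mmol mmol g-1 soil.
#' @param clamp clamp negative excess to zero instead of erroring.
#' @return mg C g-1 soil.
#' @export
fungal_residue_c <- function(glucosamine, muramic_acid_mmol, clamp = FALSE) {
  if (any(glucosamine < 0) || any(muramic_acid_mmol < 0))
    ws_stop("amino-sugar concentrations must be non-negative")
  excess <- glucosamine - 2 * muramic_acid_mmol
  if (any(excess < 0)) {
    if (!clamp)
      ws_stop(sprintf(
        "glucosamine < 2 x muramic acid (mmol) for %d sample(s); negative fungal necromass is invalid (set clamp = TRUE to floor at 0)",
        sum(excess < 0)))
    warning(sprintf("%d negative glucosamine excess value(s) clamped to 0",
                    sum(excess < 0)), call. = FALSE)
    excess <- pmax(excess, 0)
  }
  excess * 179.2 * 9
}

#' Necromass summary per sample
#'
#' Combines the bacterial and fungal conversions and expresses the fungal
#' fraction of total necromass and the contribution of total necromass to
#' SOC. Component pools are harmonized to mg C g-1 soil (the bacterial
#' ug -> mg conversion is applied once here).
#'
#' @param profile an [amino_sugar_profile()].
#' @param soc SOC concentration(s), mg C g-1 soil (scalar or per-row).
#' @param clamp passed to [fungal_residue_c()].
#' @return data.frame of class `necromass_result` with columns `sample_id`,
#'   `bacterial_c`, `fungal_c`, `total_c` (all mg C g-1 soil),
#'   `fungal_fraction` (% of total necromass; NA when total is 0) and
#'   `contribution_to_soc` (% of SOC).
#' @export
summarize_necromass <- function(profile, soc, clamp = FALSE) {
  profile <- if (inherits(profile, "amino_sugar_profile")) profile
             else amino_sugar_profile(profile)
  if (any(!is.finite(soc) | soc <= 0))
    ws_stop("soc must be positive (mg C g-1 soil)")
  soc <- rep_len(soc, nrow(profile))
  bact_mg <- bacterial_residue_c(profile$muramic_acid_mass) / 1000
  fung_mg <- fungal_residue_c(profile$glucosamine, profile$muramic_acid_mmol,
                              clamp = clamp)
  total <- bact_mg + fung_mg
  out <- data.frame(
    sample_id = profile$sample_id,
    bacterial_c = bact_mg,
    fungal_c = fung_mg,
    total_c = total,
    fungal_fraction = ifelse(total > 0, 100 * fung_mg / total, NA_real_),
    contribution_to_soc = 100 * total / soc,
    stringsAsFactors = FALSE)
  class(out) <- c("necromass_result", "data.frame")
  out
}
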