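# Microbial physiology from 18O-H2O incubations: growth from DNA 18O
# enrichment, respiration from headspace CO2 accumulation, CUE = G/(G+R),
# and root-exudation carbon from in-situ cuvette trap measurements.

NAT_ABUNDANCE_18O <- 0.2005  # atom% 18O at natural abundance
R_GAS <- 8.314               # J mol-1 K-1
C_MOLAR_UG <- 12.01e6        # ug C per mol

#' Assemble an isotope-incubation table
#'
#' One row per incubated sample. A labeled tube receives water enriched to
#' `water_label_atpct` atom% 18O (default 30); a parallel natural-abundance
#' tube provides `dna_atpct_control`. Both tubes run for `incubation_hours`
#' (default 48 h).
#'
#' @param df data.frame with columns `sample_id`, `soil_dry_mass` (g),
#'   `dna_total_o` (ug O), `dna_atpct_labeled`, `dna_atpct_control` (atom%),
#'   `co2_delta_ppm` (ppm v/v), `headspace_volume` (L), `headspace_temp` (K);
#'   optional `water_label_atpct` (default 30), `incubation_hours` (default
#'   48), `headspace_pressure` (Pa, default 101325, logged when defaulted).
#' @return validated data.frame of class `isotope_incubation`.
#' @export
isotope_incubation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "soil_dry_mass", "dna_total_o", "dna_atpct_labeled",
           "dna_atpct_control", "co2_delta_ppm", "headspace_volume",
           "headspace_temp")
  miss <- setdiff(req, names(df))
  if (length(miss))
    ws_stop(sprintf("incubation table missing column(s): %s",
                    paste(miss, collapse = ", ")))
  if (is.null(df$water_label_atpct)) df$water_label_atpct <- 30
  if (is.null(df$incubation_hours)) df$incubation_hours <- 48
  if (is.null(df$headspace_pressure)) {
    df$headspace_pressure <- 101325
    message("headspace_pressure not recorded; defaulting to 101325 Pa")
  }
  pos <- c("soil_dry_mass", "headspace_volume", "headspace_temp",
           "headspace_pressure", "incubation_hours")
  for (v in pos) if (any(!is.finite(df[[v]]) | df[[v]] <= 0))
    ws_stop(sprintf("%s must be positive for all incubations", v))
  bad <- df$dna_atpct_control < 0 |
    df$dna_atpct_labeled < df$dna_atpct_control - 1e-12 |
    df$dna_atpct_labeled > df$water_label_atpct + 1e-12
  if (any(bad))
    ws_stop(sprintf(
      "atom%% ordering violated (need 0 <= control <= labeled <= water) for: %s",
      paste(df$sample_id[bad], collapse = ", ")))
  class(df) <- c("isotope_incubation", "data.frame")
  df
}

#' Microbial growth from DNA 18O incorporation
#'
#' Proportional-labeling model: the fraction of DNA oxygen that is newly
#' synthesized during the incubation is the atom% excess of the labeled tube
#' over the natural-abundance control, relative to the excess of the soil
#' water; new DNA-O is converted to biomass C through the user-supplied
#' factor `f_co` (ug microbial biomass C per ug new DNA-O). There is no
#' default for `f_co`: it is soil-specific and must be calibrated.
#'
#' @param inc an [isotope_incubation()] table (or compatible data.frame).
#' @param f_co ug C produced per ug newly synthesized DNA-O; required.
#' @return numeric vector, ug C g-1 dry soil per incubation.
#' @export
compute_growth <- function(inc, f_co = NULL) {
  inc <- if (inherits(inc, "isotope_incubation")) inc else isotope_incubation(inc)
  if (is.null(f_co))
    ws_config_stop(paste(
      "f_co (ug biomass C per ug new DNA-O) must be supplied explicitly;",
      "it is a soil-specific calibration constant with no defensible default"))
  if (!is.numeric(f_co) || any(f_co <= 0))
    ws_config_stop("f_co must be positive")
  new_frac <- (inc$dna_atpct_labeled - inc$dna_atpct_control) /
    (inc$water_label_atpct - inc$dna_atpct_control)
  inc$dna_total_o * new_frac * f_co / inc$soil_dry_mass
}

#' Microbial respiration from headspace CO2 accumulation
#'
#' Converts the CO2 mixing-ratio increase over the incubation to carbon mass
#' via the ideal gas law at the recorded headspace conditions. Negative CO2
#' deltas (blank drift) are clamped to zero with a warning reporting the
#' count.
#'
#' @param inc an [isotope_incubation()] table.
#' @return numeric vector, ug C g-1 dry soil per incubation.
#' @export
compute_respiration <- function(inc) {
  inc <- if (inherits(inc, "isotope_incubation")) inc else isotope_incubation(inc)
  dppm <- inc$co2_delta_ppm
  n_neg <- sum(dppm < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative CO2 delta(s) clamped to 0 (blank drift)",
                    n_neg), call. = FALSE)
    dppm <- pmax(dppm, 0)
  }
  vol_m3 <- inc$headspace_volume * 1e-3
  mol <- inc$headspace_pressure * (dppm * 1e-6 * vol_m3) /
    (R_GAS * inc$headspace_temp)
  mol * C_MOLAR_UG / inc$soil_dry_mass
}

#' Carbon use efficiency
#'
#' CUE = C_growth / (C_growth + C_respiration); uptake is their sum. Both
#' inputs are cumulative over the same incubation.
#'
#' @param growth,respiration non-negative numeric vectors (ug C g-1 soil).
#' @return data.frame of class `cue_result` with columns `c_growth`,
#'   `c_respiration`, `c_uptake`, `cue`.
#' @export
compute_cue <- function(growth, respiration) {
  if (length(growth) != length(respiration))
    ws_stop("growth and respiration must have equal length")
  if (any(growth < 0) || any(respiration < 0))
    ws_stop("growth and respiration must be non-negative")
  both_zero <- growth == 0 & respiration == 0
  if (any(both_zero))
    ws_stop(sprintf("CUE undefined (growth and respiration both zero) for %d element(s)",
                    sum(both_zero)))
  out <- data.frame(
    c_growth = growth,
    c_respiration = respiration,
    c_uptake = growth + respiration,
    cue = growth / (growth + respiration))
  class(out) <- c("cue_result", "data.frame")
  out
}

#' One-call CUE from raw incubation data
#'
#' @inheritParams compute_growth
#' @return a `cue_result` with a `sample_id` column prepended.
#' @export
cue_from_incubation <- function(inc, f_co = NULL) {
  inc <- if (inherits(inc, "isotope_incubation")) inc else isotope_incubation(inc)
  res <- compute_cue(compute_growth(inc, f_co), compute_respiration(inc))
  cbind(data.frame(sample_id = inc$sample_id, stringsAsFactors = FALSE), res)
}

#' Root exudation rate
#'
#' Carbon exuded per unit root biomass and time from a cuvette trap:
#' rate = (delta_c x V) / (G x T).
#'
#' @param delta_c TOC difference, root cuvette minus blank (mg C L-1).
#' @param solution_volume trap solution volume V (L).
#' @param root_mass root weight G (g).
#' @param collection_hours collection time T (h).
#' @return mg C g-1 root h-1.
#' @export
exudation_rate <- function(delta_c, solution_volume, root_mass,
                           collection_hours) {
  if (any(root_mass <= 0)) ws_stop("root_mass must be positive")
  if (any(collection_hours <= 0)) ws_stop("collection_hours must be positive")
  if (any(delta_c < 0) || any(solution_volume < 0))
    ws_stop("delta_c and solution_volume must be non-negative")
  (delta_c * solution_volume) / (root_mass * collection_hours)
}

#' Whole-growth-period root exudation carbon
#'
#' c = (delta_c x V) / (G x T) x S x 24 x d: the hourly areal exudation,
#' scaled by root biomass per area S (g C m-2), 24 h per day, and the length
#' of the growth period d (days). The mg -> g conversion (factor 1/1000) is
#' applied once at the end so the result is in g C m-2 per growth period.
#'
#' @param delta_c mg C L-1; @param solution_volume L; @param root_mass g;
#' @param collection_hours h.
#' @param root_biomass_areal S, g C m-2.
#' @param period_days d, days in the growth period.
#' @param convert_mg_to_g apply the mg -> g conversion (default TRUE).
#' @return g C m-2 period-1 (or mg-scale when `convert_mg_to_g = FALSE`).
#' @export
whole_period_exudation <- function(delta_c, solution_volume, root_mass,
                                   collection_hours, root_biomass_areal,
                                   period_days, convert_mg_to_g = TRUE) {
  if (any(root_biomass_areal < 0) || any(period_days < 0))
    ws_stop("root_biomass_areal and period_days must be non-negative")
  rate <- exudation_rate(delta_c, solution_volume, root_mass,
                         collection_hours)
  out <- rate * root_biomass_areal * 24 * period_days
  if (convert_mg_to_g) out / 1000 else out
}
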