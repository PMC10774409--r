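# Seeded synthetic experiment generator. Emulates the field design
# (2 managements x 2 warming levels x 4 blocks x 6 biennial years,
# 2010-2020; 3 of 4 blocks sequenced) and injects known ground truth:
# geometric-replacement community turnover, a directional warming drift
# under conservation, an SOC warming multiplier from an onset year, and a
# linear warming effect-size trajectory for CUE that crosses zero near
# year 5. Everything is a deterministic-plus-noise function of recorded
# latent values, so the physiology and necromass modules recover the truth
# exactly at noise 0.

default_turnover <- function() {
  data.frame(
    domain = rep(c("bacteria", "fungi"), each = 4),
    management = rep(rep(c("conservation", "conventional"), each = 2), 2),
    warming = rep(c("ambient", "warmed"), 4),
    rho = c(0.10, 0.12, 0.10, 0.10,   # bacteria: slow turnover
            0.30, 0.40, 0.30, 0.30),  # fungi: faster, accelerated by warming
    stringsAsFactors = FALSE)         # under conservation only
}

default_drift <- function() {
  data.frame(
    domain = rep(c("bacteria", "fungi"), each = 2),
    management = rep(c("conservation", "conventional"), 2),
    drift = c(0.010, 0, 0.030, 0),  # per 2-year step, warmed plots only
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' All tunables of the synthetic experiment with the stated-world defaults:
#' 4 blocks, biennial years 2010-2020, 3 sequenced blocks, SOC warming
#' multiplier 1.031 under conservation from onset year 2016, a CUE warming
#' effect-size trajectory with slope 0.83 per year crossing zero at year 5,
#' fungal turnover faster than bacterial and accelerated by warming under
#' conservation.
#'
#' @param seed integer master seed; every stream is derived from it.
#' @param n_blocks number of field blocks.
#' @param years sampling years (strictly increasing; biennial by default).
#' @param sequencing_blocks how many blocks are sequenced (<= n_blocks).
#' @param n_taxa taxa per domain in the regional pool.
#' @param depth sequencing depth per sample (multinomial); `Inf` yields
#'   noise-free relative abundances.
#' @param turnover data.frame (domain, management, warming, rho): fraction
#'   of abundance mass replaced per 2-year step, in \[0, 1).
#' @param drift data.frame (domain, management, drift): per-step directional
#'   shift applied to warmed plots only.
#' @param soc_params,cue_params,growth_params,aminosugar_params,
#'   incubation_constants,noise_sd lists overriding individual defaults
#'   (partial lists allowed).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_blocks = 4,
                             years = seq(2010, 2020, by = 2),
                             sequencing_blocks = 3,
                             n_taxa = 500,
                             depth = 25000,
                             turnover = default_turnover(),
                             drift = default_drift(),
                             soc_params = list(),
                             cue_params = list(),
                             growth_params = list(),
                             aminosugar_params = list(),
                             incubation_constants = list(),
                             noise_sd = list()) {
  soc <- utils::modifyList(list(
    baseline = c(conservation = 16, conventional = 13),   # mg C g-1
    annual_trend = c(conservation = 0.25, conventional = 0.02),
    warming_multiplier = c(conservation = 1.031, conventional = 1.0),
    onset_year = 2016,
    block_sd = 0.4), soc_params)
  cue <- utils::modifyList(list(
    base = 0.30,
    block_sd = 0.01,
    effect_intercept = c(conservation = -4.15, conventional = 0),
    effect_slope = c(conservation = 0.83, conventional = 0)), cue_params)
  growth <- utils::modifyList(list(
    base = 3.0,            # ug C g-1 48 h-1
    block_sd = 0.2,
    annual_trend = 0.05,
    warming_gain_final = c(conservation = 0.43, conventional = 0)),
    growth_params)
  amino <- utils::modifyList(list(
    muramic_mass_base = 50,        # ug g-1
    muramic_annual_rel = 0.01,
    glucosamine_excess_base = 0.005,  # mmol g-1 above the 2x muramic floor
    glucosamine_annual_rel = 0.02,
    warming_gain_final = c(conservation = 0.29, conventional = 0),
    block_sd_rel = 0.05), aminosugar_params)
  inc <- utils::modifyList(list(
    soil_dry_mass = 0.5, dna_total_o = 10, water_label_atpct = 30,
    control_atpct = NAT_ABUNDANCE_18O, headspace_volume = 0.02,
    headspace_temp = 293.15, headspace_pressure = 101325, f_co = 1.8),
    incubation_constants)
  noise <- utils::modifyList(list(
    soc = 0.05, doc = 2, aboveground_biomass = 15,
    dna_atpct = 0.01, co2_ppm = 5,
    glucosamine = 5e-5, muramic = 1), noise_sd)

  if (!is_count(seed)) ws_config_stop("seed must be an integer")
  if (sequencing_blocks > n_blocks)
    ws_config_stop("sequencing_blocks must be <= n_blocks")
  if (any(diff(years) <= 0)) ws_config_stop("years must be strictly increasing")
  if (length(years) < 2) ws_config_stop("need at least 2 sampling years")
  if (any(turnover$rho < 0 | turnover$rho >= 1))
    ws_config_stop("turnover rho must lie in [0, 1)")
  if (any(drift$drift < 0)) ws_config_stop("drift must be >= 0")
  if (any(unlist(noise) < 0)) ws_config_stop("noise_sd values must be >= 0")
  if (!(is.infinite(depth) || (is_count(depth) && depth >= 1)))
    ws_config_stop("depth must be a positive integer or Inf")

  structure(
    list(seed = as.integer(seed), n_blocks = n_blocks, years = years,
         sequencing_blocks = sequencing_blocks, n_taxa = n_taxa,
         depth = depth, turnover = turnover, drift = drift,
         soc_params = soc, cue_params = cue, growth_params = growth,
         aminosugar_params = amino, incubation_constants = inc,
         noise_sd = noise),
    class = "generator_config")
}

#' Generate the factorial study design
#'
#' @param config a [generator_config()].
#' @return a [study_design()] with one sample per (management, warming,
#'   block, year).
#' @export
generate_design <- function(config) {
  g <- expand.grid(year = config$years, block = seq_len(config$n_blocks),
                   warming = WARMING_LEVELS, management = MANAGEMENTS,
                   stringsAsFactors = FALSE)
  g$plot_id <- plot_id(g$management, g$warming, g$block)
  g$sample_id <- sprintf("%s-y%d", g$plot_id, g$year)
  study_design(g[c("sample_id", "plot_id", "block", "management",
                   "warming", "year")])
}

lookup_rho <- function(config, domain, management, warming) {
  t <- config$turnover
  v <- t$rho[t$domain == domain & t$management == management &
               t$warming == warming]
  if (length(v) != 1)
    ws_config_stop(sprintf("no turnover rho for (%s, %s, %s)",
                           domain, management, warming))
  v
}

lookup_drift <- function(config, domain, management) {
  d <- config$drift
  v <- d$drift[d$domain == domain & d$management == management]
  if (length(v) != 1) 0 else v
}

#' Generate one domain's community feature table
#'
#' Per (management, block), a shared initial relative-abundance vector for
#' both warming arms evolves by geometric replacement: at each 2-year step a
#' fraction rho of abundance mass is reassigned to previously unused taxa
#' (so the retained mass shared with the first year is exactly
#' prod(1 - rho) and pairwise similarity decays monotonically with lag).
#' Replacement draws are shared between the paired warming arms of a block;
#' warmed plots under a drifting management are additionally pulled toward a
#' fixed warm-adapted direction, so paired dissimilarity grows with time
#' only when drift > 0 (or the two arms' rho differ). Counts are multinomial
#' at `depth`; `depth = Inf` returns the noise-free relative abundances.
#'
#' @param config a [generator_config()].
#' @param design a [study_design()].
#' @param domain `"bacteria"` or `"fungi"`.
#' @param depth overrides `config$depth` when given.
#' @return a [feature_table()] over the sequenced blocks.
#' @export
generate_communities <- function(config, design, domain = "bacteria",
                                 depth = NULL) {
  depth <- depth %||% config$depth
  if (!(is.infinite(depth) || (is_count(depth) && depth >= 1)))
    ws_config_stop("depth must be a positive integer or Inf")
  n <- config$n_taxa
  years <- config$years
  n_steps <- length(years) - 1
  init_support <- max(2L, round(n * 0.30))
  n_reserved <- max(1L, round(n * 0.04))
  reserved <- (n - n_reserved + 1L):n   # drift-direction taxa only

  # Replacement support size that keeps the community's evenness (sum of
  # sqrt abundances, which sets the multinomial Bray-Curtis noise floor)
  # approximately stationary under geometric replacement at rate rho, so
  # the sampling-noise floor of paired dissimilarities does not trend with
  # time on its own.
  m_new_for <- function(rho) {
    if (rho <= 0) return(0L)
    max(1L, round(init_support * ((1 - sqrt(1 - rho)) / sqrt(rho))^2))
  }

  pfx <- if (domain == "fungi") "F" else "B"
  taxon_ids <- sprintf("%s%04d", pfx, seq_len(n))

  # fixed warm-adapted direction per management
  wdir <- lapply(stats::setNames(MANAGEMENTS, MANAGEMENTS), function(m)
    with_seed(child_seed(config$seed, paste("wdir", domain, m)), {
      v <- numeric(n)
      v[reserved] <- stats::rlnorm(n_reserved)
      v / sum(v)
    }))

  s <- design$samples
  s <- s[s$block <= config$sequencing_blocks, ]
  cols <- list()
  for (m in MANAGEMENTS) for (b in seq_len(config$sequencing_blocks)) {
    rho_a <- lookup_rho(config, domain, m, "ambient")
    rho_w <- lookup_rho(config, domain, m, "warmed")
    dr <- lookup_drift(config, domain, m)
    m_new <- m_new_for(mean(c(rho_a, rho_w)))
    traj <- with_seed(child_seed(config$seed, paste("comm", domain, m, b)), {
      support <- sample(setdiff(seq_len(n), reserved), init_support)
      x <- numeric(n)
      x[support] <- stats::rlnorm(init_support)
      x <- x / sum(x)
      xa <- xw <- x
      used <- x > 0
      out <- list(list(ambient = xa, warmed = xw))
      for (k in seq_len(n_steps)) {
        avail <- which(!used & !(seq_len(n) %in% reserved))
        pick <- if (length(avail) > m_new) sample(avail, m_new)
                else if (m_new > 0) avail else integer(0)
        r <- numeric(n)
        if (length(pick)) {
          r[pick] <- stats::rlnorm(length(pick))
          r <- r / sum(r)
          xa <- (1 - rho_a) * xa + rho_a * r
          xw <- (1 - rho_w) * xw + rho_w * r
        }
        if (dr > 0) xw <- (1 - dr) * xw + dr * wdir[[m]]
        used <- used | xa > 0 | xw > 0
        out[[k + 1]] <- list(ambient = xa, warmed = xw)
      }
      out
    })
    for (w in WARMING_LEVELS) for (t in seq_along(years)) {
      sid <- sprintf("%s-y%d", plot_id(m, w, b), years[t])
      p <- traj[[t]][[w]]
      cols[[sid]] <- if (is.infinite(depth)) p else
        with_seed(child_seed(config$seed, paste("seq", domain, sid)),
                  as.numeric(stats::rmultinom(1, depth, p)))
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- taxon_ids
  mat <- mat[, intersect(s$sample_id, colnames(mat)), drop = FALSE]
  feature_table(mat, relative = is.infinite(depth))
}

#' Generate a taxonomy for one domain's taxa
#'
#' Taxa are assigned to a realistic phylum pool (dominant soil phyla for
#' bacteria; Ascomycota/Basidiomycota-dominated for fungi); ranks below
#' phylum carry the explicit "unclassified" marker.
#'
#' @param config a [generator_config()].
#' @param domain `"bacteria"` or `"fungi"`.
#' @return taxonomy data.frame (see [parse_lineage()]).
#' @export
generate_taxonomy <- function(config, domain = "bacteria") {
  n <- config$n_taxa
  if (domain == "fungi") {
    phyla <- c("Ascomycota", "Basidiomycota", "Mortierellomycota",
               "Chytridiomycota")
    prob <- c(0.55, 0.25, 0.12, 0.08)
    pfx <- "F"
  } else {
    phyla <- c("Proteobacteria", "Acidobacteriota", "Actinobacteriota",
               "Firmicutes", "Bacteroidota", "Verrucomicrobiota",
               "Planctomycetota", "Gemmatimonadota")
    prob <- c(0.25, 0.18, 0.18, 0.10, 0.09, 0.08, 0.07, 0.05)
    pfx <- "B"
  }
  assign <- with_seed(child_seed(config$seed, paste("tax", domain)),
                      sample(phyla, n, replace = TRUE, prob = prob))
  out <- data.frame(
    taxon_id = sprintf("%s%04d", pfx, seq_len(n)),
    domain = if (domain == "fungi") "Fungi" else "Bacteria",
    phylum = assign, class = "unclassified", order = "unclassified",
    family = "unclassified", genus = "unclassified",
    stringsAsFactors = FALSE)
  out
}

# Persistent block effects, shared between warming arms: field plots differ
# spatially and that heterogeneity dominates analytical noise.
block_effects <- function(config, label, sd) {
  eff <- list()
  for (m in MANAGEMENTS) {
    eff[[m]] <- with_seed(child_seed(config$seed, paste("blk", label, m)),
                          stats::rnorm(config$n_blocks, 0, sd))
  }
  eff
}

#' Latent physiology and measurement ground truth
#'
#' Computes every latent (noise-free) quantity per design sample plus the
#' injected parameters, so downstream recovery can be checked exactly.
#'
#' @param config a [generator_config()].
#' @param design a [study_design()].
#' @return object of class `ground_truth`: list with `per_sample` (latent
#'   growth, respiration, cue, soc, amino sugars per sample), `turnover`,
#'   `drift`, `cue_effect` (injected per-year d), `soc_params`, `f_co`,
#'   `block_effects`.
#' @export
generate_truth <- function(config, design) {
  s <- design$samples
  y0 <- min(config$years)
  span <- diff(range(config$years))
  gp <- config$growth_params; cp <- config$cue_params
  sp <- config$soc_params; ap <- config$aminosugar_params

  be_g <- block_effects(config, "growth", gp$block_sd)
  be_c <- block_effects(config, "cue", cp$block_sd)
  be_s <- block_effects(config, "soc", sp$block_sd)
  be_a <- block_effects(config, "amino", ap$block_sd_rel)

  t_rel <- (s$year - y0) / span
  warmed <- s$warming == "warmed"

  # CUE: ambient latent plus an injected effect-size trajectory expressed in
  # units of the realized between-block SD, so Cohen's d across blocks
  # recovers the injected d exactly at noise 0.
  cue_a <- cp$base + vapply(seq_len(nrow(s)), function(i)
    be_c[[s$management[i]]][s$block[i]], numeric(1))
  sd_blk <- vapply(MANAGEMENTS, function(m) stats::sd(be_c[[m]]), numeric(1))
  d_inj <- cp$effect_intercept[s$management] +
    cp$effect_slope[s$management] * (s$year - y0)
  cue <- cue_a + ifelse(warmed, d_inj * sd_blk[s$management], 0)
  cue <- pmin(pmax(cue, 0.02), 0.98)

  growth <- gp$base + gp$annual_trend * (s$year - y0) +
    vapply(seq_len(nrow(s)), function(i)
      be_g[[s$management[i]]][s$block[i]], numeric(1))
  growth <- growth *
    ifelse(warmed, 1 + gp$warming_gain_final[s$management] * t_rel, 1)
  growth <- pmax(growth, 0.01)
  respiration <- growth * (1 / cue - 1)

  soc <- sp$baseline[s$management] + sp$annual_trend[s$management] *
    (s$year - y0) +
    vapply(seq_len(nrow(s)), function(i)
      be_s[[s$management[i]]][s$block[i]], numeric(1))
  soc <- soc * ifelse(warmed & s$year >= sp$onset_year,
                      sp$warming_multiplier[s$management], 1)

  blk_rel <- vapply(seq_len(nrow(s)), function(i)
    be_a[[s$management[i]]][s$block[i]], numeric(1))
  muramic <- ap$muramic_mass_base *
    (1 + ap$muramic_annual_rel * (s$year - y0)) * (1 + blk_rel)
  excess <- ap$glucosamine_excess_base *
    (1 + ap$glucosamine_annual_rel * (s$year - y0)) * (1 + blk_rel)
  excess <- excess *
    ifelse(warmed, 1 + ap$warming_gain_final[s$management] * t_rel, 1)
  muramic <- pmax(muramic, 0)
  excess <- pmax(excess, 0)
  glucosamine <- 2 * muramic / (MURAMIC_MOLAR_MASS * 1000) + excess

  per_sample <- data.frame(
    sample_id = s$sample_id, management = s$management,
    warming = s$warming, block = s$block, year = s$year,
    growth = growth, respiration = respiration, cue = cue,
    soc = unname(soc), muramic_acid_mass = muramic,
    glucosamine = glucosamine, glucosamine_excess = excess,
    stringsAsFactors = FALSE)

  cue_effect <- do.call(rbind, lapply(MANAGEMENTS, function(m)
    data.frame(management = m, year = config$years,
               d_injected = cp$effect_intercept[[m]] +
                 cp$effect_slope[[m]] * (config$years - y0))))

  structure(
    list(per_sample = per_sample, turnover = config$turnover,
         drift = config$drift, cue_effect = cue_effect,
         soc_params = sp, f_co = config$incubation_constants$f_co,
         block_effects = list(growth = be_g, cue = be_c, soc = be_s,
                              amino = be_a)),
    class = "ground_truth")
}

#' Generate raw isotope-incubation measurements
#'
#' Inverts the physiology module: raw DNA-18O and headspace CO2 values are
#' constructed from the latent growth and respiration in `truth`, so that
#' [compute_growth()] / [compute_respiration()] recover them exactly when
#' all noise SDs are zero.
#'
#' @param config a [generator_config()].
#' @param design a [study_design()].
#' @param truth a [generate_truth()] result.
#' @return an [isotope_incubation()] table.
#' @export
generate_incubation <- function(config, design, truth) {
  k <- config$incubation_constants
  ns <- config$noise_sd
  ps <- truth$per_sample
  n <- nrow(ps)
  noise <- with_seed(child_seed(config$seed, "incubation"), list(
    at_c = stats::rnorm(n, 0, ns$dna_atpct),
    at_l = stats::rnorm(n, 0, ns$dna_atpct),
    ppm = stats::rnorm(n, 0, ns$co2_ppm)))
  at_c <- pmax(k$control_atpct + noise$at_c, 0)
  new_frac <- ps$growth * k$soil_dry_mass / (k$f_co * k$dna_total_o)
  at_l <- at_c + new_frac * (k$water_label_atpct - at_c) + noise$at_l
  at_l <- pmin(pmax(at_l, at_c), k$water_label_atpct)
  vol_m3 <- k$headspace_volume * 1e-3
  ppm <- ps$respiration * k$soil_dry_mass / C_MOLAR_UG *
    R_GAS * k$headspace_temp / (k$headspace_pressure * vol_m3) / 1e-6
  ppm <- ppm + noise$ppm
  isotope_incubation(data.frame(
    sample_id = ps$sample_id,
    soil_dry_mass = k$soil_dry_mass,
    incubation_hours = 48,
    water_label_atpct = k$water_label_atpct,
    dna_total_o = k$dna_total_o,
    dna_atpct_labeled = at_l,
    dna_atpct_control = at_c,
    co2_delta_ppm = ppm,
    headspace_volume = k$headspace_volume,
    headspace_temp = k$headspace_temp,
    headspace_pressure = k$headspace_pressure,
    stringsAsFactors = FALSE))
}

#' Generate measurement table and amino-sugar profiles
#'
#' SOC (and auxiliary DOC / aboveground biomass) per sample, plus
#' amino-sugar profiles. Noise on glucosamine is applied to the excess above
#' the 2 x muramic floor and floored at zero, so generated profiles always
#' satisfy the fungal-conversion precondition.
#'
#' @param config a [generator_config()].
#' @param design a [study_design()].
#' @param truth a [generate_truth()] result.
#' @return list with `measurements` (a [measurement_table()]) and
#'   `aminosugars` (an [amino_sugar_profile()]).
#' @export
generate_measurements <- function(config, design, truth) {
  ps <- truth$per_sample
  ns <- config$noise_sd
  n <- nrow(ps)
  y0 <- min(config$years)
  noise <- with_seed(child_seed(config$seed, "measure"), list(
    soc = stats::rnorm(n, 0, ns$soc),
    doc = stats::rnorm(n, 0, ns$doc),
    agb = stats::rnorm(n, 0, ns$aboveground_biomass),
    glu = stats::rnorm(n, 0, ns$glucosamine),
    mur = stats::rnorm(n, 0, ns$muramic)))
  doc_lat <- 4 * ps$soc + 10   # DOC tracks SOC (mg C kg-1 scale)
  agb_lat <- 600 + 15 * (ps$year - y0) +
    ifelse(ps$warming == "warmed" & ps$management == "conservation", 40, 0)
  measurements <- measurement_table(
    data.frame(sample_id = ps$sample_id,
               soc = ps$soc + noise$soc,
               doc = doc_lat + noise$doc,
               aboveground_biomass = agb_lat + noise$agb,
               stringsAsFactors = FALSE),
    units = c(soc = "mg C g-1 soil", doc = "mg C kg-1 soil",
              aboveground_biomass = "g m-2"))
  mur <- pmax(ps$muramic_acid_mass + noise$mur, 0)
  excess <- pmax(ps$glucosamine_excess + noise$glu, 0)
  glu <- 2 * mur / (MURAMIC_MOLAR_MASS * 1000) + excess
  aminosugars <- amino_sugar_profile(data.frame(
    sample_id = ps$sample_id,
    glucosamine = glu,
    galactosamine = 0.8 * glu,
    muramic_acid_mass = mur,
    stringsAsFactors = FALSE))
  list(measurements = measurements, aminosugars = aminosugars)
}

#' Generate the full synthetic experiment
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_experiment` with `design`, `tables`
#'   (bacteria/fungi feature tables), `taxonomy` (per domain), `incubations`,
#'   `aminosugars`, `measurements`, `truth`, `config`.
#' @export
generate_experiment <- function(config = generator_config()) {
  design <- generate_design(config)
  truth <- generate_truth(config, design)
  meas <- generate_measurements(config, design, truth)
  structure(
    list(design = design,
         tables = list(
           bacteria = generate_communities(config, design, "bacteria"),
           fungi = generate_communities(config, design, "fungi")),
         taxonomy = list(
           bacteria = generate_taxonomy(config, "bacteria"),
           fungi = generate_taxonomy(config, "fungi")),
         incubations = generate_incubation(config, design, truth),
         aminosugars = meas$aminosugars,
         measurements = meas$measurements,
         truth = truth,
         config = config),
    class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Emits every datamodel format (metadata TSV, feature-table and taxonomy
#' TSVs, incubation and amino-sugar CSVs, measurement CSV) plus
#' `ground_truth.json`.
#'
#' @param exp a [generate_experiment()] result.
#' @param out_dir output directory.
#' @return named character vector of the paths written.
#' @export
write_experiment <- function(exp, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(metadata = file.path(out_dir, "metadata.tsv"))
  write_design(exp$design, paths["metadata"])
  for (dom in names(exp$tables)) {
    p <- file.path(out_dir, paste0("feature_table_", dom, ".tsv"))
    tp <- file.path(out_dir, paste0("taxonomy_", dom, ".tsv"))
    write_feature_table(exp$tables[[dom]], p, exp$taxonomy[[dom]], tp)
    paths[paste0("table_", dom)] <- p
    paths[paste0("taxonomy_", dom)] <- tp
  }
  paths["incubations"] <- file.path(out_dir, "incubations.csv")
  utils::write.csv(as.data.frame(exp$incubations), paths["incubations"],
                   row.names = FALSE)
  paths["aminosugars"] <- file.path(out_dir, "aminosugars.csv")
  utils::write.csv(as.data.frame(exp$aminosugars), paths["aminosugars"],
                   row.names = FALSE)
  paths["measurements"] <- file.path(out_dir, "measurements.csv")
  write_measurements(exp$measurements, paths["measurements"])
  paths["ground_truth"] <- file.path(out_dir, "ground_truth.json")
  truth <- exp$truth
  jsonlite::write_json(
    list(per_sample = truth$per_sample, turnover = truth$turnover,
         drift = truth$drift, cue_effect = truth$cue_effect,
         soc_params = as.list(truth$soc_params), f_co = truth$f_co,
         seed = exp$config$seed),
    paths["ground_truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
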