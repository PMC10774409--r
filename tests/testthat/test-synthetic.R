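test_that("generator config validates its stated world", {
  cfg <- generator_config(seed = 1)
  expect_equal(cfg$soc_params$warming_multiplier[["conservation"]], 1.031)
  expect_equal(cfg$soc_params$onset_year, 2016)
  expect_equal(cfg$cue_params$effect_slope[["conservation"]], 0.83)
  # fungi turn over faster than bacteria by default, per treatment
  tv <- cfg$turnover
  for (m in c("conservation", "conventional")) for (w in c("ambient", "warmed"))
    expect_gt(tv$rho[tv$domain == "fungi" & tv$management == m & tv$warming == w],
              tv$rho[tv$domain == "bacteria" & tv$management == m & tv$warming == w])
  expect_error(generator_config(sequencing_blocks = 5),
               class = "warmsoil_config_error")
  expect_error(generator_config(turnover = within(uniform_turnover(), rho <- 1)),
               class = "warmsoil_config_error")
  expect_error(generator_config(noise_sd = list(soc = -1)),
               class = "warmsoil_config_error")
})

test_that("generate_experiment obeys the factorial arithmetic and determinism", {
  cfg <- small_config(seed = 5)
  e1 <- generate_experiment(cfg)
  expect_equal(nrow(e1$design$samples), 96)
  # 3 sequenced blocks x 4 treatments x 6 years
  expect_equal(ncol(e1$tables$bacteria$counts), 72)
  expect_equal(ncol(e1$tables$fungi$counts), 72)
  e2 <- generate_experiment(small_config(seed = 5))
  expect_identical(e1$tables$fungi$counts, e2$tables$fungi$counts)
  expect_identical(e1$incubations$dna_atpct_labeled,
                   e2$incubations$dna_atpct_labeled)
  expect_identical(e1$truth$per_sample, e2$truth$per_sample)
  e3 <- generate_experiment(small_config(seed = 6))
  expect_false(identical(e1$tables$fungi$counts, e3$tables$fungi$counts))
})

test_that("community turnover follows the geometric-replacement closed form", {
  cfg <- small_config(seed = 8, turnover = uniform_turnover(0.5, 0.5),
                      drift = no_drift())
  d <- generate_design(cfg)
  ft <- generate_communities(cfg, d, "bacteria", depth = Inf)
  for (b in 1:2) {
    p0 <- ft$counts[, sprintf("conserv-amb-b%d-y2010", b)]
    p2 <- ft$counts[, sprintf("conserv-amb-b%d-y2012", b)]
    p4 <- ft$counts[, sprintf("conserv-amb-b%d-y2014", b)]
    expect_equal(sum(pmin(p0, p2)), 0.5, tolerance = 1e-12)
    expect_equal(sum(pmin(p0, p4)), 0.25, tolerance = 1e-12)
    expect_equal(bray_curtis_pair(p0, p2), 0.5, tolerance = 1e-12)
  }
})

test_that("rho = 0 freezes communities; higher rho lowers similarity at every lag", {
  cfg0 <- small_config(seed = 9, turnover = uniform_turnover(0, 0),
                       drift = no_drift())
  d <- generate_design(cfg0)
  ft0 <- generate_communities(cfg0, d, "bacteria", depth = Inf)
  pl <- "conserv-amb-b1"
  for (yr in c(2012, 2016, 2020))
    expect_equal(
      bray_curtis_pair(ft0$counts[, sprintf("%s-y2010", pl)],
                       ft0$counts[, sprintf("%s-y%d", pl, yr)]),
      1, tolerance = 1e-12)

  # Monte-Carlo: across 20 seeded replicates, mean similarity at each lag is
  # lower under the higher turnover rate
  mean_sim_by_lag <- function(rho, seed) {
    cfg <- small_config(seed = seed, turnover = uniform_turnover(rho, rho),
                        drift = no_drift())
    des <- generate_design(cfg)
    ft <- generate_communities(cfg, des, "bacteria", depth = Inf)
    fit_pairs <- warmsoil:::tdr_pairs(bray_curtis_similarity(ft), des,
                                      "conservation", "ambient")
    tapply(fit_pairs$similarity, fit_pairs$lag, mean)
  }
  lo <- Reduce(`+`, lapply(1:20, function(s) mean_sim_by_lag(0.2, 500 + s))) / 20
  hi <- Reduce(`+`, lapply(1:20, function(s) mean_sim_by_lag(0.5, 500 + s))) / 20
  expect_true(all(hi < lo))
  # monotone non-increasing in lag for rho > 0
  expect_true(all(diff(lo) <= 1e-12))
})

test_that("noise-free incubations invert to the latent physiology exactly", {
  cfg <- generator_config(seed = 12, noise_sd = zero_noise())
  d <- generate_design(cfg)
  tr <- generate_truth(cfg, d)
  inc <- generate_incubation(cfg, d, tr)
  g <- compute_growth(inc, f_co = cfg$incubation_constants$f_co)
  r <- compute_respiration(inc)
  expect_equal(g, tr$per_sample$growth, tolerance = 1e-12)
  expect_equal(r, tr$per_sample$respiration, tolerance = 1e-12)
  expect_equal(compute_cue(g, r)$cue, tr$per_sample$cue, tolerance = 1e-12)
  # latent growth ~ 0 produces at% equal to the natural-abundance control
  tr0 <- tr
  tr0$per_sample$growth <- rep(0.01, nrow(tr0$per_sample)) * 0  # exactly 0
  tr0$per_sample$growth[] <- 0
  inc0 <- generate_incubation(cfg, d, tr0)
  expect_equal(inc0$dna_atpct_labeled, inc0$dna_atpct_control,
               tolerance = 1e-12)
})

test_that("injected CUE trajectory orders the arms and crosses zero", {
  cfg <- generator_config(seed = 13, noise_sd = zero_noise())
  d <- generate_design(cfg)
  tr <- generate_truth(cfg, d)
  ps <- tr$per_sample[tr$per_sample$management == "conservation", ]
  m <- function(yr, w) mean(ps$cue[ps$year == yr & ps$warming == w])
  expect_lt(m(2010, "warmed"), m(2010, "ambient"))
  expect_gt(m(2020, "warmed"), m(2020, "ambient"))
})

test_that("noise-free SOC hits the configured warming multiplier exactly", {
  cfg <- generator_config(seed = 14, noise_sd = zero_noise())
  d <- generate_design(cfg)
  tr <- generate_truth(cfg, d)
  mm <- generate_measurements(cfg, d, tr)
  df <- merge(mm$measurements$data, d$samples, by = "sample_id")
  rel <- function(mgmt, yr) {
    w <- mean(df$soc[df$management == mgmt & df$year == yr &
                       df$warming == "warmed"])
    a <- mean(df$soc[df$management == mgmt & df$year == yr &
                       df$warming == "ambient"])
    (w - a) / a
  }
  expect_equal(rel("conservation", 2020), 0.031, tolerance = 1e-12)
  expect_equal(rel("conservation", 2014), 0, tolerance = 1e-12)  # pre-onset
  expect_equal(rel("conventional", 2020), 0, tolerance = 1e-12)  # null arm
})

test_that("generated amino sugars always satisfy the fungal precondition", {
  for (s in 1:5) {
    cfg <- generator_config(seed = 700 + s)
    d <- generate_design(cfg)
    tr <- generate_truth(cfg, d)
    am <- generate_measurements(cfg, d, tr)$aminosugars
    expect_true(all(am$fungal_valid))
    expect_true(all(am$glucosamine >= 2 * am$muramic_acid_mmol - 1e-15))
    # conversion runs in strict mode without error
    expect_silent(res <- summarize_necromass(am, soc = 20))
    expect_true(all(res$total_c >= 0))
  }
})

test_that("write_experiment emits files the package readers accept", {
  cfg <- small_config(seed = 15)
  e <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_experiment(e, dir)
  expect_true(all(file.exists(paths)))
  d2 <- read_design(paths["metadata"])
  expect_equal(d2$samples, e$design$samples)
  r <- read_feature_table(paths["table_fungi"], paths["taxonomy_fungi"])
  expect_equal(r$table$counts, e$tables$fungi$counts, tolerance = 1e-12)
  expect_equal(r$taxonomy$phylum, e$taxonomy$fungi$phylum)
  m2 <- read_measurements(paths["measurements"])
  expect_identical(m2$data$soc, e$measurements$data$soc)
  gt <- jsonlite::read_json(paths["ground_truth"], simplifyVector = TRUE)
  expect_equal(gt$seed, cfg$seed)
  expect_equal(gt$f_co, cfg$incubation_constants$f_co)
})
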