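test_that("rarefy subsamples to exact depth and drops shallow samples", {
  set.seed(1)
  counts <- matrix(rpois(40, 120), nrow = 8,
                   dimnames = list(sprintf("t%d", 1:8), sprintf("s%d", 1:5)))
  counts[, 5] <- c(3L, rep(0L, 7))  # shallow sample
  ft <- feature_table(counts)
  expect_message(rt <- rarefy(ft, 500, seed = 4), "s5")
  expect_true(all(colSums(rt$counts) == 500))
  expect_true(all(rt$counts <= counts[, colnames(rt$counts)]))
  # depth equal to total leaves the sample unchanged
  tot <- sum(counts[, 1])
  ft1 <- feature_table(counts[, 1, drop = FALSE])
  expect_identical(rarefy(ft1, tot, seed = 1)$counts[, 1], counts[, 1])
  # determinism
  expect_identical(rarefy(ft, 500, seed = 9)$counts,
                   rarefy(ft, 500, seed = 9)$counts)
  expect_error(rarefy(ft, 10^7, seed = 1), class = "warmsoil_validation_error")
  expect_error(rarefy(ft, 0, seed = 1), class = "warmsoil_config_error")
})

test_that("bray_curtis_similarity matches hand values and the vegan oracle", {
  m <- cbind(a = c(2, 1), b = c(1, 3))
  rownames(m) <- c("t1", "t2")
  sim <- bray_curtis_similarity(feature_table(m, relative = TRUE))
  expect_equal(sim$values["a", "b"], 4 / 7)
  expect_equal(diag(sim$values), c(a = 1, b = 1))
  expect_equal(bray_curtis_pair(c(1, 0), c(0, 2)), 0)  # disjoint supports
  expect_equal(bray_curtis_pair(c(3, 2), c(3, 2)), 1)

  skip_if_not_installed("vegan")
  set.seed(8)
  mm <- matrix(rpois(60, 20), nrow = 6,
               dimnames = list(sprintf("t%d", 1:6), sprintf("s%d", 1:10)))
  sim2 <- bray_curtis_similarity(feature_table(mm))
  veg <- 1 - as.matrix(vegan::vegdist(t(mm), method = "bray"))
  expect_equal(unname(sim2$values), unname(veg), tolerance = 1e-12)

  mm[, 3] <- 0
  err <- expect_error(bray_curtis_similarity(feature_table(mm)),
                      class = "warmsoil_validation_error")
  expect_match(conditionMessage(err), "s3")
})

test_that("tdr_fit reproduces the moving-window pair census", {
  d <- toy_design()
  sim <- power_law_sim(d)
  fit <- tdr_fit(sim, d, "conservation", "ambient")
  # 6 biennial time points: 15 pairs per plot, 45 per treatment,
  # intervals {2:5, 4:4, 6:3, 8:2, 10:1} per plot
  expect_equal(fit$n_pairs, 45)
  expect_equal(fit$pairs_per_interval,
               c(`2` = 15, `4` = 12, `6` = 9, `8` = 6, `10` = 3))
  expect_equal(sum(fit$pairs_per_interval), fit$n_pairs)
  # exact power law S = 0.9 * lag^-0.5 -> w = -0.5, v = 0.5, R2 = 1
  expect_equal(fit$slope_w, -0.5, tolerance = 1e-12)
  expect_equal(fit$turnover_v, 0.5, tolerance = 1e-12)
  expect_equal(fit$r2_adjusted, 1, tolerance = 1e-12)
  expect_identical(fit$turnover_v, -fit$slope_w)
  # slope invariant to the log base
  fit_e <- tdr_fit(sim, d, "conservation", "ambient", log_base = exp(1))
  expect_equal(fit_e$slope_w, fit$slope_w, tolerance = 1e-12)
})

test_that("tdr_fit equals the brute-force oracle on generator output", {
  cfg <- small_config(seed = 31)
  d <- generate_design(cfg)
  ft <- generate_communities(cfg, d, "fungi")
  rt <- suppressMessages(rarefy(ft, 1800, seed = 2))
  sim <- bray_curtis_similarity(rt)
  for (m in c("conservation", "conventional")) {
    fit <- tdr_fit(sim, d, m, "warmed")
    expect_equal(fit$slope_w,
                 brute_force_tdr_slope(sim, d, m, "warmed"),
                 tolerance = 1e-10)
  }
})

test_that("tdr_fit error contracts", {
  d <- toy_design(years = c(2010, 2012))
  expect_error(tdr_fit(power_law_sim(d), d, "conservation", "ambient"),
               class = "warmsoil_validation_error")
  d6 <- toy_design()
  expect_error(tdr_fit(power_law_sim(d6), d6, "conservation", "warmed"),
               class = "warmsoil_validation_error")  # no matching samples
})

test_that("tdr_slope_compare is calibrated under the null and saturates", {
  # saturated case: well-separated slopes, 10 plots per group, tiny noise
  set.seed(1)
  mk <- function(n_plots, slope, label) {
    do.call(rbind, lapply(seq_len(n_plots), function(p)
      data.frame(plot_id = sprintf("%s%d", label, p),
                 lag = c(2, 4, 6, 8, 10),
                 similarity = 10^(slope * log10(c(2, 4, 6, 8, 10)) +
                                    rnorm(5, 0, 0.005)))))
  }
  a <- fake_tdr_result(mk(10, -0.2, "a"))
  b <- fake_tdr_result(mk(10, -0.9, "b"))
  expect_equal(tdr_slope_compare(a, b, n_perm = 999, seed = 1), 1 / 1000)
  expect_error(tdr_slope_compare(a, b, n_perm = 0),
               class = "warmsoil_config_error")

  # null calibration: one point set split randomly -> median p large
  pool <- mk(8, -0.5, "p")
  plots <- unique(pool$plot_id)
  ps <- vapply(1:50, function(k) {
    set.seed(100 + k)
    ga <- sample(plots, 4)
    ra <- fake_tdr_result(pool[pool$plot_id %in% ga, ])
    rb <- fake_tdr_result(pool[!pool$plot_id %in% ga, ])
    tdr_slope_compare(ra, rb, n_perm = 99, seed = 200 + k)
  }, numeric(1))
  expect_gt(median(ps), 0.3)
})

test_that("lineage_tdr subsets, renormalizes and orders by turnover", {
  cfg <- small_config(seed = 41)
  d <- generate_design(cfg)
  ft <- generate_communities(cfg, d, "bacteria")
  tax <- generate_taxonomy(cfg, "bacteria")
  rt <- suppressMessages(rarefy(ft, 1800, seed = 3))
  # whole-domain lineage is identical to the overall fit on the same table
  rel <- sweep(rt$counts, 2, colSums(rt$counts), "/")
  overall <- tdr_fit(bray_curtis_similarity(feature_table(rel, relative = TRUE)),
                     d, "conservation", "ambient")
  dom <- suppressMessages(
    lineage_tdr(rt, tax, "domain", "Bacteria", d, "conservation", "ambient"))
  expect_equal(dom$slope_w, overall$slope_w, tolerance = 1e-12)
  expect_error(
    lineage_tdr(rt, tax, "phylum", "NoSuchPhylum", d, "conservation",
                "ambient"),
    class = "warmsoil_validation_error")

  # two synthetic "phyla" with different rho: fitted v ordering matches rho
  slow <- generate_communities(
    small_config(seed = 42, turnover = uniform_turnover(0.2, 0.2)),
    d, "bacteria")
  fast <- generate_communities(
    small_config(seed = 43, turnover = uniform_turnover(0.6, 0.6)),
    d, "fungi")
  merged <- rbind(slow$counts, fast$counts)
  tax2 <- rbind(
    data.frame(taxon_id = rownames(slow$counts), domain = "Bacteria",
               phylum = "SlowPhylum", class = "unclassified",
               order = "unclassified", family = "unclassified",
               genus = "unclassified"),
    data.frame(taxon_id = rownames(fast$counts), domain = "Bacteria",
               phylum = "FastPhylum", class = "unclassified",
               order = "unclassified", family = "unclassified",
               genus = "unclassified"))
  mt <- suppressMessages(rarefy(feature_table(merged), 3000, seed = 5))
  v_slow <- suppressMessages(lineage_tdr(mt, tax2, "phylum", "SlowPhylum", d,
                                         "conservation", "ambient"))$turnover_v
  v_fast <- suppressMessages(lineage_tdr(mt, tax2, "phylum", "FastPhylum", d,
                                         "conservation", "ambient"))$turnover_v
  expect_gt(v_fast, v_slow)
})

test_that("lineage_tdr_relative_change is the guarded ratio", {
  expect_equal(lineage_tdr_relative_change(0.6, 0.6), 0)
  expect_equal(lineage_tdr_relative_change(0.9, 0.6), 0.5)
  expect_equal(lineage_tdr_relative_change(0.3, 0.6), -0.5)
  expect_error(lineage_tdr_relative_change(0.5, 0),
               class = "warmsoil_validation_error")
})

test_that("divergence_series pairs blocks and fits exact trends", {
  # construct a similarity matrix with dissimilarity = 0.01 * (year - 2010)
  cfg <- generator_config(seed = 51, n_blocks = 3, sequencing_blocks = 3)
  d <- generate_design(cfg)
  ids <- d$samples$sample_id
  vals <- matrix(0.2, length(ids), length(ids), dimnames = list(ids, ids))
  diag(vals) <- 1
  s <- d$samples
  for (b in 1:3) for (yr in d$years) {
    w <- s$sample_id[s$management == "conservation" & s$block == b &
                       s$year == yr & s$warming == "warmed"]
    a <- s$sample_id[s$management == "conservation" & s$block == b &
                       s$year == yr & s$warming == "ambient"]
    vals[w, a] <- vals[a, w] <- 1 - 0.01 * (yr - 2010)
  }
  sim <- structure(list(values = vals, sample_ids = ids, metric = "synthetic"),
                   class = "similarity_matrix")
  dv <- divergence_series(sim, d, "conservation")
  expect_equal(nrow(dv$points), 18)  # 3 blocks x 6 years
  expect_equal(dv$trend_slope, 0.01, tolerance = 1e-12)
  expect_equal(dv$trend_r2, 1, tolerance = 1e-12)
  # constant dissimilarity -> zero slope
  dv0 <- divergence_series(sim, d, "conventional")
  expect_equal(dv0$trend_slope, 0, tolerance = 1e-12)
  # independent brute-force recomputation of the same trend
  bf <- trend_ols(dv$points$year, dv$points$dissimilarity)
  expect_equal(dv$trend_slope, bf$slope, tolerance = 1e-12)
})

test_that("divergence_series skips incomplete pairs with a message", {
  cfg <- generator_config(seed = 52, n_blocks = 2, sequencing_blocks = 2)
  d <- generate_design(cfg)
  keep <- d$samples$sample_id[-1]  # drop one warmed sample
  ids <- keep
  vals <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  diag(vals) <- 1
  sim <- structure(list(values = vals, sample_ids = ids, metric = "x"),
                   class = "similarity_matrix")
  expect_message(dv <- divergence_series(sim, d, "conservation"), "skipped")
  expect_equal(nrow(dv$points), 11)
})
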