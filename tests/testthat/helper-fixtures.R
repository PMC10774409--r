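# Shared fixtures, built in code at test time.

zero_noise <- function() {
  list(soc = 0, doc = 0, aboveground_biomass = 0, dna_atpct = 0,
       co2_ppm = 0, glucosamine = 0, muramic = 0)
}

# scaled-down community config for tests (quantities checked are scale-free)
small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_taxa = 120, depth = 2000, ...)
}

# uniform turnover / drift tables for controlled experiments
uniform_turnover <- function(rho_bacteria = 0.1, rho_fungi = 0.3) {
  t <- warmsoil:::default_turnover()
  t$rho <- ifelse(t$domain == "bacteria", rho_bacteria, rho_fungi)
  t
}

no_drift <- function() {
  d <- warmsoil:::default_drift()
  d$drift <- 0
  d
}

# minimal 3-plot, 6-year single-treatment design for TDR unit tests
toy_design <- function(years = seq(2010, 2020, 2), blocks = 1:3,
                       management = "conservation", warming = "ambient") {
  g <- expand.grid(year = years, block = blocks, stringsAsFactors = FALSE)
  g$management <- management
  g$warming <- warming
  g$plot_id <- plot_id(g$management, g$warming, g$block)
  g$sample_id <- sprintf("%s-y%d", g$plot_id, g$year)
  study_design(g[c("sample_id", "plot_id", "block", "management",
                   "warming", "year")])
}

# similarity matrix following an exact power law S = c * lag^exponent within
# plots (between-plot entries set to an arbitrary constant; tdr_fit never
# reads them)
power_law_sim <- function(design, c0 = 0.9, exponent = -0.5) {
  ids <- design$samples$sample_id
  n <- length(ids)
  vals <- matrix(0.5, n, n, dimnames = list(ids, ids))
  diag(vals) <- 1
  s <- design$samples
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (s$plot_id[i] == s$plot_id[j]) {
      lag <- abs(s$year[i] - s$year[j])
      vals[i, j] <- vals[j, i] <- c0 * lag^exponent
    }
  }
  structure(list(values = vals, sample_ids = ids, metric = "synthetic"),
            class = "similarity_matrix")
}

# independent brute-force TDR oracle: explicit double loop over all
# within-plot pairs plus closed-form normal-equation OLS
brute_force_tdr_slope <- function(sim, design, management, warming,
                                  log_base = 10) {
  s <- design$samples
  s <- s[s$management == management & s$warming == warming &
           s$sample_id %in% sim$sample_ids, ]
  xs <- c(); ys <- c()
  for (pl in unique(s$plot_id)) {
    sp <- s[s$plot_id == pl, ]
    sp <- sp[order(sp$year), ]
    nr <- nrow(sp)
    if (nr < 2) next
    for (i in 1:(nr - 1)) for (j in (i + 1):nr) {
      S <- sim$values[sp$sample_id[i], sp$sample_id[j]]
      if (S > 0) {
        xs <- c(xs, log(sp$year[j] - sp$year[i], base = log_base))
        ys <- c(ys, log(S, base = log_base))
      }
    }
  }
  n <- length(xs)
  (n * sum(xs * ys) - sum(xs) * sum(ys)) / (n * sum(xs^2) - sum(xs)^2)
}

# build a synthetic tdr_result-shaped object directly from a pair table
fake_tdr_result <- function(pairs, treatment = "synthetic") {
  pairs$log_lag <- log10(pairs$lag)
  pairs$log_sim <- log10(pairs$similarity)
  structure(list(treatment = treatment, pairs = pairs), class = "tdr_result")
}
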