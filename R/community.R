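# Community temporal analyses: rarefaction, Bray-Curtis similarity,
# moving-window time-decay relationships (overall and per lineage),
# plot-level permutation comparison of TDR slopes, and warmed-vs-ambient
# divergence trajectories.

#' Rarefy a feature table to even depth
#'
#' Random subsampling without replacement so that every retained sample has
#' column sum exactly `depth`. Samples below the depth are dropped with a
#' message listing them.
#'
#' @param table a [feature_table()] of counts.
#' @param depth target depth (reads per sample); the conventional defaults in
#'   this package are 24579 (bacteria) and 21550 (fungi).
#' @param seed integer seed (subsampling is deterministic given the seed).
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(table, depth, seed = 1) {
  if (!is_count(depth) || depth < 1) ws_config_stop("depth must be a positive integer")
  if (table$relative) ws_stop("cannot rarefy a relative-abundance table")
  counts <- table$counts
  sums <- colSums(counts)
  keep <- sums >= depth
  if (!any(keep)) ws_stop(sprintf("all samples are below depth %d", depth))
  if (any(!keep))
    message(sprintf("rarefy: dropped %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(counts)[!keep], collapse = ", ")))
  counts <- counts[, keep, drop = FALSE]
  out <- with_seed(seed, {
    apply(counts, 2, function(col) {
      tot <- sum(col)
      if (tot == depth) return(col)
      picked <- sample.int(tot, depth)
      # positions 1..tot laid out taxon by taxon; count picks per taxon
      breaks <- c(0, cumsum(col))
      as.integer(tabulate(findInterval(picked, breaks + 1L) + 1L,
                          nbins = length(col) + 1L)[-1])
    })
  })
  rownames(out) <- rownames(counts)
  feature_table(out)
}

#' Bray-Curtis similarity matrix
#'
#' S(x, y) = 1 - sum|x_i - y_i| / sum(x_i + y_i) between all sample pairs.
#'
#' @param table a [feature_table()] (counts or relative abundances).
#' @return object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix, unit diagonal), `sample_ids`, `metric`.
#' @export
bray_curtis_similarity <- function(table) {
  m <- table$counts
  zero <- colSums(m) == 0
  if (any(zero))
    ws_stop(sprintf("zero-sum sample(s): %s",
                    paste(colnames(m)[zero], collapse = ", ")))
  n <- ncol(m)
  vals <- diag(1, n)
  for (i in seq_len(n - 1)) {
    xi <- m[, i]
    rest <- m[, (i + 1):n, drop = FALSE]
    num <- colSums(abs(rest - xi))
    den <- colSums(rest + xi)
    vals[i, (i + 1):n] <- vals[(i + 1):n, i] <- 1 - num / den
  }
  dimnames(vals) <- list(colnames(m), colnames(m))
  structure(list(values = vals, sample_ids = colnames(m),
                 metric = "bray-curtis"),
            class = "similarity_matrix")
}

#' Similarity between two abundance vectors
#' @param x,y non-negative numeric vectors of equal length.
#' @return scalar Bray-Curtis similarity.
#' @export
bray_curtis_pair <- function(x, y) {
  if (length(x) != length(y)) ws_stop("vectors must have equal length")
  1 - sum(abs(x - y)) / sum(x + y)
}

# Assemble the within-plot pair set (the moving-window census) for one
# treatment: every pair of time points of the same plot, at every lag.
tdr_pairs <- function(sim, design, management, warming) {
  s <- design$samples
  s <- s[s$management == management & s$warming == warming, ]
  s <- s[s$sample_id %in% sim$sample_ids, ]
  if (nrow(s) == 0) ws_stop("no samples match the treatment filter")
  out <- list()
  for (pl in unique(s$plot_id)) {
    sp <- s[s$plot_id == pl, ]
    sp <- sp[order(sp$year), ]
    if (nrow(sp) < 2) next
    for (i in seq_len(nrow(sp) - 1)) for (j in (i + 1):nrow(sp)) {
      out[[length(out) + 1]] <- data.frame(
        plot_id = pl, year_i = sp$year[i], year_j = sp$year[j],
        lag = sp$year[j] - sp$year[i],
        similarity = sim$values[sp$sample_id[i], sp$sample_id[j]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) ws_stop("no within-plot pairs available")
  do.call(rbind, out)
}

#' Time-decay relationship fit
#'
#' Moving-window pairing: all within-plot pairs of time points, at every
#' possible lag (2, 4, ... years for a biennial series), pooled across the
#' plots of one treatment. The fit is an OLS regression of log10 similarity
#' on log10 temporal distance (years); the slope `w` is expected negative
#' and the turnover rate is `v = -w`. Zero-similarity pairs are dropped
#' (log undefined) and counted.
#'
#' @param sim a `similarity_matrix` from [bray_curtis_similarity()].
#' @param design a [study_design()].
#' @param management,warming treatment filter labels.
#' @param log_base base of both logarithms (the slope is invariant to it).
#' @return object of class `tdr_result`: list with `treatment`, `slope_w`,
#'   `turnover_v`, `intercept`, `r2_adjusted`, `p`, `n_pairs`,
#'   `pairs_per_interval` (named vector, lag -> pair count),
#'   `n_dropped_zero`, and `pairs` (the point set with log coordinates,
#'   retained for permutation testing).
#' @export
tdr_fit <- function(sim, design, management, warming, log_base = 10) {
  pairs <- tdr_pairs(sim, design, management, warming)
  n_zero <- sum(pairs$similarity <= 0)
  if (n_zero > 0)
    message(sprintf("tdr_fit: dropped %d zero-similarity pair(s)", n_zero))
  pairs <- pairs[pairs$similarity > 0, ]
  if (nrow(pairs) == 0) ws_stop("all pairs have zero similarity")
  if (length(unique(pairs$lag)) < 2)
    ws_stop("tdr_fit needs >= 2 distinct time lags")
  pairs$log_lag <- log(pairs$lag, base = log_base)
  pairs$log_sim <- log(pairs$similarity, base = log_base)
  fit <- trend_ols(pairs$log_lag, pairs$log_sim)
  census <- table(pairs$lag)
  ppi <- as.integer(census)
  names(ppi) <- names(census)
  structure(
    list(treatment = paste(management, warming, sep = "."),
         slope_w = fit$slope, turnover_v = -fit$slope,
         intercept = fit$intercept, r2_adjusted = fit$r2_adjusted,
         p = fit$p, n_pairs = nrow(pairs), pairs_per_interval = ppi,
         n_dropped_zero = n_zero, pairs = pairs, log_base = log_base),
    class = "tdr_result")
}

#' @export
print.tdr_result <- function(x, ...) {
  cat(sprintf(
    "tdr_result [%s]: w = %.4f (v = %.4f), adj R2 = %.3f, n = %d pairs\n",
    x$treatment, x$slope_w, x$turnover_v, x$r2_adjusted, x$n_pairs))
  cat("  pairs per interval:",
      paste(sprintf("%s yr: %d", names(x$pairs_per_interval),
                    x$pairs_per_interval), collapse = ", "), "\n")
  invisible(x)
}

# OLS slope of log_sim on log_lag for a pair subset; NA when degenerate.
tdr_slope_of <- function(pairs) {
  if (length(unique(pairs$log_lag)) < 2) return(NA_real_)
  x <- pairs$log_lag; y <- pairs$log_sim
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Permutation comparison of two TDR slopes
#'
#' Two-sided test of the observed slope difference against the distribution
#' obtained by permuting plot membership between the two treatments. The
#' exchangeable unit is the plot: all of a plot's pairs move together,
#' because within-plot pairs share samples and are not independent.
#'
#' @param result_a,result_b `tdr_result` objects that retain their point
#'   sets.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return p-value `(1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_perm)`.
#' @export
tdr_slope_compare <- function(result_a, result_b, n_perm = 999, seed = 1) {
  if (!is_count(n_perm) || n_perm < 1)
    ws_config_stop("n_perm must be a positive integer")
  pa <- result_a$pairs; pb <- result_b$pairs
  obs <- tdr_slope_of(pa) - tdr_slope_of(pb)
  plots_a <- unique(pa$plot_id); plots_b <- unique(pb$plot_id)
  # disambiguate plots that appear in both inputs (e.g. a random split of
  # one treatment's point set)
  pa$.plot <- paste0("A:", pa$plot_id)
  pb$.plot <- paste0("B:", pb$plot_id)
  pooled <- rbind(pa, pb)
  plots <- unique(pooled$.plot)
  n_a <- length(plots_a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      grp_a <- sample(plots, n_a)
      da <- tdr_slope_of(pooled[pooled$.plot %in% grp_a, ])
      db <- tdr_slope_of(pooled[!pooled$.plot %in% grp_a, ])
      isTRUE(abs(da - db) >= abs(obs) - 1e-12)
    }, logical(1)))
  })
  (1 + exceed) / (1 + n_perm)
}

#' Lineage-restricted time-decay relationship
#'
#' Subsets the feature table to the taxa of one lineage at a given rank,
#' renormalizes within the subset, and delegates to [tdr_fit()].
#'
#' @param table a [feature_table()].
#' @param taxonomy taxonomy data.frame (see [parse_lineage()]).
#' @param rank one of domain/phylum/class/order/family/genus.
#' @param lineage lineage label at that rank.
#' @param design a [study_design()].
#' @param management,warming treatment filter.
#' @param min_share flag (message) when the lineage holds less than this
#'   count share in more than 20% of samples.
#' @return a `tdr_result`.
#' @export
lineage_tdr <- function(table, taxonomy, rank, lineage, design,
                        management, warming, min_share = 0.001) {
  if (!rank %in% TAX_RANKS)
    ws_config_stop(sprintf("rank must be one of: %s",
                           paste(TAX_RANKS, collapse = ", ")))
  taxa <- taxonomy$taxon_id[taxonomy[[rank]] == lineage]
  taxa <- intersect(taxa, rownames(table$counts))
  if (!length(taxa))
    ws_stop(sprintf("no taxa in the table belong to %s '%s'", rank, lineage))
  sub <- table$counts[taxa, , drop = FALSE]
  share <- colSums(sub) / colSums(table$counts)
  if (mean(share >= min_share) < 0.8)
    message(sprintf(
      "lineage_tdr: %s '%s' holds < %.2g%% of counts in %d%% of samples",
      rank, lineage, 100 * min_share, round(100 * mean(share < min_share))))
  nz <- colSums(sub) > 0
  if (any(!nz))
    message(sprintf("lineage_tdr: dropped %d sample(s) with no counts in lineage",
                    sum(!nz)))
  sub <- sub[, nz, drop = FALSE]
  rel <- sweep(sub, 2, colSums(sub), "/")
  ft <- feature_table(rel, relative = TRUE)
  tdr_fit(bray_curtis_similarity(ft), design, management, warming)
}

#' Warming-induced relative change of a lineage turnover rate
#'
#' (v_warm - v_control) / v_control: positive values mean warming
#' accelerated the lineage's temporal turnover.
#'
#' @param v_warm,v_control turnover rates (v = -w); `v_control` must be
#'   positive.
#' @return dimensionless relative change.
#' @export
lineage_tdr_relative_change <- function(v_warm, v_control) {
  if (any(v_control <= 0))
    ws_stop("v_control must be positive for a relative change")
  (v_warm - v_control) / v_control
}

#' Warmed-vs-ambient divergence trajectory
#'
#' For each (block, year) of one management, the Bray-Curtis dissimilarity
#' between the warmed and the ambient sample of that block; then an OLS
#' trend of dissimilarity on calendar year.
#'
#' @param sim a `similarity_matrix` covering both warming arms.
#' @param design a [study_design()].
#' @param management management label.
#' @return object of class `divergence_series`: list with `management`,
#'   `points` (data.frame block/year/dissimilarity), `trend_slope`,
#'   `trend_r2`, `trend_p`, `trend_slope_se` (NA with a message when fewer
#'   than 3 years have data).
#' @export
divergence_series <- function(sim, design, management) {
  s <- design$samples
  s <- s[s$management == management & s$sample_id %in% sim$sample_ids, ]
  pts <- list(); n_skip <- 0
  for (b in sort(unique(s$block))) for (yr in sort(unique(s$year))) {
    w <- s$sample_id[s$block == b & s$year == yr & s$warming == "warmed"]
    a <- s$sample_id[s$block == b & s$year == yr & s$warming == "ambient"]
    if (length(w) != 1 || length(a) != 1) { n_skip <- n_skip + 1; next }
    pts[[length(pts) + 1]] <- data.frame(
      block = b, year = yr, dissimilarity = 1 - sim$values[w, a])
  }
  if (n_skip > 0)
    message(sprintf("divergence_series: skipped %d incomplete (block, year) pair(s)",
                    n_skip))
  if (!length(pts)) ws_stop("no complete warmed/ambient pairs found")
  points <- do.call(rbind, pts)
  trend <- list(slope = NA_real_, r2_adjusted = NA_real_, p = NA_real_,
                slope_se = NA_real_)
  if (length(unique(points$year)) >= 3) {
    trend <- trend_ols(points$year, points$dissimilarity)
  } else {
    message("divergence_series: < 3 years with data; trend not fit")
  }
  structure(
    list(management = management, points = points,
         trend_slope = trend$slope, trend_r2 = trend$r2_adjusted,
         trend_p = trend$p, trend_slope_se = trend$slope_se),
    class = "divergence_series")
}

#' @export
print.divergence_series <- function(x, ...) {
  cat(sprintf(
    "divergence_series [%s]: slope = %.5g, adj R2 = %.3f, p = %.3g, n = %d\n",
    x$management, x$trend_slope, x$trend_r2, x$trend_p, nrow(x$points)))
  invisible(x)
}
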