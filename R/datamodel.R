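# Typed containers for the warming x management experiment, plus readers and
# writers for the on-disk formats. All downstream modules join against a
# study_design and operate on feature_table / measurement_table objects.

MANAGEMENTS <- c("conservation", "conventional")
WARMING_LEVELS <- c("ambient", "warmed")

#' Construct a study design
#'
#' The factorial sample layout of the experiment: management (conservation vs
#' conventional agriculture) x warming (ambient vs +2 degC) x block x sampling
#' year. Every analysis stage joins its inputs against this object.
#'
#' @param samples data.frame with columns `sample_id`, `plot_id`, `block`,
#'   `management`, `warming`, `year`.
#' @param managements,warming_levels allowed factor labels (canonical
#'   lowercase).
#' @param years ordered integer vector of calendar sampling years; defaults to
#'   the years present in `samples`.
#' @return an object of class `study_design`: a list with elements `samples`,
#'   `managements`, `warming_levels`, `years`, `blocks`.
#' @export
study_design <- function(samples,
                         managements = MANAGEMENTS,
                         warming_levels = WARMING_LEVELS,
                         years = NULL) {
  req <- c("sample_id", "plot_id", "block", "management", "warming", "year")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    ws_stop(sprintf("study design is missing column(s): %s",
                    paste(miss, collapse = ", ")))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$management <- tolower(trimws(samples$management))
  samples$warming <- tolower(trimws(samples$warming))
  samples$block <- as.integer(samples$block)
  samples$year <- as.integer(samples$year)

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    ws_stop(sprintf("duplicate sample_id: %s",
                    paste(unique(dup), collapse = ", ")))
  bad_m <- setdiff(unique(samples$management), managements)
  if (length(bad_m))
    ws_stop(sprintf(
      "unknown management label(s): %s (allowed: %s)",
      paste(bad_m, collapse = ", "), paste(managements, collapse = ", ")))
  bad_w <- setdiff(unique(samples$warming), warming_levels)
  if (length(bad_w))
    ws_stop(sprintf(
      "unknown warming label(s): %s (allowed: %s)",
      paste(bad_w, collapse = ", "), paste(warming_levels, collapse = ", ")))

  years <- sort(unique(as.integer(years %||% samples$year)))
  if (any(diff(years) <= 0))
    ws_stop("years must be strictly increasing")
  if (!all(samples$year %in% years))
    ws_stop("sample year(s) outside the declared year set")

  key <- interaction(samples$management, samples$warming, samples$block,
                     samples$year, drop = TRUE)
  if (anyDuplicated(key))
    ws_stop("duplicated (management, warming, block, year) combination")

  structure(
    list(samples = samples,
         managements = managements,
         warming_levels = warming_levels,
         years = years,
         blocks = sort(unique(samples$block))),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "study_design: %d samples | %d blocks | years %s\n  managements: %s | warming: %s\n",
    nrow(x$samples), length(x$blocks),
    paste(range(x$years), collapse = "-"),
    paste(x$managements, collapse = ", "),
    paste(x$warming_levels, collapse = ", ")))
  invisible(x)
}

#' Deterministic plot identifier
#'
#' Plot identity is a pure function of (management, warming, block) so that
#' the within-plot time series needed for time-decay pairing is well defined.
#'
#' @param management,warming,block vectors of equal length.
#' @return character vector of plot ids.
#' @export
plot_id <- function(management, warming, block) {
  sprintf("%s-%s-b%d", substr(management, 1, 7), substr(warming, 1, 3),
          as.integer(block))
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns `sample-id`, `plot`,
#' `block`, `management`, `warming`, `year` (QIIME-style metadata).
#'
#' @param path file path.
#' @return a [study_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) ws_io_stop(sprintf("metadata file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  req <- c("sample-id", "plot", "block", "management", "warming", "year")
  miss <- setdiff(req, names(df))
  if (length(miss))
    ws_stop(sprintf("metadata is missing column(s): %s",
                    paste(miss, collapse = ", ")))
  samples <- data.frame(
    sample_id = df[["sample-id"]],
    plot_id = df[["plot"]],
    block = as.integer(df[["block"]]),
    management = df[["management"]],
    warming = df[["warming"]],
    year = as.integer(df[["year"]]),
    stringsAsFactors = FALSE)
  study_design(samples)
}

#' Write a study design to a metadata TSV
#' @param design a [study_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  s <- design$samples
  out <- data.frame(`sample-id` = s$sample_id, plot = s$plot_id,
                    block = s$block, management = s$management,
                    warming = s$warming, year = s$year,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a feature table
#'
#' Taxon counts per sample (taxa x samples), the substrate of all community
#' analyses. Counts must be non-negative integers unless `relative = TRUE`
#' (used by the infinite-depth flag of the community generator, in which case
#' the columns are relative abundances).
#'
#' @param counts numeric matrix with taxon ids as rownames and sample ids as
#'   colnames.
#' @param relative logical; `TRUE` marks noise-free relative abundances.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, relative = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ws_stop("feature table needs taxon ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    ws_stop("duplicate taxon ids in feature table")
  if (anyDuplicated(colnames(counts)))
    ws_stop("duplicate sample ids in feature table")
  if (anyNA(counts) || any(counts < 0))
    ws_stop("feature table counts must be non-negative and non-missing")
  if (!relative && any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    ws_stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                    rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  structure(list(counts = counts, relative = relative),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d taxa x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$relative) " (relative abundances)" else ""))
  invisible(x)
}

#' Read a feature table and its taxonomy
#'
#' The feature table is a dense BIOM-style TSV (taxa as rows, samples as
#' columns, first column the taxon id); taxonomy is a two-column TSV mapping
#' taxon id to a semicolon-delimited ranked lineage
#' (`d__...;p__...;c__...;o__...;f__...;g__...`).
#'
#' @param table_path,taxonomy_path file paths.
#' @return list with elements `table` ([feature_table()]) and `taxonomy`
#'   (a taxonomy data.frame, see [parse_lineage()]). Taxa absent from the
#'   taxonomy trigger a warning listing them.
#' @export
read_feature_table <- function(table_path, taxonomy_path = NULL) {
  if (!file.exists(table_path))
    ws_io_stop(sprintf("feature table not found: %s", table_path))
  df <- utils::read.delim(table_path, check.names = FALSE, sep = "\t")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) ws_stop("feature table contains non-numeric cells")
  bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    ws_stop(sprintf("invalid count at taxon '%s', sample '%s'",
                    ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(mat) <- ids
  ft <- feature_table(mat)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- read_taxonomy(taxonomy_path)
    uncovered <- setdiff(ids, tax$taxon_id)
    if (length(uncovered))
      warning(sprintf("taxonomy does not cover %d taxa: %s",
                      length(uncovered),
                      paste(utils::head(uncovered, 10), collapse = ", ")),
              call. = FALSE)
  }
  list(table = ft, taxonomy = tax)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Parse semicolon-delimited lineages into a ranked taxonomy table
#'
#' @param taxon_id character vector.
#' @param lineage character vector of `d__...;p__...;...` strings; missing
#'   ranks become `"unclassified"`.
#' @return data.frame with columns `taxon_id` and the six ranks.
#' @export
parse_lineage <- function(taxon_id, lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    p[p == ""] <- "unclassified"
    length(p) <- length(TAX_RANKS)
    p[is.na(p)] <- "unclassified"
    p
  }, character(length(TAX_RANKS))))
  out <- data.frame(taxon_id = taxon_id, mat, stringsAsFactors = FALSE)
  names(out) <- c("taxon_id", TAX_RANKS)
  out
}

#' @rdname parse_lineage
#' @param path two-column TSV (taxon id, lineage string); a header line is
#'   detected and skipped if present.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) ws_io_stop(sprintf("taxonomy file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) && grepl("taxon", df[1, 1], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  parse_lineage(df[[1]], df[[2]])
}

#' Write a feature table (and optional taxonomy) to TSV
#' @param ft a [feature_table()].
#' @param path output path for the count table.
#' @param taxonomy optional taxonomy data.frame; written alongside.
#' @param taxonomy_path output path for the taxonomy.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, taxonomy = NULL,
                                taxonomy_path = NULL) {
  df <- data.frame(`taxon-id` = rownames(ft$counts), ft$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy)) {
    lin <- apply(taxonomy[TAX_RANKS], 1, function(r)
      paste0(substr(TAX_RANKS, 1, 1), "__", r, collapse = ";"))
    utils::write.table(
      data.frame(`taxon-id` = taxonomy$taxon_id, taxonomy = lin,
                 check.names = FALSE),
      taxonomy_path %||% sub("\\.tsv$", "_taxonomy.tsv", path),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a measurement table
#'
#' Numeric measurements keyed by sample id, with a declared unit per column.
#' Missing values are `NA`-marked, never silent zeros; operations that drop
#' NAs report the dropped count.
#'
#' @param df data.frame with a `sample_id` column plus numeric columns.
#' @param units named character vector: unit string per numeric column.
#' @return object of class `measurement_table`.
#' @export
measurement_table <- function(df, units) {
  if (!"sample_id" %in% names(df)) ws_stop("measurement table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) ws_stop("duplicate sample_id in measurement table")
  vars <- setdiff(names(df), "sample_id")
  miss <- setdiff(vars, names(units))
  if (length(miss))
    ws_stop(sprintf("no unit declared for column(s): %s",
                    paste(miss, collapse = ", ")))
  for (v in vars) df[[v]] <- as.numeric(df[[v]])
  structure(list(data = as.data.frame(df, stringsAsFactors = FALSE),
                 units = units[vars]),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("measurement_table: %d samples x %d variables\n",
              nrow(x$data), length(x$units)))
  for (v in names(x$units)) cat(sprintf("  %s [%s]\n", v, x$units[[v]]))
  invisible(x)
}

#' Read / write measurement tables
#'
#' On disk a measurement table is a CSV whose second line is a units record:
#' `#units,<unit1>,<unit2>,...` aligned with the header columns.
#'
#' @param path file path.
#' @return [measurement_table()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) ws_io_stop(sprintf("measurement file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[2], "#units"))
    ws_stop("measurement CSV must carry a '#units,...' line after the header")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  units <- strsplit(lines[2], ",", fixed = TRUE)[[1]][-1]
  body <- if (length(lines) > 2) lines[-2] else lines[1]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  vars <- setdiff(header, "sample_id")
  names(units) <- vars
  measurement_table(df, units)
}

#' @rdname read_measurements
#' @param mt a [measurement_table()].
#' @export
write_measurements <- function(mt, path) {
  vars <- setdiff(names(mt$data), "sample_id")
  header <- paste(c("sample_id", vars), collapse = ",")
  units <- paste(c("#units", unname(mt$units[vars])), collapse = ",")
  # 17 significant digits round-trip doubles exactly
  cols <- c(list(mt$data$sample_id),
            lapply(mt$data[vars], function(v)
              ifelse(is.na(v), "NA",
                     vapply(v, format, character(1), digits = 17,
                            trim = TRUE, scientific = FALSE))))
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, units, body), path)
  invisible(path)
}

#' Write pipeline results to an output directory
#'
#' Tabular results become TSV files, scalar summaries a JSON document; every
#' file written is re-readable by the package's own readers.
#'
#' @param result a pipeline result object (`tdr_result`, `divergence_series`,
#'   `effect_size_series`, `measurement_table`, a data.frame, or a named list
#'   of scalars).
#' @param out_dir output directory (created if needed).
#' @param name file stem.
#' @return character vector of paths written.
#' @export
write_results <- function(result, out_dir, name = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      ws_io_stop(sprintf("cannot create output directory: %s", out_dir))
  }
  UseMethod("write_results")
}

#' @export
write_results.data.frame <- function(result, out_dir, name = "result") {
  p <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(result, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' @export
write_results.measurement_table <- function(result, out_dir,
                                            name = "measurements") {
  p <- file.path(out_dir, paste0(name, ".csv"))
  write_measurements(result, p)
  p
}

#' @export
write_results.list <- function(result, out_dir, name = "summary") {
  p <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(result, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  p
}

#' @export
write_results.tdr_result <- function(result, out_dir, name = "tdr") {
  fits <- data.frame(
    treatment = result$treatment, slope_w = result$slope_w,
    turnover_v = result$turnover_v, intercept = result$intercept,
    r2_adjusted = result$r2_adjusted, n_pairs = result$n_pairs,
    n_dropped_zero = result$n_dropped_zero)
  p1 <- write_results(fits, out_dir, paste0(name, "_fits"))
  p2 <- write_results(result$pairs, out_dir, paste0(name, "_pairs"))
  p3 <- write_results(
    list(treatment = result$treatment,
         pairs_per_interval = as.list(result$pairs_per_interval)),
    out_dir, paste0(name, "_summary"))
  c(p1, p2, p3)
}

#' @export
write_results.divergence_series <- function(result, out_dir,
                                            name = "divergence") {
  p1 <- write_results(result$points, out_dir, name)
  p2 <- write_results(
    list(management = result$management, trend_slope = result$trend_slope,
         trend_r2 = result$trend_r2, trend_p = result$trend_p),
    out_dir, paste0(name, "_summary"))
  c(p1, p2)
}

#' @export
write_results.effect_size_series <- function(result, out_dir,
                                             name = "effect_sizes") {
  p1 <- write_results(result$per_year, out_dir, name)
  p2 <- write_results(
    list(variable = result$variable, management = result$management,
         trend_slope = result$trend_slope,
         trend_slope_sma = result$trend_slope_sma,
         trend_r2_adjusted = result$trend_r2_adjusted,
         trend_p = result$trend_p),
    out_dir, paste0(name, "_summary"))
  c(p1, p2)
}
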