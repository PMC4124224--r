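#' Indicator descriptor
#'
#' Metadata for a single assessment indicator: a short unique id, a free-text
#' label, the thematic category it belongs to and its orientation.
#' Orientation distinguishes benefit-type ("positive") criteria, where larger
#' values mean a healthier environment, from cost-type ("contrarian")
#' criteria, where larger values drive vulnerability; it decides whether the
#' proportion p or its complement (1 - p) enters the composite index.
#'
#' @param id Non-empty character scalar, unique within a catalog.
#' @param label Free-text description of the indicator.
#' @param category One of `"climate"`, `"water"`, `"soil"`, `"human"`.
#' @param orientation One of `"positive"`, `"contrarian"`.
#' @return A one-row data frame with columns `id`, `label`, `category`,
#'   `orientation`.
#' @seealso [indicator_catalog()], [indicator_matrix()]
#' @export
#' @examples
#' indicator_descriptor("ws", "average water shortage", "water", "contrarian")
indicator_descriptor <- function(id, label = id,
                                 category = c("climate", "water", "soil", "human"),
                                 orientation = c("positive", "contrarian")) {
  category <- match.arg(category)
  orientation <- match.arg(orientation)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop_validation("indicator id must be a non-empty character scalar")
  data.frame(id = id, label = as.character(label), category = category,
             orientation = orientation, stringsAsFactors = FALSE)
}

#' Indicator catalog
#'
#' Binds indicator descriptors into a catalog (a data frame with one row per
#' indicator) and validates id uniqueness.
#'
#' @param ... Indicator descriptors (see [indicator_descriptor()]) or data
#'   frames with the same columns.
#' @return A data frame of class `indicator_catalog`.
#' @export
indicator_catalog <- function(...) {
  cat <- do.call(rbind, list(...))
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  needed <- c("id", "label", "category", "orientation")
  if (!is.data.frame(cat) || !all(needed %in% names(cat)))
    stop_validation("catalog must have columns id, label, category, orientation")
  if (anyDuplicated(cat$id))
    stop_validation("duplicate indicator id(s): ",
                    paste(unique(cat$id[duplicated(cat$id)]), collapse = ", "))
  bad_cat <- setdiff(cat$category, c("climate", "water", "soil", "human"))
  if (length(bad_cat))
    stop_validation("unknown category: ", paste(bad_cat, collapse = ", "))
  bad_or <- setdiff(cat$orientation, c("positive", "contrarian"))
  if (length(bad_or))
    stop_validation("unknown orientation: ", paste(bad_or, collapse = ", "))
  rownames(cat) <- NULL
  class(cat) <- c("indicator_catalog", "data.frame")
  cat
}

#' Decision matrix of regions by indicators
#'
#' The raw decision matrix consumed by the assessment pipeline.  Rows are the
#' n regions (alternatives), columns the m indicators; cell (j, i) holds the
#' attribute value of indicator i observed in region j, in whatever unit that
#' indicator uses.  Following the human reading convention the matrix is laid
#' out regions-as-rows, while the method's index pair (i, j) keeps i for
#' indicators and j for regions; all column-wise operations below are
#' per-indicator statistics across regions.
#'
#' @param values Numeric n x m matrix (or coercible data frame), all cells
#'   finite.  `n >= 2` is required because per-indicator population
#'   statistics over a single region are degenerate.
#' @param regions Character vector of n unique region ids.
#' @param catalog An [indicator_catalog()] (or plain data frame with the same
#'   columns) covering exactly the m columns, in column order.
#' @return An object of class `indicator_matrix`: a list with elements
#'   `values` (dimnamed matrix), `regions`, `catalog`.
#' @export
#' @examples
#' m <- indicator_matrix(matrix(c(1, 2, 3, 6, 5, 4), nrow = 3),
#'                       regions = c("a", "b", "c"),
#'                       catalog = rbind(
#'                         indicator_descriptor("x", category = "water"),
#'                         indicator_descriptor("y", category = "soil")))
#' dim(m$values)
indicator_matrix <- function(values, regions, catalog) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  catalog <- validate_catalog(catalog)
  n <- nrow(values); m <- ncol(values)
  if (n < 2L)
    stop_validation("at least 2 regions are required (got ", n,
                    "): population statistics over one region are degenerate")
  if (m < 1L)
    stop_validation("at least 1 indicator column is required")
  if (length(regions) != n)
    stop_validation("length(regions) must equal nrow(values)")
  regions <- as.character(regions)
  if (anyDuplicated(regions))
    stop_validation("duplicate region id(s): ",
                    paste(unique(regions[duplicated(regions)]), collapse = ", "))
  if (nrow(catalog) != m)
    stop_validation("catalog has ", nrow(catalog), " indicators but the matrix has ",
                    m, " columns")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_validation("non-finite value at region '", regions[bad[1L]],
                    "', indicator '", catalog$id[bad[2L]], "'")
  }
  dimnames(values) <- list(regions, catalog$id)
  structure(list(values = values, regions = regions, catalog = catalog),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("Decision matrix: ", length(x$regions), " regions x ",
      nrow(x$catalog), " indicators\n", sep = "")
  print(x$values, ...)
  invisible(x)
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

# classed conditions so callers can distinguish bad input (validation),
# unparsable files (parse) and degenerate computations
stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ecoentropy_validation_error", "error")))
}
stop_parse <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ecoentropy_parse_error", "error")))
}
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ecoentropy_degenerate_error", "error")))
}
stop_amplitude <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ecoentropy_amplitude_error",
                                "ecoentropy_degenerate_error", "error")))
}

#' Read a decision matrix from CSV
#'
#' Expects a UTF-8 CSV with header `region,<id1>,...,<idm>`: first column
#' region ids, remaining columns numeric indicator values.  Row and column
#' order are preserved.  Every indicator column must be covered by the
#' catalog; blank or non-numeric cells raise a parse error naming the cell.
#'
#' @param path Path to the CSV file.
#' @param catalog An [indicator_catalog()], or the list returned by
#'   [read_config()] (its `catalog` element is used).  Column order need not
#'   match the file; the catalog is reordered to the file's columns.
#' @return An [indicator_matrix()].
#' @export
read_matrix <- function(path, catalog) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  if (is.list(catalog) && !is.data.frame(catalog) && !is.null(catalog$catalog))
    catalog <- catalog$catalog
  catalog <- validate_catalog(catalog)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    stop_parse("expected a region column plus at least one indicator column in ", path)
  ids <- names(raw)[-1L]
  missing <- setdiff(ids, catalog$id)
  if (length(missing))
    stop_validation("indicator column(s) not in catalog: ",
                    paste(missing, collapse = ", "))
  regions <- raw[[1L]]
  vals <- matrix(NA_real_, nrow(raw), length(ids))
  for (i in seq_along(ids)) {
    cell <- trimws(raw[[i + 1L]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(cell))
    if (length(bad))
      stop_parse("non-numeric or blank cell at region '", regions[bad[1L]],
                 "', indicator '", ids[i], "'")
    vals[, i] <- num
  }
  indicator_matrix(vals, regions,
                   catalog[match(ids, catalog$id), , drop = FALSE])
}

#' Write a decision matrix to CSV at full precision
#'
#' Cells are written with 17 significant digits so that
#' `read_matrix(write_matrix(x))` reproduces `x` exactly.
#'
#' @param x An [indicator_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "indicator_matrix"))
  chr <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(region = x$regions, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("region", x$catalog$id)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an indicator catalog + run options config
#'
#' @param catalog An [indicator_catalog()].
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @param config Optional [assessment_config()] whose scalar options are
#'   embedded alongside the indicator list.
#' @return `path`, invisibly.
#' @export
write_config <- function(catalog, path, config = NULL) {
  catalog <- validate_catalog(catalog)
  obj <- list(indicators = lapply(seq_len(nrow(catalog)), function(i)
    as.list(catalog[i, c("id", "label", "category", "orientation")])))
  if (!is.null(config)) {
    stopifnot(inherits(config, "assessment_config"))
    for (key in c("amplitude", "aggregation_mode", "zero_variance_policy",
                  "report_decimals", "seed"))
      if (!is.null(config[[key]])) obj[[key]] <- config[[key]]
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read an indicator catalog + run options config
#'
#' Accepts YAML or JSON with an `indicators` list of
#' `{id, label, category, orientation}` records plus optional run options
#' (`amplitude`, `aggregation_mode`, `zero_variance_policy`,
#' `report_decimals`, `seed`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list with elements `catalog` (an [indicator_catalog()]) and
#'   `config` (an [assessment_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(obj$indicators))
    stop_parse("config has no 'indicators' list: ", path)
  rows <- lapply(obj$indicators, function(it) {
    if (is.null(it$id)) stop_parse("indicator entry without an 'id' in ", path)
    indicator_descriptor(as.character(it$id),
                         label = if (is.null(it$label)) as.character(it$id) else it$label,
                         category = if (is.null(it$category)) "climate" else it$category,
                         orientation = if (is.null(it$orientation)) "contrarian" else it$orientation)
  })
  cfg <- assessment_config(
    amplitude = if (is.null(obj$amplitude)) NULL else as.numeric(obj$amplitude),
    aggregation_mode = if (is.null(obj$aggregation_mode)) "weighted_complement" else obj$aggregation_mode,
    zero_variance_policy = if (is.null(obj$zero_variance_policy)) "error" else obj$zero_variance_policy,
    report_decimals = if (is.null(obj$report_decimals)) 4L else as.integer(obj$report_decimals),
    seed = if (is.null(obj$seed)) NULL else as.integer(obj$seed))
  list(catalog = do.call(indicator_catalog, rows), config = cfg)
}

#' Assessment run configuration
#'
#' @param amplitude Optional positive translation amplitude A; when `NULL`
#'   the default rule of [default_amplitude()] is used.
#' @param aggregation_mode `"weighted_complement"` (default; weighted sum of
#'   p for positive and 1 - p for contrarian indicators) or
#'   `"literal_ratio"` (positive-weighted sum divided by contrarian-weighted
#'   complement sum).  See [composite_index()] for why the complement sum is
#'   the default.
#' @param zero_variance_policy `"error"` (default) or `"drop"`: what to do
#'   with an indicator column that is constant across regions.
#' @param report_decimals Rounding used in written reports only (0..10);
#'   all computation runs at full floating precision.
#' @param seed Optional integer seed for randomized subcommands.
#' @return An object of class `assessment_config`.
#' @export
assessment_config <- function(amplitude = NULL,
                              aggregation_mode = c("weighted_complement", "literal_ratio"),
                              zero_variance_policy = c("error", "drop"),
                              report_decimals = 4L,
                              seed = NULL) {
  aggregation_mode <- match.arg(aggregation_mode)
  zero_variance_policy <- match.arg(zero_variance_policy)
  if (!is.null(amplitude)) {
    amplitude <- as.numeric(amplitude)
    if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude <= 0)
      stop_validation("amplitude must be a positive finite scalar")
  }
  report_decimals <- as.integer(report_decimals)
  if (is.na(report_decimals) || report_decimals < 0L || report_decimals > 10L)
    stop_validation("report_decimals must be in [0, 10]")
  structure(list(amplitude = amplitude, aggregation_mode = aggregation_mode,
                 zero_variance_policy = zero_variance_policy,
                 report_decimals = report_decimals, seed = seed),
            class = "assessment_config")
}

#' The western Jilin decision matrix
#'
#' Loads the packaged 9-region x 10-indicator decision matrix for the
#' western part of Jilin Province (Tiaobei, Zhenlai, Tiaonan, Da'an, Tongyu,
#' Qian'an, Fuyu, Changling, Qianguo).  The ten indicators cover average
#' water shortage, change rates of the aridity index and of water, spring
#' and summer drought frequencies, flood frequency, grassland degradation,
#' sand salinization, an unnamed ninth indicator and desertification rate;
#' all ten are encoded as contrarian (vulnerability-driving) criteria.
#'
#' @return An [indicator_matrix()] with n = 9 regions, m = 10 indicators.
#' @export
#' @examples
#' jl <- load_jilin_fixture()
#' jl$values["Changling", "10"]  # 77.29
load_jilin_fixture <- function() {
  csv <- system.file("extdata", "jilin_matrix.csv", package = "ecoentropy",
                     mustWork = TRUE)
  cfg <- system.file("extdata", "jilin_catalog.yaml", package = "ecoentropy",
                     mustWork = TRUE)
  read_matrix(csv, read_config(cfg)$catalog)
}
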