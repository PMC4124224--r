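#' Composite vulnerability index per region
#'
#' Aggregates the weighted indicator proportions of each region into a single
#' index V_j.  Two modes are provided:
#'
#' * `weighted_complement` (default):
#'   V_j = sum over positive indicators of w_i p_ij +
#'         sum over contrarian indicators of w_k (1 - p_kj).
#'   With every indicator contrarian this reduces to sum_k w_k (1 - p_kj),
#'   whose mean over regions is exactly (n - 1)/n for any weights summing
#'   to 1 — the form under which the packaged worked example's published
#'   numbers (mean 0.8889 = 8/9) are reproducible.
#' * `literal_ratio`: V_j = (positive-weighted sum of p) /
#'   (contrarian-weighted sum of 1 - p).  Requires both orientation sets to
#'   be non-empty and does not match the worked example's numbers; it is
#'   kept as an explicit opt-in.
#'
#' @param p Proportion matrix (regions x indicators, columns sum to 1).
#' @param w Weight vector summing to 1, one entry per indicator.
#' @param orientations Character vector of `"positive"`/`"contrarian"`, one
#'   per indicator.
#' @param mode `"weighted_complement"` or `"literal_ratio"`.
#' @return Named numeric vector V of length n (names = region ids).
#' @export
composite_index <- function(p, w, orientations,
                            mode = c("weighted_complement", "literal_ratio")) {
  mode <- match.arg(mode)
  p <- as.matrix(p)
  m <- ncol(p)
  if (length(w) != m || length(orientations) != m)
    stop_validation("weights and orientations must have one entry per indicator")
  if (abs(sum(w) - 1) > 1e-9)
    stop_validation("weights must sum to 1")
  if (any(abs(colSums(p) - 1) > 1e-9))
    stop_validation("proportion columns must each sum to 1")
  pos <- orientations == "positive"
  con <- orientations == "contrarian"
  if (!all(pos | con))
    stop_validation("orientations must be 'positive' or 'contrarian'")
  benefit <- as.numeric(p[, pos, drop = FALSE] %*% w[pos])
  cost    <- as.numeric((1 - p[, con, drop = FALSE]) %*% w[con])
  v <- if (mode == "weighted_complement") {
    benefit + cost
  } else {
    if (!any(pos) || !any(con))
      stop_degenerate("literal_ratio mode needs at least one positive and ",
                      "one contrarian indicator; the ratio is undefined otherwise")
    if (any(cost == 0))
      stop_degenerate("literal_ratio denominator is zero for region ",
                      paste(rownames(p)[cost == 0], collapse = ", "))
    benefit / cost
  }
  stats::setNames(v, rownames(p))
}

#' Rank regions by composite index
#'
#' Sorts regions by descending V.  Exact ties keep the input (row) order, so
#' the ranking is deterministic and auditable.
#'
#' @param v Named numeric vector of composite indices.
#' @return Character vector of region ids, highest V first.
#' @export
rank_regions <- function(v) {
  names(v)[order(-v, seq_along(v))]
}

# run one pipeline stage, prefixing any error with the stage name but
# preserving the condition class
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(errorCondition(paste0("[", stage, "] ", conditionMessage(e)),
                        class = setdiff(class(e), "simpleError")))
  })
}

#' Run the full entropy-weight assessment pipeline
#'
#' Chains z-score standardization (population SD), amplitude selection
#' (config override or the [default_amplitude()] rule), coordinate
#' translation, proportions, entropies with k = 1/ln(n), difference
#' coefficients, normalized weights, the composite index and the ranking.
#' All intermediates are returned for reporting.
#'
#' @param x An [indicator_matrix()].
#' @param config An [assessment_config()].
#' @return An object of class `ew_assessment`: list with `std`
#'   (`standardized_matrix`), `weighting` (`weighting_result`) and `result`
#'   (list with `composite`, `ranking`, `mode`, `amplitude`, `provenance`).
#' @export
#' @examples
#' fit <- assess(load_jilin_fixture(), assessment_config())
#' round(range(fit$result$composite), 4)
#' fit$result$ranking
assess <- function(x, config = assessment_config()) {
  stopifnot(inherits(x, "indicator_matrix"), inherits(config, "assessment_config"))
  std <- with_stage("standardization",
                    zscore_standardize(x, config$zero_variance_policy))
  std <- with_stage("translation", translate(std, config$amplitude))
  weighting <- with_stage("weighting", entropy_weighting(std))
  v <- with_stage("aggregation",
                  composite_index(weighting$proportions, weighting$weights,
                                  std$catalog$orientation,
                                  config$aggregation_mode))
  result <- list(composite = v,
                 ranking = rank_regions(v),
                 mode = config$aggregation_mode,
                 amplitude = std$amplitude,
                 provenance = list(package = "ecoentropy",
                                   version = as.character(utils::packageVersion("ecoentropy")),
                                   n_regions = length(std$regions),
                                   m_indicators = ncol(std$z),
                                   dropped = std$dropped,
                                   config = unclass(config)))
  structure(list(std = std, weighting = weighting, result = result),
            class = "ew_assessment")
}

#' @export
print.ew_assessment <- function(x, ...) {
  r <- x$result
  cat("Entropy-weight vulnerability assessment (mode = ", r$mode,
      ", A = ", format(r$amplitude), ")\n", sep = "")
  ord <- match(r$ranking, names(r$composite))
  print(data.frame(region = r$ranking,
                   V = round(unname(r$composite[ord]), 4),
                   rank = seq_along(ord)), row.names = FALSE)
  invisible(x)
}

#' Amplitude sensitivity analysis
#'
#' The translation amplitude A is the one tunable of the pipeline: the
#' closer A stays to its lower bound |min z|, the more the proportions — and
#' hence the entropy weights — differ between indicators.  As A grows all
#' proportions approach uniformity, entropies approach 1 and the weight
#' spread collapses.  This runs the full pipeline once per candidate A and
#' tabulates the weight spread and ranking so the discrimination decay is
#' inspectable.
#'
#' @param x An [indicator_matrix()].
#' @param config An [assessment_config()]; its `amplitude` is ignored in
#'   favour of each candidate.
#' @param amplitudes Numeric vector of candidate amplitudes.  An invalid
#'   entry (violating A > |min z|) is reported in the table's `error` column;
#'   the other entries still run.
#' @return A data frame with one row per amplitude: `amplitude`,
#'   `weight_spread` (max w - min w), `min_entropy`, `ranking`
#'   (" > "-separated), `error`.  The full `ew_assessment` objects are
#'   attached as attribute `"runs"`.
#' @export
amplitude_sensitivity <- function(x, config = assessment_config(), amplitudes) {
  stopifnot(length(amplitudes) >= 1L)
  runs <- vector("list", length(amplitudes))
  rows <- lapply(seq_along(amplitudes), function(i) {
    a <- amplitudes[i]
    cfg <- config
    cfg$amplitude <- a
    fit <- tryCatch(assess(x, cfg), error = identity)
    if (inherits(fit, "error"))
      return(data.frame(amplitude = a, weight_spread = NA_real_,
                        min_entropy = NA_real_, ranking = NA_character_,
                        error = conditionMessage(fit)))
    runs[[i]] <<- fit
    w <- fit$weighting$weights
    data.frame(amplitude = a,
               weight_spread = max(w) - min(w),
               min_entropy = min(fit$weighting$entropies),
               ranking = paste(fit$result$ranking, collapse = " > "),
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}

#' Write report tables for an assessment run
#'
#' Emits, into `out_dir`: `standardized.csv` (z-scores), `translated.csv`
#' (shifted values), `proportions.csv`, `weights.csv` (entropy, difference
#' coefficient and weight per indicator) and `summary.json` (composite
#' indices, ranking, amplitude, mode, config echo).  All table values are
#' rounded to `decimals` for presentation; the JSON summary additionally
#' carries the composite indices at full precision under
#' `composite_full_precision` so it round-trips exactly.
#'
#' @param fit An `ew_assessment` from [assess()].
#' @param out_dir Output directory, created if absent.
#' @param decimals Rounding for the CSV tables and displayed summary values;
#'   defaults to the run's `report_decimals`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(fit, out_dir,
                         decimals = fit$result$provenance$config$report_decimals) {
  stopifnot(inherits(fit, "ew_assessment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  std <- fit$std; wt <- fit$weighting; res <- fit$result
  write_table <- function(m, file) {
    df <- data.frame(region = rownames(m), round(m, decimals),
                     check.names = FALSE)
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE,
                     fileEncoding = "UTF-8")
    file.path(out_dir, file)
  }
  files <- c(
    write_table(std$z, "standardized.csv"),
    write_table(std$shifted, "translated.csv"),
    write_table(wt$proportions, "proportions.csv"))
  wdf <- data.frame(indicator = std$catalog$id,
                    entropy = round(wt$entropies, decimals),
                    diff_coeff = round(wt$diff_coeffs, decimals),
                    weight = round(wt$weights, decimals))
  utils::write.csv(wdf, file.path(out_dir, "weights.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  files <- c(files, file.path(out_dir, "weights.csv"))
  summary <- list(
    composite = as.list(round(res$composite, decimals)),
    composite_full_precision = as.list(res$composite),
    ranking = res$ranking,
    amplitude = res$amplitude,
    k = wt$k,
    mode = res$mode,
    dropped = std$dropped,
    provenance = res$provenance)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(out_dir, "summary.json")))
}
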