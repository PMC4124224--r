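#' Indicator proportions over regions
#'
#' For each indicator i, divides the translated value of every region by the
#' indicator's column sum: p_ij = x'_ij / sum_j x'_ij.  Each column is then a
#' discrete distribution over the n regions, the object the entropy is taken
#' of.
#'
#' @param std A translated `standardized_matrix` (see [translate()]), or a
#'   plain numeric matrix of strictly positive values.
#' @return Numeric n x m matrix of proportions; every column sums to 1.
#' @export
#' @examples
#' std <- translate(zscore_standardize(load_jilin_fixture()), 2.2)
#' round(ew_proportions(std)["Tiaobei", "1"], 4)  # 0.1516
ew_proportions <- function(std) {
  s <- if (inherits(std, "standardized_matrix")) {
    if (is.null(std$shifted))
      stop_degenerate("matrix has not been translated; call translate() first")
    std$shifted
  } else std
  if (any(s <= 0))
    stop_degenerate("proportions require strictly positive values; ",
                    "min = ", format(min(s)))
  sweep(s, 2L, colSums(s), `/`)
}

#' Information entropy of each indicator
#'
#' Shannon entropy of each indicator's proportion column over the n regions,
#' normalized by k = 1/ln(n) so that e_i is in `[0, 1]` with e_i = 1 exactly
#' at the uniform distribution:
#' e_i = -(1/ln n) * sum_j p_ij ln p_ij.
#' A low entropy means indicator i is concentrated in few regions and hence
#' carries more discriminating information.
#'
#' @param p Proportion matrix (columns sum to 1, entries > 0).  Zero entries
#'   are tolerated defensively with the 0 * ln 0 = 0 convention and a
#'   warning; the translation step upstream guarantees positivity.
#' @param n Number of regions; defaults to `nrow(p)`.
#' @return Named numeric vector e of length m, each entry in `[0, 1]`.
#' @export
ew_entropies <- function(p, n = nrow(p)) {
  p <- as.matrix(p)
  if (n < 2L)
    stop_degenerate("entropy normalization k = 1/ln(n) is undefined for n < 2")
  sums <- colSums(p)
  if (any(abs(sums - 1) > 1e-9))
    stop_degenerate("proportion column(s) do not sum to 1: ",
                    paste(which(abs(sums - 1) > 1e-9), collapse = ", "))
  if (any(p < 0))
    stop_degenerate("negative proportion encountered")
  if (any(p == 0))
    warning("zero proportion encountered; applying the 0*ln(0) = 0 convention")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(n)
  # clamp only floating-point overshoot, never a real violation
  e[e > 1 & e <= 1 + 1e-12] <- 1
  e[e < 0 & e >= -1e-12] <- 0
  e
}

#' Difference coefficients and entropy weights
#'
#' The difference coefficient g_i = 1 - e_i measures the useful information
#' an indicator carries; weights are the normalized coefficients
#' w_i = g_i / sum(g).  When every column is perfectly uniform (all e_i = 1)
#' the weights are undefined; this raises a degenerate-computation error
#' suggesting equal weights rather than silently applying them.
#'
#' @param e Entropy vector from [ew_entropies()], each entry in `[0, 1]`.
#' @return List with `diff_coeffs` (g) and `weights` (w, summing to 1).
#' @export
ew_weights <- function(e) {
  if (any(e < 0 | e > 1))
    stop_degenerate("entropies must lie in [0, 1]")
  g <- 1 - e
  total <- sum(g)
  if (total <= 0)
    stop_degenerate("all indicators have entropy 1 (perfectly uniform ",
                    "proportions): entropy weights are undefined; consider ",
                    "assigning equal weights explicitly")
  list(diff_coeffs = g, weights = g / total)
}

#' Full entropy weighting of a translated matrix
#'
#' Convenience wrapper running proportions, entropies and weights in one
#' call.
#'
#' @param std A translated `standardized_matrix`.
#' @return An object of class `weighting_result`: list with `proportions`
#'   (n x m), `k` (1/ln n), `entropies`, `diff_coeffs`, `weights`.
#' @export
#' @examples
#' std <- translate(zscore_standardize(load_jilin_fixture()), 2.2)
#' sum(entropy_weighting(std)$weights)  # 1
entropy_weighting <- function(std) {
  p <- ew_proportions(std)
  n <- nrow(p)
  e <- ew_entropies(p, n)
  gw <- ew_weights(e)
  structure(list(proportions = p, k = 1 / log(n), entropies = e,
                 diff_coeffs = gw$diff_coeffs, weights = gw$weights),
            class = "weighting_result")
}

#' @export
print.weighting_result <- function(x, ...) {
  cat("Entropy weighting over ", nrow(x$proportions), " regions, ",
      length(x$weights), " indicators (k = ", format(x$k), ")\n", sep = "")
  print(round(rbind(entropy = x$entropies, diff_coeff = x$diff_coeffs,
                    weight = x$weights), 4), ...)
  invisible(x)
}
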