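#' Z-score standardization of a decision matrix
#'
#' Standardizes each indicator column across regions to mean 0 and variance 1
#' using the population standard deviation (divide by n, not n - 1).  The
#' population form is the one under which the method's worked example is
#' reproducible; with the sample SD every downstream number changes.
#'
#' @param x An [indicator_matrix()].
#' @param policy What to do with a zero-variance (constant) indicator column:
#'   `"error"` (default) stops with a degenerate-computation error;
#'   `"drop"` removes the column with a warning.  Dropping changes the
#'   weights of all remaining indicators, so it is never silent.
#' @return An object of class `standardized_matrix`: list with `z` (n x m
#'   z-score matrix), `col_means`, `col_stds` (population SDs), `catalog`,
#'   `regions`, `dropped` (ids of dropped columns), `amplitude` (`NA` until
#'   [translate()] is applied) and `shifted` (`NULL` until translated).
#' @seealso [translate()], [default_amplitude()]
#' @export
#' @examples
#' jl <- load_jilin_fixture()
#' std <- zscore_standardize(jl)
#' round(std$z["Tiaobei", "1"], 4)  # 0.8009
zscore_standardize <- function(x, policy = c("error", "drop")) {
  stopifnot(inherits(x, "indicator_matrix"))
  policy <- match.arg(policy)
  v <- x$values
  mu <- colMeans(v)
  # population SD: sqrt(mean squared deviation), denominator n
  sd_pop <- sqrt(colMeans(sweep(v, 2L, mu)^2))
  zero <- sd_pop == 0
  dropped <- character(0)
  if (any(zero)) {
    ids <- x$catalog$id[zero]
    if (policy == "error")
      stop_degenerate("zero-variance indicator ", paste(ids, collapse = ", "),
                      ": constant across all regions")
    warning("dropping zero-variance indicator(s): ", paste(ids, collapse = ", "))
    dropped <- ids
    v <- v[, !zero, drop = FALSE]
    mu <- mu[!zero]
    sd_pop <- sd_pop[!zero]
    if (ncol(v) == 0L)
      stop_degenerate("all indicator columns are zero-variance; nothing to assess")
  }
  z <- sweep(sweep(v, 2L, mu), 2L, sd_pop, `/`)
  structure(list(z = z, col_means = mu, col_stds = sd_pop,
                 catalog = x$catalog[!zero, , drop = FALSE],
                 regions = x$regions, dropped = dropped,
                 amplitude = NA_real_, shifted = NULL),
            class = "standardized_matrix")
}

#' Default translation amplitude
#'
#' The amplitude A must exceed the absolute value of the most negative
#' z-score so that every translated value is strictly positive, and should
#' stay close to that bound: the larger A grows, the more uniform the
#' proportions become and the less the entropy weights discriminate (see
#' [amplitude_sensitivity()]).  The default rule returns the smallest
#' multiple of 0.1 strictly greater than |min z| (e.g. min z = -2.1209 gives
#' A = 2.2), or 0 when no z-score is negative.
#'
#' @param std A `standardized_matrix` (or plain numeric matrix of z-scores).
#' @return Scalar amplitude A.
#' @export
default_amplitude <- function(std) {
  z <- if (inherits(std, "standardized_matrix")) std$z else std
  mn <- min(z)
  if (mn >= 0) return(0)
  m <- abs(mn)
  a <- ceiling(m * 10) / 10
  if (a <= m) a <- a + 0.1   # exact 0.1-multiple: step up to stay strict
  a
}

#' Coordinate translation to strict positivity
#'
#' Adds the amplitude A to every z-score so all values become strictly
#' positive before proportions are formed.  Pairwise differences within each
#' column are preserved exactly; only the location shifts.
#'
#' @param std A `standardized_matrix` from [zscore_standardize()].
#' @param amplitude Scalar A >= 0; when `NULL`, [default_amplitude()] is
#'   used.  With any negative z present, A must be strictly greater than
#'   |min z|.
#' @return The `standardized_matrix` with `shifted` and `amplitude` filled.
#' @export
#' @examples
#' std <- translate(zscore_standardize(load_jilin_fixture()), 2.2)
#' round(std$shifted["Fuyu", "8"], 4)  # 0.0791
translate <- function(std, amplitude = NULL) {
  stopifnot(inherits(std, "standardized_matrix"))
  if (is.null(amplitude)) amplitude <- default_amplitude(std)
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude < 0)
    stop_amplitude("amplitude must be a finite scalar >= 0")
  mn <- min(std$z)
  if (mn < 0 && amplitude <= abs(mn))
    stop_amplitude("amplitude A = ", amplitude, " violates A > |min(z)| = ",
                   format(abs(mn)), ": translated values would not all be positive")
  std$shifted <- std$z + amplitude
  std$amplitude <- amplitude
  std
}

#' Alternative column normalizations
#'
#' The standard textbook normalizations that the entropy pipeline
#' deliberately does not use, provided for comparison: range transformation
#' discards inter-column scale relationships, linear scaling cannot handle
#' negative values, and vector normalization does not separate benefit from
#' cost criteria.  These are utilities only; the default pipeline is always
#' z-score + translation.
#'
#' @param x An [indicator_matrix()].
#' @param scheme `"range"` ((X - min)/(max - min) per column),
#'   `"linear_scaling"` (X/max per column; all values must be > 0) or
#'   `"vector"` (X / sqrt(sum(X^2)) per column).
#' @return Numeric n x m matrix of normalized values.
#' @export
alt_normalize <- function(x, scheme = c("range", "linear_scaling", "vector")) {
  stopifnot(inherits(x, "indicator_matrix"))
  scheme <- match.arg(scheme)
  v <- x$values
  ids <- x$catalog$id
  out <- switch(scheme,
    range = {
      rng <- apply(v, 2L, range)
      flat <- rng[2L, ] == rng[1L, ]
      if (any(flat))
        stop_degenerate("range normalization undefined for constant column ",
                        paste(ids[flat], collapse = ", "))
      sweep(sweep(v, 2L, rng[1L, ]), 2L, rng[2L, ] - rng[1L, ], `/`)
    },
    linear_scaling = {
      if (any(v <= 0)) {
        bad <- unique(which(v <= 0, arr.ind = TRUE)[, 2L])
        stop_degenerate("linear scaling requires all values > 0; violated in column ",
                        paste(ids[bad], collapse = ", "))
      }
      sweep(v, 2L, apply(v, 2L, max), `/`)
    },
    vector = {
      nrm <- sqrt(colSums(v^2))
      if (any(nrm == 0))
        stop_degenerate("vector normalization undefined for all-zero column ",
                        paste(ids[nrm == 0], collapse = ", "))
      sweep(v, 2L, nrm, `/`)
    })
  dimnames(out) <- dimnames(v)
  out
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("Standardized matrix: ", length(x$regions), " regions x ",
      ncol(x$z), " indicators\n", sep = "")
  if (length(x$dropped))
    cat("dropped zero-variance indicator(s): ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  if (!is.na(x$amplitude))
    cat("translated with amplitude A = ", format(x$amplitude), "\n", sep = "")
  print(round(x$z, 4), ...)
  invisible(x)
}
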