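#' Specification for a synthetic decision matrix
#'
#' Describes the statistical shape of a random decision matrix: each
#' indicator column is drawn i.i.d. across regions from a log-normal
#' distribution with a prescribed mean (`base_scale`) and coefficient of
#' variation (`dispersion`).  The log-normal keeps all raw values strictly
#' positive, as real vulnerability indicators are, so every comparison
#' normalization is exercisable too.  Defaults mimic the packaged case
#' study's shape: few regions, heterogeneous indicator scales.
#'
#' @param n_regions Integer >= 2.
#' @param m_indicators Integer >= 1.
#' @param dispersion Per-indicator target coefficient of variation across
#'   regions (positive; recycled to length m).
#' @param base_scale Per-indicator mean raw magnitude (positive; recycled).
#' @param orientation_pattern Per-indicator orientations (recycled).
#' @param seed Integer seed; the matrix is fully reproducible from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_regions = 9L, m_indicators = 10L,
                       dispersion = 0.5, base_scale = 10,
                       orientation_pattern = "contrarian", seed = 1L) {
  n_regions <- as.integer(n_regions)
  m_indicators <- as.integer(m_indicators)
  if (is.na(n_regions) || n_regions < 2L)
    stop_validation("n_regions must be an integer >= 2")
  if (is.na(m_indicators) || m_indicators < 1L)
    stop_validation("m_indicators must be an integer >= 1")
  dispersion <- rep_len(as.numeric(dispersion), m_indicators)
  base_scale <- rep_len(as.numeric(base_scale), m_indicators)
  if (any(!is.finite(dispersion)) || any(dispersion <= 0))
    stop_validation("all dispersion entries must be positive")
  if (any(!is.finite(base_scale)) || any(base_scale <= 0))
    stop_validation("all base_scale entries must be positive")
  orientation_pattern <- rep_len(orientation_pattern, m_indicators)
  if (!all(orientation_pattern %in% c("positive", "contrarian")))
    stop_validation("orientation_pattern entries must be 'positive' or 'contrarian'")
  structure(list(n_regions = n_regions, m_indicators = m_indicators,
                 dispersion = dispersion, base_scale = base_scale,
                 orientation_pattern = orientation_pattern,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a random decision matrix
#'
#' Draws indicator i's column i.i.d. across regions from a log-normal with
#' mean `base_scale[i]` and coefficient of variation `dispersion[i]`
#' (moment-matched parameterization: sdlog^2 = log(1 + cv^2),
#' meanlog = log(mean) - sdlog^2 / 2).  Higher dispersion concentrates the
#' column's mass in fewer regions, which after translation lowers that
#' indicator's entropy and raises its weight — the behaviour the entropy
#' method is built on.
#'
#' @param spec A [synth_spec()].
#' @return An [indicator_matrix()] with regions `R01`, `R02`, ... and
#'   indicators `S01`, `S02`, ... cycling through the four categories.
#' @export
#' @examples
#' x <- generate_matrix(synth_spec(n_regions = 9, m_indicators = 10, seed = 42))
#' dim(x$values)
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions; m <- spec$m_indicators
  sdlog <- sqrt(log(1 + spec$dispersion^2))
  meanlog <- log(spec$base_scale) - sdlog^2 / 2
  vals <- vapply(seq_len(m),
                 function(i) stats::rlnorm(n, meanlog[i], sdlog[i]),
                 numeric(n))
  cats <- rep_len(c("climate", "water", "soil", "human"), m)
  catalog <- do.call(rbind, lapply(seq_len(m), function(i)
    indicator_descriptor(sprintf("S%02d", i),
                         label = sprintf("synthetic indicator %d", i),
                         category = cats[i],
                         orientation = spec$orientation_pattern[i])))
  indicator_matrix(vals, sprintf("R%02d", seq_len(n)), catalog)
}

#' Degenerate fixtures for error-path testing
#'
#' Constructs, in code, the inputs that must trigger each declared error
#' path:
#'
#' * `zero_variance`: a valid [indicator_matrix()] whose second column is
#'   constant — [zscore_standardize()] with `policy = "error"` must raise
#'   the zero-variance error.
#' * `single_region`: raw constructor arguments (`values`, `regions`,
#'   `catalog`) for a 1-region matrix — [indicator_matrix()] must reject
#'   n < 2.
#' * `non_finite_csv`: the text of a CSV with a blank cell, for feeding
#'   [read_matrix()] through a temp file — must raise a parse error naming
#'   the cell.
#' * `all_uniform`: a proportion matrix with every column uniform (all
#'   entries 1/n) — [ew_entropies()] returns all 1 and [ew_weights()] must
#'   raise the degenerate-weights error.
#'
#' @return Named list of the four fixtures described above.
#' @export
degenerate_fixtures <- function() {
  two_ind <- rbind(indicator_descriptor("a", category = "water"),
                   indicator_descriptor("b", category = "soil"))
  list(
    zero_variance = indicator_matrix(
      cbind(c(1, 2, 3), c(5, 5, 5)), c("r1", "r2", "r3"), two_ind),
    single_region = list(
      values = matrix(c(1, 2), nrow = 1),
      regions = "only",
      catalog = two_ind),
    non_finite_csv = c("region,a,b", "r1,1.5,", "r2,2.5,3.5"),
    all_uniform = matrix(1 / 4, nrow = 4, ncol = 3,
                         dimnames = list(sprintf("r%d", 1:4),
                                         sprintf("u%d", 1:3)))
  )
}
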