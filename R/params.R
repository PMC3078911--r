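#' Model parameters for the colony population model
#'
#' Constructs and validates the parameter set of the two-compartment
#' hive-bee/forager model. Defaults are the standard parameterisation for a
#' healthy European honey bee colony: a queen laying `L = 2000` eggs/day,
#' brood-rearing half-saturation at `w = 27000` workers, an uninhibited
#' recruitment rate `alpha = 0.25`/day (foraging onset at a minimum of four
#' days of adult age), and a social-inhibition coefficient `sigma = 0.75`/day,
#' under which foragers revert to hive tasks only when more than one third of
#' the adult workforce is foraging. The default forager death rate
#' `m = 1/6.5`/day corresponds to the roughly 6.5-day flightspan of foragers
#' in healthy colonies.
#'
#' The precocious-mortality settings (`m_l`, `sigma_bar_sq`,
#' `precocious_mode`) control an optional feedback in which the forager death
#' rate is replaced by the Hill-form response
#' `m_l * R^2 / (sigma_bar_sq + R^2)` to the per-capita recruitment rate `R`;
#' see [effective_death_rate()].
#'
#' @param L Queen laying rate, eggs/day. Must be >= 0.
#' @param w Brood-rearing saturation constant, bees. Must be > 0.
#' @param alpha Maximum per-capita recruitment rate to foraging, 1/day.
#'   Must be > 0.
#' @param sigma Social-inhibition coefficient, 1/day. Must be >= 0.
#' @param m Forager death rate, 1/day. Must be > 0.
#' @param m_l Maximal precocious-forager death rate, 1/day. Must be >= 0.
#' @param sigma_bar_sq Half-saturation constant of the precocious-mortality
#'   response, (1/day)^2. Must be > 0.
#' @param precocious_mode One of `"off"` (constant death rate `m`),
#'   `"when_R_negative"` (Hill replacement only while the recruitment rate is
#'   negative, i.e. during forager reversion), or `"always"` (Hill
#'   replacement for all recruitment rates).
#'
#' @return An object of class `bee_params`: a named list with the fields
#'   above.
#' @seealso [read_params()], [write_params()], [derivatives()],
#'   [steady_state()]
#' @examples
#' p <- bee_params(m = 0.24)
#' p
#' @export
bee_params <- function(L = 2000, w = 27000, alpha = 0.25, sigma = 0.75,
                       m = 1 / 6.5, m_l = 0.6, sigma_bar_sq = 0.059,
                       precocious_mode = c("off", "when_R_negative", "always")) {
  precocious_mode <- match.arg(precocious_mode)
  p <- structure(
    list(L = L, w = w, alpha = alpha, sigma = sigma, m = m,
         m_l = m_l, sigma_bar_sq = sigma_bar_sq,
         precocious_mode = precocious_mode),
    class = "bee_params"
  )
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the admissibility constraints on a [bee_params()] object and stops
#' with an informative error naming the offending field.
#'
#' @param params A `bee_params` object (or a named list with the same
#'   fields).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  num_fields <- c("L", "w", "alpha", "sigma", "m", "m_l", "sigma_bar_sq")
  for (f in num_fields) {
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (params$L < 0) stop("parameter 'L' must be >= 0", call. = FALSE)
  if (params$w <= 0) stop("parameter 'w' must be > 0", call. = FALSE)
  if (params$alpha <= 0) stop("parameter 'alpha' must be > 0", call. = FALSE)
  if (params$sigma < 0) stop("parameter 'sigma' must be >= 0", call. = FALSE)
  if (params$m <= 0) stop("parameter 'm' must be > 0", call. = FALSE)
  if (params$m_l < 0) stop("parameter 'm_l' must be >= 0", call. = FALSE)
  if (params$sigma_bar_sq <= 0)
    stop("parameter 'sigma_bar_sq' must be > 0", call. = FALSE)
  mode <- params$precocious_mode
  if (is.null(mode) ||
      !mode %in% c("off", "when_R_negative", "always"))
    stop("parameter 'precocious_mode' must be one of 'off', ",
         "'when_R_negative', 'always'", call. = FALSE)
  invisible(params)
}

#' @export
print.bee_params <- function(x, ...) {
  cat("Colony model parameters\n")
  cat(sprintf("  L       = %g eggs/day (queen laying rate)\n", x$L))
  cat(sprintf("  w       = %g bees (brood-rearing saturation)\n", x$w))
  cat(sprintf("  alpha   = %g /day (max recruitment rate)\n", x$alpha))
  cat(sprintf("  sigma   = %g /day (social inhibition)\n", x$sigma))
  cat(sprintf("  m       = %g /day (forager death rate; flightspan %.3g d)\n",
              x$m, 1 / x$m))
  cat(sprintf("  m_l     = %g /day, sigma_bar_sq = %g (1/day)^2 [mode: %s]\n",
              x$m_l, x$sigma_bar_sq, x$precocious_mode))
  invisible(x)
}

params_fields <- c("L", "w", "alpha", "sigma", "m", "m_l", "sigma_bar_sq",
                   "precocious_mode")

#' Read a parameter set from a YAML file
#'
#' The file holds a flat mapping whose keys are exactly the parameter names
#' of [bee_params()] (`L`, `w`, `alpha`, `sigma`, `m`, `m_l`,
#' `sigma_bar_sq`, `precocious_mode`). Missing keys fall back to the
#' defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A validated `bee_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  params_from_list(raw)
}

params_from_list <- function(raw, where = "params") {
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("'", where, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), params_fields)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in setdiff(params_fields, names(raw)))
    message("using default for '", f, "'")
  args <- utils::modifyList(
    list(L = 2000, w = 27000, alpha = 0.25, sigma = 0.75, m = 1 / 6.5,
         m_l = 0.6, sigma_bar_sq = 0.059, precocious_mode = "off"),
    raw)
  for (f in setdiff(params_fields, "precocious_mode"))
    if (!is.numeric(args[[f]]))
      stop("non-numeric value for key '", f, "'", call. = FALSE)
  do.call(bee_params, args)
}

#' Write a parameter set to a YAML file
#'
#' Inverse of [read_params()]; the round trip is exact up to numeric
#' formatting.
#'
#' @param params A `bee_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}
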