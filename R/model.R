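#' @keywords internal
check_state <- function(H, F) {
  if (!is.numeric(H) || !is.numeric(F) || length(H) != length(F))
    stop("H and F must be numeric vectors of equal length", call. = FALSE)
  if (any(!is.finite(H)) || any(!is.finite(F)))
    stop("H and F must be finite", call. = FALSE)
  if (any(H < 0) || any(F < 0))
    stop("populations must be nonnegative (got H = ",
         H[which.min(pmin(H, F))], ", F = ", F[which.min(pmin(H, F))], ")",
         call. = FALSE)
  invisible(NULL)
}

#' Forager fraction of the adult workforce
#'
#' `F / (H + F)`, defined as 0 for the empty colony so that the origin is a
#' genuine fixed point of the model.
#'
#' @param H Hive bees (continuous count).
#' @param F Foragers (continuous count).
#' @return Fraction in `[0, 1]`, vectorised over `H`, `F`.
#' @export
forager_fraction <- function(H, F) {
  check_state(H, F)
  N <- H + F
  ifelse(N > 0, F / N, 0)
}

#' Brood eclosion rate
#'
#' Daily emergence of new adult workers, `E(H, F) = L * N / (w + N)` with
#' `N = H + F`: zero with no workers, saturating at the queen's laying rate
#' `L` as the workforce grows, with half-saturation at `N = w`.
#'
#' @inheritParams forager_fraction
#' @param params A [bee_params()] object.
#' @return Eclosion rate in bees/day, vectorised over `H`, `F`.
#' @examples
#' p <- bee_params()
#' eclosion_rate(27000, 0, p)  # N = w gives L / 2
#' @export
eclosion_rate <- function(H, F, params) {
  validate_params(params)
  check_state(H, F)
  N <- H + F
  params$L * N / (params$w + N)
}

#' Per-capita recruitment rate to foraging
#'
#' `R(H, F) = alpha - sigma * F / N`: hive bees become foragers at the
#' uninhibited rate `alpha` when no foragers are present, and the rate falls
#' linearly in the forager fraction (social inhibition via ethyl oleate
#' transfer). Negative values mean net reversion of foragers to hive tasks,
#' which with the default `alpha/sigma = 1/3` occurs only when more than one
#' third of the workforce is foraging. The forager fraction is taken as 0 at
#' `N = 0`.
#'
#' @inheritParams eclosion_rate
#' @return Per-capita rate in 1/day, vectorised over `H`, `F`.
#' @export
recruitment_rate <- function(H, F, params) {
  validate_params(params)
  params$alpha - params$sigma * forager_fraction(H, F)
}

#' Effective forager death rate
#'
#' Applies the precocious-foraging mortality feedback selected by
#' `params$precocious_mode` to the baseline death rate `m`. The feedback
#' replaces `m` by the Hill-form response
#' `m_l * R^2 / (sigma_bar_sq + R^2)` to the per-capita recruitment rate
#' `R`, either never (`"off"`), only while `R < 0` (`"when_R_negative"`), or
#' for every `R` (`"always"`). The result always lies in
#' `[0, max(m, m_l)]`.
#'
#' @param R Per-capita recruitment rate, 1/day (vectorised).
#' @param params A [bee_params()] object.
#' @return Effective death rate in 1/day.
#' @export
effective_death_rate <- function(R, params) {
  validate_params(params)
  if (!is.numeric(R)) stop("R must be numeric", call. = FALSE)
  hill <- params$m_l * R^2 / (params$sigma_bar_sq + R^2)
  switch(params$precocious_mode,
         off = rep_len(params$m, length(R)),
         when_R_negative = ifelse(R < 0, hill, params$m),
         always = hill)
}

# d m_eff / d R, matching effective_death_rate branch for branch
death_rate_gradient <- function(R, params) {
  s <- params$sigma_bar_sq
  dhill <- 2 * params$m_l * R * s / (s + R^2)^2
  switch(params$precocious_mode,
         off = rep_len(0, length(R)),
         when_R_negative = ifelse(R < 0, dhill, 0),
         always = dhill)
}

#' Instantaneous model rates at a state
#'
#' Convenience wrapper returning the eclosion rate `E`, the per-capita
#' recruitment rate `R` and the effective forager death rate `m_eff` at a
#' state, the three quantities that drive the model.
#'
#' @inheritParams eclosion_rate
#' @return A list with numeric elements `E` (bees/day), `R` (1/day) and
#'   `m_eff` (1/day).
#' @export
colony_rates <- function(H, F, params) {
  E <- eclosion_rate(H, F, params)
  R <- recruitment_rate(H, F, params)
  list(E = E, R = R, m_eff = effective_death_rate(R, params))
}

#' Right-hand side of the colony model
#'
#' The two coupled balance equations of the compartment model:
#' `dH/dt = E(H, F) - H * R(H, F)` (eclosion in, recruitment out) and
#' `dF/dt = H * R(H, F) - m_eff * F` (recruitment in, death out). When `R`
#' is negative the flux `H * R` reverses and moves foragers back to hive
#' tasks. Recruitment conserves adults, so
#' `dN/dt = E - m_eff * F` identically. The empty colony is a fixed point.
#'
#' @inheritParams eclosion_rate
#' @return Named numeric vector `c(dH = ..., dF = ...)` in bees/day.
#' @examples
#' derivatives(9000, 0, bee_params())
#' @export
derivatives <- function(H, F, params) {
  r <- colony_rates(H, F, params)
  flux <- H * r$R
  c(dH = r$E - flux, dF = flux - r$m_eff * F)
}
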