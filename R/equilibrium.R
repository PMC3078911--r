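#' Equilibrium forager-to-hive ratio
#'
#' On the slow manifold the colony keeps a fixed caste ratio `J = F0 / H0`.
#' Setting `dF/dt = 0` with `F = J * H` gives the quadratic
#' `m J^2 + (m + sigma - alpha) J - alpha = 0`, which has exactly one
#' positive root for `alpha > 0`. With no social inhibition (`sigma = 0`)
#' the quadratic degenerates and `J = alpha / m`.
#'
#' @param params A [bee_params()] object with `m > 0`.
#' @return The positive root `J` (dimensionless).
#' @examples
#' equilibrium_ratio(bee_params(m = 0.24))
#' @export
equilibrium_ratio <- function(params) {
  validate_params(params)
  m <- params$m
  if (m <= 0) stop("equilibrium ratio requires m > 0", call. = FALSE)
  a <- params$alpha
  s <- params$sigma
  if (s == 0) return(a / m)
  b <- m + s - a
  # positive root of m J^2 + b J - a = 0; written to avoid cancellation
  disc <- sqrt(b^2 + 4 * m * a)
  if (b >= 0) 2 * a / (b + disc) else (disc - b) / (2 * m)
}

#' Closed-form steady state of the colony model
#'
#' Computes the caste ratio `J` from [equilibrium_ratio()], then the
#' equilibrium hive-bee population `H0 = L / (m J) - w / (1 + J)` from the
#' eclosion balance. A positive equilibrium exists (the colony is *viable*)
#' exactly when `m J / (1 + J) < L / w`, i.e. when brood production can
#' replace forager losses; otherwise the only attractor is the empty colony
#' and the zero state is reported. Eigenvalues of the analytic Jacobian at
#' the returned state are attached for the viable case; at the origin the
#' vector field is not differentiable (the forager fraction is 0/0), so
#' stability of the empty state is a basin property probed by simulation,
#' not by eigenvalues.
#'
#' @param params A [bee_params()] object with `m > 0`. The baseline death
#'   rate `m` is used (`precocious_mode` is ignored here; the feedback has
#'   no positive equilibrium of its own with default settings).
#' @return An object of class `bee_equilibrium`: list with fields `J`,
#'   `H0`, `F0`, `N0` (bees), `viable` (logical) and `eigenvalues`
#'   (complex pair, 1/day; `NA` for the nonviable case).
#' @examples
#' steady_state(bee_params(m = 0.24))
#' steady_state(bee_params(m = 0.40))
#' @export
steady_state <- function(params) {
  J <- equilibrium_ratio(params)
  base <- bee_params(L = params$L, w = params$w, alpha = params$alpha,
                     sigma = params$sigma, m = params$m, m_l = params$m_l,
                     sigma_bar_sq = params$sigma_bar_sq,
                     precocious_mode = "off")
  H0 <- params$L / (params$m * J) - params$w / (1 + J)
  viable <- is.finite(H0) && H0 > 0
  if (viable) {
    F0 <- J * H0
    ev <- jacobian_eigenvalues(H0, F0, base)
  } else {
    H0 <- 0
    F0 <- 0
    ev <- as.complex(c(NA, NA))
  }
  structure(list(J = J, H0 = H0, F0 = F0, N0 = H0 + F0,
                 viable = viable, eigenvalues = ev, params = base),
            class = "bee_equilibrium")
}

#' @export
print.bee_equilibrium <- function(x, ...) {
  cat("Colony steady state (m =", format(x$params$m), "/day)\n")
  if (x$viable) {
    cat(sprintf("  viable: H0 = %.2f, F0 = %.2f, N0 = %.2f bees (J = %.5f)\n",
                x$H0, x$F0, x$N0, x$J))
    cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "/day\n")
  } else {
    cat(sprintf("  not viable (J = %.5f): the empty colony is the attractor\n",
                x$J))
  }
  invisible(x)
}

#' Analytic Jacobian of the colony model
#'
#' Closed-form partial derivatives of `(dH/dt, dF/dt)` with respect to
#' `(H, F)`, including the chain rule through the precocious death-rate
#' feedback when it is active. Requires `N = H + F > 0` (the vector field
#' is not differentiable at the origin).
#'
#' @inheritParams eclosion_rate
#' @return A 2x2 numeric matrix, 1/day.
#' @export
jacobian_matrix <- function(H, F, params) {
  validate_params(params)
  check_state(H, F)
  N <- H + F
  if (N <= 0)
    stop("Jacobian is undefined at the empty colony (N = 0)", call. = FALSE)
  L <- params$L; w <- params$w; s <- params$sigma
  R <- recruitment_rate(H, F, params)
  m_eff <- effective_death_rate(R, params)
  dm <- death_rate_gradient(R, params)
  dEdN <- L * w / (w + N)^2
  dRdH <- s * F / N^2
  dRdF <- -s * H / N^2
  j11 <- dEdN - R - H * dRdH
  j12 <- dEdN - H * dRdF
  j21 <- R + H * dRdH - F * dm * dRdH
  j22 <- H * dRdF - m_eff - F * dm * dRdF
  matrix(c(j11, j21, j12, j22), 2, 2,
         dimnames = list(c("dH", "dF"), c("H", "F")))
}

#' Eigenvalues of the Jacobian at a state
#'
#' Linear growth rates of perturbations about a state; both real parts
#' negative at an equilibrium means local asymptotic stability.
#'
#' @inheritParams eclosion_rate
#' @return Complex vector of length 2, 1/day, ordered by decreasing real
#'   part.
#' @export
jacobian_eigenvalues <- function(H, F, params) {
  ev <- eigen(jacobian_matrix(H, F, params), only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(-Re(ev))]
}

viability_margin <- function(m, params) {
  p <- params
  p$m <- m
  J <- equilibrium_ratio(p)
  m * J / (1 + J) - p$L / p$w
}

#' Critical forager death rate (collapse threshold)
#'
#' Finds the bifurcation point `m*` at which the positive equilibrium
#' disappears: the root of `m J(m) / (1 + J(m)) = L / w` on the viability
#' boundary `H0 = 0`. Colonies persist for every `m` below `m*` and
#' collapse to zero for every `m` above it. With the default parameters
#' `m*` is about 0.355/day, i.e. a mean foraging life of about 2.8 days.
#'
#' @param params A [bee_params()] object (its `m` is ignored).
#' @param bracket Length-2 interval of death rates known to contain the
#'   threshold; viability must differ at the two ends.
#' @param tol Absolute tolerance on `m*`, 1/day.
#' @return The critical death rate `m*`, 1/day, with the number of
#'   root-finder iterations in attribute `"iter"`.
#' @examples
#' critical_death_rate(bee_params())
#' @export
critical_death_rate <- function(params, bracket = c(0.05, 0.60), tol = 1e-8) {
  validate_params(params)
  if (length(bracket) != 2L || !all(is.finite(bracket)) ||
      bracket[1] <= 0 || bracket[1] >= bracket[2])
    stop("bracket must be an increasing positive interval", call. = FALSE)
  g <- vapply(bracket, viability_margin, numeric(1), params = params)
  if (prod(sign(g)) >= 0)
    stop("viability does not change across bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  root <- stats::uniroot(viability_margin, interval = bracket,
                         params = params, tol = tol)
  structure(root$root, iter = root$iter)
}

#' Equilibrium population across a grid of death rates
#'
#' Bifurcation scan: the equilibrium total population `N0` as a function of
#' the forager death rate `m`, with `N0 = 0` on the nonviable branch. On
#' the viable branch `N0` decreases strictly as `m` grows.
#'
#' @param params A [bee_params()] object (its `m` is ignored).
#' @param m_grid Positive death rates to evaluate, 1/day.
#' @return A data frame with columns `m`, `H0`, `F0`, `N0`, `viable`.
#' @export
bifurcation_scan <- function(params,
                             m_grid = seq(0.05, 0.60, length.out = 200)) {
  validate_params(params)
  if (any(m_grid <= 0)) stop("m_grid must be positive", call. = FALSE)
  rows <- lapply(m_grid, function(m) {
    p <- params
    p$m <- m
    eq <- steady_state(p)
    data.frame(m = m, H0 = eq$H0, F0 = eq$F0, N0 = eq$N0,
               viable = eq$viable)
  })
  do.call(rbind, rows)
}
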