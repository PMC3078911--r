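#' Integrate the colony model
#'
#' Adaptive time integration of the hive-bee/forager system with
#' [deSolve::ode()] (lsoda), sampled at fixed output steps. Alongside the
#' state, the trajectory records the instantaneous eclosion rate `E`,
#' per-capita recruitment rate `R` and effective death rate `m_eff` at each
#' sample. Tiny negative excursions produced by the integrator are clipped
#' to zero (the count of clipped samples is kept in attribute `"clipped"`
#' and reported via a message).
#'
#' @param params A [bee_params()] object.
#' @param initial Named numeric vector `c(H = ..., F = ...)`, bees; both
#'   nonnegative.
#' @param t_end Final time, days (> 0).
#' @param output_step Output sampling interval, days (> 0); default 1 day.
#' @param rtol,atol Relative and absolute integration tolerances (absolute
#'   tolerance in bees).
#' @return An object of class `bee_trajectory`: a data frame with columns
#'   `t`, `H`, `F`, `N`, `E`, `R`, `m_eff`, one row per sample, first row
#'   equal to the initial condition. The parameter set is attached as
#'   attribute `"params"`.
#' @examples
#' traj <- simulate_colony(bee_params(m = 0.24), c(H = 9000, F = 0), 100)
#' tail(traj, 3)
#' @export
simulate_colony <- function(params, initial, t_end, output_step = 1,
                            rtol = 1e-8, atol = 1e-6) {
  validate_params(params)
  if (length(initial) != 2L || is.null(names(initial)) ||
      !setequal(names(initial), c("H", "F")))
    stop("initial must be a named vector c(H = ..., F = ...)", call. = FALSE)
  H0 <- unname(initial[["H"]]); F0 <- unname(initial[["F"]])
  check_state(H0, F0)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (!is.numeric(output_step) || output_step <= 0)
    stop("output_step must be > 0", call. = FALSE)

  times <- seq(0, t_end, by = output_step)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  rhs <- function(t, y, p) {
    H <- max(y[[1]], 0); F <- max(y[[2]], 0)
    list(unname(derivatives(H, F, p)))
  }
  out <- deSolve::ode(y = c(H = H0, F = F0), times = times, func = rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    last <- out[nrow(out), ]
    stop(sprintf(paste0("integration failed (istate = %d) at t = %g; ",
                        "last state H = %g, F = %g"),
                 istate[1], last[["time"]], last[["H"]], last[["F"]]),
         call. = FALSE)
  }
  H <- out[, "H"]; F <- out[, "F"]
  clipped <- sum(H < 0) + sum(F < 0)
  if (clipped > 0) {
    message(clipped, " negative sample(s) clipped to 0")
    H <- pmax(H, 0); F <- pmax(F, 0)
  }
  r <- colony_rates(H, F, params)
  traj <- data.frame(t = out[, "time"], H = H, F = F, N = H + F,
                     E = r$E, R = r$R, m_eff = r$m_eff)
  structure(traj, params = params, clipped = clipped,
            class = c("bee_trajectory", "data.frame"))
}

#' Phase portrait: trajectories from many initial conditions
#'
#' Integrates the model from each supplied initial condition, for plotting
#' forager against hive-bee numbers. Below the collapse threshold all
#' trajectories approach the positive equilibrium; above it they approach
#' the empty state. In either case the caste ratio `F/H` relaxes to the
#' slow-manifold value `J` much faster than the total population adjusts.
#'
#' @param params A [bee_params()] object.
#' @param initials Data frame (or matrix) with columns `H` and `F`, one row
#'   per starting state.
#' @param t_end Integration horizon, days.
#' @param ... Passed to [simulate_colony()].
#' @return A list of `bee_trajectory` objects, one per row of `initials`.
#' @export
phase_portrait <- function(params, initials, t_end, ...) {
  initials <- as.data.frame(initials)
  if (nrow(initials) == 0L || !all(c("H", "F") %in% names(initials)))
    stop("initials must have columns H and F and at least one row",
         call. = FALSE)
  lapply(seq_len(nrow(initials)), function(i)
    simulate_colony(params, c(H = initials$H[i], F = initials$F[i]),
                    t_end, ...))
}

#' Relaxation time of the caste ratio versus the population
#'
#' Finds the first time after which the forager-to-hive ratio `F/H` stays
#' within `band * J` of the slow-manifold ratio `J` for the remainder of
#' the trajectory, and, for comparison, the analogous settling time of the
#' total population `N` towards its terminal value. The ratio relaxes on
#' the fast time scale; the population adjusts much more slowly.
#'
#' @param traj A `bee_trajectory`.
#' @param J Target ratio, typically from [equilibrium_ratio()].
#' @param band Relative half-width of the acceptance band around `J`.
#' @return List with elements `ratio` and `population` (days);
#'   `NA_real_` when the corresponding band is never finally entered.
#' @export
ratio_relaxation_time <- function(traj, J, band = 0.05) {
  stopifnot(inherits(traj, "bee_trajectory"), is.numeric(J), J > 0)
  ratio <- ifelse(traj$H > 0, traj$F / traj$H, Inf)
  first_settled <- function(ok) {
    n <- length(ok)
    bad <- which(!ok)
    idx <- if (length(bad) == 0L) 1L
           else if (max(bad) == n) NA_integer_
           else max(bad) + 1L
    if (is.na(idx)) NA_real_ else traj$t[idx]
  }
  Nend <- traj$N[nrow(traj)]
  list(
    ratio = first_settled(abs(ratio - J) <= band * J),
    population = first_settled(abs(traj$N - Nend) <= band * max(Nend, 1))
  )
}

#' Collapse time of a trajectory
#'
#' First time at which the total population falls below a threshold
#' (default 50 bees; below about one bee the continuum model is
#' meaningless, and colonies this small fail for reasons outside the
#' model).
#'
#' @param traj A `bee_trajectory`.
#' @param threshold Population threshold, bees.
#' @return Time in days, or `NA_real_` if the threshold is never crossed.
#' @export
collapse_time <- function(traj, threshold = 50) {
  stopifnot(inherits(traj, "bee_trajectory"))
  idx <- which(traj$N < threshold)
  if (length(idx) == 0L) NA_real_ else traj$t[idx[1]]
}

#' Decline with and without the precocious-mortality feedback
#'
#' Runs the same collapse scenario twice: once with a constant forager
#' death rate (`precocious_mode = "off"`) and once with the Hill-form
#' recruitment-dependent death rate active in the requested mode. Intended
#' for nonviable (collapsing) baselines; a warning is issued if the
#' baseline is viable. Note that with the default feedback parameters the
#' replacement death rate is *smaller* than a super-critical baseline `m`
#' whenever `|R|` is modest, so the feedback as specified does not
#' necessarily accelerate the decline; see the package vignette for an
#' analysis.
#'
#' @param params A [bee_params()] object; its `m`, `m_l` and
#'   `sigma_bar_sq` are shared by both runs.
#' @param initial Named vector `c(H = ..., F = ...)`.
#' @param t_end Horizon, days.
#' @param mode Feedback mode for the modified run:
#'   `"when_R_negative"` or `"always"`.
#' @param ... Passed to [simulate_colony()].
#' @return List with `bee_trajectory` elements `baseline` and `precocious`.
#' @export
decline_comparison <- function(params, initial, t_end,
                               mode = c("when_R_negative", "always"), ...) {
  mode <- match.arg(mode)
  validate_params(params)
  if (steady_state(params)$viable)
    warning("baseline parameters are viable; this is not a collapse scenario",
            call. = FALSE)
  base <- params; base$precocious_mode <- "off"
  prec <- params; prec$precocious_mode <- mode
  list(baseline = simulate_colony(base, initial, t_end, ...),
       precocious = simulate_colony(prec, initial, t_end, ...))
}
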