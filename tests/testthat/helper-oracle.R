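# Shared helpers: finite-difference Jacobian, a brute-force RK4 integrator
# kept deliberately independent of simulate_colony()/deSolve for
# cross-checks, and a generator of random viable parameter sets.

fd_jacobian <- function(H, F, params, h = 1e-4) {
  cols <- lapply(list(c(h, 0), c(0, h)), function(d) {
    (derivatives(H + d[1], F + d[2], params) -
       derivatives(max(H - d[1], 0), max(F - d[2], 0), params)) / (2 * h)
  })
  matrix(c(cols[[1]], cols[[2]]), 2, 2)
}

# fixed-step classical RK4 on the model equations, written out directly
rk4_integrate <- function(params, H0, F0, t_end, dt = 0.02) {
  n <- ceiling(t_end / dt)
  y <- c(H0, F0)
  f <- function(y) {
    H <- max(y[1], 0); F <- max(y[2], 0); N <- H + F
    E <- if (N > 0) params$L * N / (params$w + N) else 0
    R <- if (N > 0) params$alpha - params$sigma * F / N else params$alpha
    meff <- switch(params$precocious_mode,
                   off = params$m,
                   when_R_negative = if (R < 0)
                     params$m_l * R^2 / (params$sigma_bar_sq + R^2)
                   else params$m,
                   always = params$m_l * R^2 / (params$sigma_bar_sq + R^2))
    c(E - H * R, H * R - meff * F)
  }
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c(H = y[1], F = y[2])
}

random_viable_params <- function(n, seed = 42) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- runif(1, 1000, 3000)
    alpha <- runif(1, 0.20, 0.30)
    # keep L/w well below alpha so a collapse threshold m* exists
    p <- bee_params(L = L,
                    w = runif(1, L / (0.55 * alpha), 45000),
                    alpha = alpha,
                    sigma = runif(1, 0.50, 1.00),
                    m = 0.1)
    mstar <- critical_death_rate(p, bracket = c(0.005, 50))
    p$m <- runif(1, 0.3, 0.85) * as.numeric(mstar)
    out[[i]] <- p
  }
  out
}
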