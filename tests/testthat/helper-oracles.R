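# Shared fixtures and independent oracles.

mouse_phys <- load_species_physiology("mouse", 28)

# Finite-difference oracle for steady convection-diffusion across a pore
# pathway. Solves v c - D c' = const on x in [0, 1] with c(0) = Cp,
# c(1) = Ci by central differences on a fine grid and returns the flux.
# Independent of the closed-form Patlak expression.
fd_pore_flux <- function(C_plasma, C_interstitial, J, PS, sigma, N = 4000) {
  v <- J * (1 - sigma)           # effective convective velocity x area
  D <- PS                        # diffusive conductance (unit path)
  if (D <= 0) stop("oracle needs PS > 0")
  h <- 1 / N
  # steady state: v c'(x) - D c''(x) = 0, Dirichlet BCs
  # central differences: v (c[i+1]-c[i-1])/(2h) - D (c[i+1]-2c[i]+c[i-1])/h^2
  n_int <- N - 1
  lower <- -v / (2 * h) - D / h^2
  diagc <- 2 * D / h^2
  upper <- v / (2 * h) - D / h^2
  A <- matrix(0, n_int, n_int)
  rhs <- numeric(n_int)
  for (i in seq_len(n_int)) {
    A[i, i] <- diagc
    if (i > 1) A[i, i - 1] <- lower
    if (i < n_int) A[i, i + 1] <- upper
  }
  rhs[1] <- -lower * C_plasma
  rhs[n_int] <- -upper * C_interstitial
  c_int <- solve(A, rhs)
  cfull <- c(C_plasma, c_int, C_interstitial)
  # flux at x = 0 from a second-order one-sided derivative
  dc0 <- (-3 * cfull[1] + 4 * cfull[2] - cfull[3]) / (2 * h)
  v * cfull[1] - D * dc0
}

# Quick simulation of the default mouse IP scenario on a coarse time grid.
quick_sim <- function(scenario = pbpk_scenario(), phys = NULL, ...) {
  scenario$output_times <- seq(0, scenario$duration, length.out = 57)
  simulate_pbpk(scenario, phys, ...)
}
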