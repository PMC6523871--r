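#' Particle-specific kinetic parameters
#'
#' All drug-specific constants of the model. Defaults are the fixed
#' literature constants (KM, CLup, CLrec, KAbs, FupM, FrecM) together with
#' the optimized mouse estimates for the four fitted parameters: maximum
#' phagocytosis rate Pup = 0.995 mL/h/mL macrophages, biliary excretion
#' KBile = 0.0128 1/h, lymph reflection coefficient sigma_IS = 0.64 and IP
#' absorbed fraction F = 0.76.
#'
#' @param Pup Maximum phagocytosis rate (mL/h per mL macrophages).
#' @param KM Half-saturation concentration in cells (ug/mL).
#' @param CLup Pinocytosis rate (mL/h per mL endothelium or hepatocytes).
#' @param CLrec Exocytosis rate (mL/h per mL cells).
#' @param KBile First-order biliary excretion rate from hepatocytes (1/h).
#' @param sigma_IS Lymph reflection coefficient in [0, 1].
#' @param F Fraction of an IP dose that is absorbable (the remainder stays
#'   sequestered in the peritoneal space).
#' @param KAbs First-order IP absorption rate constant (1/h).
#' @param FupM Fraction of liver phagocytic uptake drawn from plasma.
#' @param FrecM Fraction of liver macrophage exocytosis returned to plasma.
#' @param solute_radius Particle hydrodynamic radius (nm); when `NULL` it is
#'   taken from the scenario's particle.
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(Pup = 0.995, KM = 5000, CLup = 0.05,
                            CLrec = 0.05, KBile = 0.0128, sigma_IS = 0.64,
                            F = 0.76, KAbs = 0.1, FupM = 0.5, FrecM = 0.5,
                            solute_radius = NULL) {
  vals <- list(Pup = Pup, KM = KM, CLup = CLup, CLrec = CLrec,
               KBile = KBile, sigma_IS = sigma_IS, F = F, KAbs = KAbs,
               FupM = FupM, FrecM = FrecM, solute_radius = solute_radius)
  for (nm in c("Pup", "KM", "CLup", "CLrec", "KBile", "KAbs"))
    if (vals[[nm]] < 0) stop(nm, " must be non-negative")
  for (nm in c("sigma_IS", "F", "FupM", "FrecM"))
    if (vals[[nm]] < 0 || vals[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (!is.null(solute_radius) && solute_radius <= 0)
    stop("solute_radius must be positive (nm)")
  structure(vals, class = "drug_parameters")
}

#' Default study particle
#'
#' The two study formulations (EGCG- and curcumin-capped gold nanoparticles)
#' had near-identical characterization and are treated as equivalent in the
#' model; the default particle takes the mean hydrodynamic diameter
#' (22.31 nm) and mean core diameter (7.0 nm) of the two arms.
#'
#' @return A [particle_properties()] object.
#' @export
default_study_particle <- function() {
  particle_properties("pooled-AuNP",
                      hydrodynamic_diameter = (25.00 + 19.62) / 2,
                      core_diameter = (7.78 + 6.21) / 2,
                      mass_concentration = 700)
}

#' Simulation scenario
#'
#' One simulated experiment: species, body weight, dose, route, particle and
#' output schedule.
#'
#' @param species_id `"mouse"` or `"rat"`.
#' @param body_weight Body weight (g).
#' @param dose Dose in mg Au per kg body weight.
#' @param route `"IV"` or `"IP"`.
#' @param particle A [particle_properties()] object.
#' @param duration Simulation horizon (h), default 56 days.
#' @param output_times Output times (h), sorted within `[0, duration]`;
#'   default a grid of ~340 points over the horizon.
#' @return An object of class `pbpk_scenario`.
#' @export
pbpk_scenario <- function(species_id = "mouse",
                          body_weight = c(mouse = 28, rat = 280)[[species_id]],
                          dose = 10,
                          route = c("IP", "IV"),
                          particle = default_study_particle(),
                          duration = 56 * 24,
                          output_times = NULL) {
  route <- match.arg(route)
  if (!species_id %in% c("mouse", "rat"))
    stop("unsupported species: ", species_id)
  if (dose <= 0) stop("dose must be strictly positive (mg Au/kg)")
  if (body_weight <= 0) stop("body_weight must be positive (g)")
  if (duration <= 0) stop("duration must be positive (h)")
  if (is.null(output_times))
    output_times <- seq(0, duration, length.out = 337)
  output_times <- sort(unique(output_times))
  if (any(output_times < 0) || any(output_times > duration))
    stop("output_times must lie within [0, duration]")
  structure(list(species_id = species_id, body_weight = body_weight,
                 dose = dose, route = route, particle = particle,
                 duration = duration, output_times = output_times),
            class = "pbpk_scenario")
}

#' Saturable phagocytic clearance
#'
#' Michaelis-Menten approximation of the volumetric phagocytosis clearance
#' of one organ's macrophage pool:
#' Pup_i = Pup * ViM * (1 - CiM / (KM + CiM)) = Pup * ViM * KM / (KM + CiM).
#' The clearance is maximal for empty macrophages and vanishes as the
#' intracellular concentration saturates.
#'
#' @param CiM Macrophage nanoparticle concentration (ug/mL).
#' @param ViM Macrophage volume (mL).
#' @param drug A [drug_parameters()] object.
#' @return Volumetric clearance (mL/h).
#' @export
phagocytosis_clearance <- function(CiM, ViM, drug = drug_parameters()) {
  if (any(CiM < 0) || any(ViM < 0))
    stop("CiM and ViM must be non-negative")
  drug$Pup * ViM * drug$KM / (drug$KM + CiM)
}

# State-vector bookkeeping -------------------------------------------------

.state_names <- function() {
  per_organ <- as.vector(t(outer(.ORGANS,
                                 c("plasma", "endothelium", "interstitial",
                                   "macrophage"), paste, sep = ".")))
  c(per_organ, "venous_plasma", "arterial_plasma", "blood_phagocytes",
    "lymph_node", "hepatocytes", "excreted", "ip_depot", "ip_sequestered")
}

#' Initial state vector for a scenario
#'
#' IV: the full dose is a bolus into venous plasma. IP: the absorbable
#' fraction `F` of the dose enters a first-order depot whose destinations
#' are the five portal organs' interstitial spaces (90%, weighted by organ
#' volume) and the lymph node (10%); the remaining `(1 - F)` of the dose
#' stays sequestered in the peritoneal space and is never absorbed.
#'
#' @param scenario A [pbpk_scenario()].
#' @param physiology A `species_physiology`.
#' @param drug A [drug_parameters()].
#' @param ip_literal_complement If `TRUE`, use the literal complementary
#'   convention in which `(1 - F)` (rather than `F`) of the dose is
#'   distributed; default `FALSE`.
#' @return Named numeric state vector (ug) with attribute `dose_ug`.
#' @export
initialize_state <- function(scenario, physiology, drug = drug_parameters(),
                             ip_literal_complement = FALSE) {
  y <- stats::setNames(numeric(length(.state_names())), .state_names())
  dose_ug <- scenario$dose * scenario$body_weight  # mg/kg * g = ug
  if (scenario$route == "IV") {
    y["venous_plasma"] <- dose_ug
  } else if (scenario$route == "IP") {
    f_abs <- if (ip_literal_complement) 1 - drug$F else drug$F
    y["ip_depot"] <- f_abs * dose_ug
    y["ip_sequestered"] <- (1 - f_abs) * dose_ug
  } else stop("unknown route: ", scenario$route)
  attr(y, "dose_ug") <- dose_ug
  y
}

# IP destination weights over organ interstitia (0.9 split by portal organ
# volume) and the lymph node (0.1); weights sum to 1.
.ip_weights <- function(physiology) {
  org <- physiology$organs
  w <- numeric(nrow(org))
  Vportal <- sum(org$total_volume[org$is_portal])
  w[org$is_portal] <- 0.9 * org$total_volume[org$is_portal] / Vportal
  list(organ = w, lymph = 0.1)
}

#' Assemble the model context for simulation
#'
#' Precomputes all per-organ volumes, flows and two-pore transport
#' coefficients and packs them into the flat parameter vector consumed by
#' the compiled right-hand side.
#'
#' @inheritParams initialize_state
#' @param pores A [pore_system()].
#' @param blood_phagocytes Include the circulating phagocyte pool?
#' @return List with the parameter vector (`parms`), the state names and
#'   derived per-organ quantities.
#' @keywords internal
build_model_context <- function(scenario, physiology,
                                drug = drug_parameters(),
                                pores = pore_system(),
                                blood_phagocytes = TRUE,
                                ip_literal_complement = FALSE) {
  org <- physiology$organs
  n <- nrow(org)
  r_sol <- drug$solute_radius %||% solute_radius(scenario$particle)

  vols <- lapply(seq_len(n), function(i)
    subcompartment_volumes(org[i, ], physiology))
  Vpl <- vapply(vols, `[[`, 0, "plasma")
  VE  <- vapply(vols, `[[`, 0, "endothelium")
  VIS <- vapply(vols, `[[`, 0, "interstitial")
  VM  <- vapply(vols, `[[`, 0, "macrophage")
  VH  <- vols[[match("liver", org$organ)]]$hepatocyte

  tp <- lapply(org$lymph_flow, pore_transport_coefficients,
               solute_radius = r_sol, pores = pores)
  JL  <- vapply(tp, function(x) x$large$J, 0)
  PSL <- vapply(tp, function(x) x$large$PS, 0)
  sigL <- vapply(tp, function(x) x$large$sigma, 0)
  JS  <- vapply(tp, function(x) x$small$J, 0)
  PSS <- vapply(tp, function(x) x$small$PS, 0)
  sigS <- vapply(tp, function(x) x$small$sigma, 0)

  w <- .ip_weights(physiology)
  VBP <- physiology$blood_phagocyte_fraction * physiology$blood_volume
  CLren <- renal_clearance_switch(scenario$particle)

  parms <- c(n,
             org$plasma_flow, org$lymph_flow, Vpl, VE, VIS, VM,
             JL, PSL, sigL, JS, PSS, sigS,
             w$organ, as.numeric(org$is_portal),
             drug$Pup, drug$KM, drug$CLup, drug$CLrec, drug$KBile,
             drug$sigma_IS, drug$FupM, drug$FrecM, drug$KAbs,
             VH, physiology$lymph_node_volume,
             physiology$venous_plasma_volume,
             physiology$arterial_plasma_volume,
             VBP, total_lymph_flow(physiology),
             physiology$cardiac_plasma_flow,
             w$lymph, CLren, as.numeric(blood_phagocytes),
             match("liver", org$organ), match("lungs", org$organ),
             match("kidneys", org$organ))

  list(parms = parms, state_names = .state_names(), organs = org$organ,
       volumes = list(plasma = Vpl, endothelium = VE, interstitial = VIS,
                      macrophage = VM, hepatocyte = VH, VBP = VBP),
       transport = tp, solute_radius = r_sol,
       ip_weights = w, renal_clearance = CLren,
       ip_literal_complement = ip_literal_complement)
}

#' Reference R implementation of the model right-hand side
#'
#' A direct R transcription of the system of mass-balance ODEs. Used as the
#' readable reference and cross-checked against the compiled version; the
#' compiled version is what [simulate_pbpk()] integrates by default.
#'
#' @param t Time (h; the system is autonomous).
#' @param y Named state vector (ug).
#' @param parms Parameter vector from [build_model_context()].
#' @return List with the derivative vector, as required by deSolve.
#' @keywords internal
pbpk_rhs_R <- function(t, y, parms) {
  p <- parms
  n <- as.integer(p[1])
  blk <- function(b) p[1 + (b - 1) * n + seq_len(n)]
  Q <- blk(1); L <- blk(2); Vpl <- blk(3); VE <- blk(4); VIS <- blk(5)
  VM <- blk(6); JL <- blk(7); PSL <- blk(8); sigL <- blk(9)
  JS <- blk(10); PSS <- blk(11); sigS <- blk(12); w_ip <- blk(13)
  is_portal <- blk(14) > 0.5
  s <- 1 + 14 * n
  Pup <- p[s + 1]; KM <- p[s + 2]; CLup <- p[s + 3]; CLrec <- p[s + 4]
  KBile <- p[s + 5]; sigIS <- p[s + 6]; FupM <- p[s + 7]; FrecM <- p[s + 8]
  KAbs <- p[s + 9]; VH <- p[s + 10]; VLN <- p[s + 11]; Vven <- p[s + 12]
  Vart <- p[s + 13]; VBP <- p[s + 14]; Ltot <- p[s + 15]; CO <- p[s + 16]
  wlym <- p[s + 17]; CLren <- p[s + 18]; bp_on <- p[s + 19] > 0.5
  liver <- as.integer(p[s + 20]); lung <- as.integer(p[s + 21])
  kidney <- as.integer(p[s + 22])

  conc <- function(a, v) ifelse(v > 0, a / v, 0)
  ipl <- (seq_len(n) - 1) * 4 + 1
  A_pl <- y[ipl]; A_E <- y[ipl + 1]; A_IS <- y[ipl + 2]; A_M <- y[ipl + 3]
  iven <- 4 * n + 1; iart <- iven + 1; ibp <- iven + 2; iln <- iven + 3
  ihep <- iven + 4; iexc <- iven + 5; idep <- iven + 6; iseq <- iven + 7

  Cpl <- conc(A_pl, Vpl); CE <- conc(A_E, VE); CIS <- conc(A_IS, VIS)
  CM <- conc(A_M, VM)
  Cven <- conc(y[iven], Vven); Cart <- conc(y[iart], Vart)
  CLN <- conc(y[iln], VLN); Adep <- y[idep]

  f2p <- vapply(seq_len(n), function(i)
    patlak_solute_flux(Cpl[i], CIS[i], JL[i], PSL[i], sigL[i]) +
      patlak_solute_flux(Cpl[i], CIS[i], JS[i], PSS[i], sigS[i]), 0)
  f_up <- CLup * VE * Cpl
  f_rec <- CLrec * VE * CE
  pupcl <- Pup * VM * KM / (KM + CM)
  f_exo <- CLrec * VM * CM

  f_phag_pl <- numeric(n); f_exo_pl <- numeric(n)
  f_phag_is <- pupcl * CIS; f_exo_is <- f_exo
  f_phag_pl[liver] <- FupM * pupcl[liver] * Cpl[liver]
  f_phag_is[liver] <- (1 - FupM) * pupcl[liver] * CIS[liver]
  f_exo_pl[liver] <- FrecM * f_exo[liver]
  f_exo_is[liver] <- (1 - FrecM) * f_exo[liver]
  f_lym <- (1 - sigIS) * L * CIS

  d_pl <- -f2p - f_up - f_phag_pl + f_exo_pl
  d_E <- f_up - f_rec
  d_IS <- f2p + f_rec - f_phag_is + f_exo_is - f_lym + KAbs * Adep * w_ip
  d_M <- f_phag_pl + f_phag_is - f_exo

  # circulation
  ven_in <- 0; art_in <- 0; portal_out <- 0; Qportal_out <- 0
  for (i in seq_len(n)) {
    if (i == lung) {
      d_pl[i] <- d_pl[i] + CO * Cven - (CO - L[i]) * Cpl[i]
      art_in <- (CO - L[i]) * Cpl[i]
    } else if (is_portal[i]) {
      d_pl[i] <- d_pl[i] + Q[i] * Cart - (Q[i] - L[i]) * Cpl[i]
      portal_out <- portal_out + (Q[i] - L[i]) * Cpl[i]
      Qportal_out <- Qportal_out + (Q[i] - L[i])
    } else if (i != liver) {
      d_pl[i] <- d_pl[i] + Q[i] * Cart - (Q[i] - L[i]) * Cpl[i]
      ven_in <- ven_in + (Q[i] - L[i]) * Cpl[i]
    }
  }
  Qout_liv <- Q[liver] + Qportal_out - L[liver]
  d_pl[liver] <- d_pl[liver] + Q[liver] * Cart + portal_out -
    Qout_liv * Cpl[liver]
  ven_in <- ven_in + Qout_liv * Cpl[liver]

  # hepatocytes and excretion
  f_hep_up <- CLup * VH * CIS[liver]
  f_hep_rec <- CLrec * y[ihep]
  f_bile <- KBile * y[ihep]
  d_IS[liver] <- d_IS[liver] - f_hep_up + f_hep_rec
  d_hep <- f_hep_up - f_hep_rec - f_bile
  d_exc <- f_bile
  if (CLren > 0) {
    f_ren <- CLren * Cpl[kidney]
    d_pl[kidney] <- d_pl[kidney] - f_ren
    d_exc <- d_exc + f_ren
  }

  # blood phagocytes
  d_bp <- 0; bp_ven <- 0; bp_art <- 0
  if (bp_on && VBP > 0) {
    CBP <- conc(y[ibp], VBP)
    pupbp <- Pup * VBP * KM / (KM + CBP)
    sv <- Vven / (Vven + Vart)
    up_v <- pupbp * sv * Cven; up_a <- pupbp * (1 - sv) * Cart
    rec <- CLrec * VBP * CBP
    d_bp <- up_v + up_a - rec
    bp_ven <- -up_v + sv * rec
    bp_art <- -up_a + (1 - sv) * rec
  }

  dy <- numeric(length(y))
  dy[ipl] <- d_pl; dy[ipl + 1] <- d_E; dy[ipl + 2] <- d_IS; dy[ipl + 3] <- d_M
  dy[iven] <- ven_in - CO * Cven + Ltot * CLN + bp_ven
  dy[iart] <- art_in - CO * Cart + bp_art
  dy[ibp] <- d_bp
  dy[iln] <- sum(f_lym) + KAbs * Adep * wlym - Ltot * CLN
  dy[ihep] <- d_hep
  dy[iexc] <- d_exc
  dy[idep] <- -KAbs * Adep
  dy[iseq] <- 0
  list(dy)
}

#' Simulate the whole-body PBPK model
#'
#' Integrates the stiff ODE system over the scenario horizon and returns
#' the full state trajectory together with organ totals and percent of
#' injected dose.
#'
#' @inheritParams build_model_context
#' @param rtol,atol Integrator tolerances (lsoda); `atol` defaults to
#'   1e-10 of the dose.
#' @param engine `"compiled"` (default) uses the C right-hand side;
#'   `"R"` uses the reference R implementation.
#' @return An object of class `pbpk_sim` with elements `times` (h),
#'   `states` (time x state matrix, ug), `organ_totals` (time x organ, ug),
#'   `percent_id`, `dose_ug`, `mass_residual` and the inputs.
#' @examples
#' \donttest{
#' phys <- load_species_physiology("mouse", 28)
#' sim <- simulate_pbpk(pbpk_scenario(), phys)
#' summary(sim)
#' }
#' @export
simulate_pbpk <- function(scenario, physiology = NULL,
                          drug = drug_parameters(),
                          pores = pore_system(),
                          blood_phagocytes = TRUE,
                          ip_literal_complement = FALSE,
                          rtol = 1e-8, atol = NULL,
                          engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (is.null(physiology))
    physiology <- load_species_physiology(scenario$species_id,
                                          scenario$body_weight)
  ctx <- build_model_context(scenario, physiology, drug, pores,
                             blood_phagocytes, ip_literal_complement)
  y0 <- initialize_state(scenario, physiology, drug, ip_literal_complement)
  dose_ug <- attr(y0, "dose_ug")
  if (is.null(atol)) atol <- 1e-10 * dose_ug
  times <- scenario$output_times
  if (times[1] > 0) times <- c(0, times)

  if (engine == "compiled") {
    out <- deSolve::lsoda(y = as.numeric(y0), times = times,
                          func = "goldpbpk_derivs", parms = ctx$parms,
                          dllname = "goldpbpk",
                          initfunc = "goldpbpk_initmod",
                          rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    out <- deSolve::lsoda(y = as.numeric(y0), times = times,
                          func = pbpk_rhs_R, parms = ctx$parms,
                          rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  states <- out[, -1, drop = FALSE]
  colnames(states) <- ctx$state_names
  bad <- which(!is.finite(states) | states < -1e-6 * dose_ug, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite or negative state during integration: ",
         ctx$state_names[bad[1, 2]])
  states[states < 0] <- 0

  organ_totals <- sapply(seq_along(.ORGANS), function(i) {
    cols <- (i - 1) * 4 + 1:4
    tot <- rowSums(states[, cols, drop = FALSE])
    if (.ORGANS[i] == "liver") tot <- tot + states[, "hepatocytes"]
    tot
  })
  if (is.null(dim(organ_totals)))
    organ_totals <- matrix(organ_totals, nrow = 1)
  colnames(organ_totals) <- .ORGANS

  total <- rowSums(states)
  res <- structure(list(
    times = out[, 1], states = states, organ_totals = organ_totals,
    percent_id = organ_totals / dose_ug * 100,
    dose_ug = dose_ug,
    mass_residual = max(abs(total - dose_ug)) / dose_ug,
    scenario = scenario, physiology = physiology, drug = drug,
    pores = pores, context = ctx, engine = engine
  ), class = "pbpk_sim")
  res
}

#' Mass-balance residual of a simulation
#'
#' Maximum over output times of |sum of all compartments, sinks and depots
#' minus the administered dose| relative to the dose.
#'
#' @param result A `pbpk_sim` object.
#' @param dose Dose in ug (default: the simulation's own dose).
#' @return Maximum relative residual (dimensionless).
#' @export
mass_balance <- function(result, dose = result$dose_ug) {
  total <- rowSums(result$states)
  max(abs(total - dose)) / dose
}

#' Organ amounts at selected times
#'
#' Linear interpolation of an organ's total amount (or percent of injected
#' dose) at arbitrary times within the simulated horizon.
#'
#' @param result A `pbpk_sim`.
#' @param organ Organ name.
#' @param times_h Times (h).
#' @param percent_id Return %ID instead of ug?
#' @return Numeric vector.
#' @export
organ_amount <- function(result, organ, times_h, percent_id = FALSE) {
  if (!organ %in% colnames(result$organ_totals))
    stop("unknown organ: ", organ)
  y <- if (percent_id) result$percent_id[, organ]
       else result$organ_totals[, organ]
  stats::approx(result$times, y, xout = times_h, rule = 2)$y
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s %.4g g, %.4g mg Au/kg %s (dose %.4g ug)\n",
              x$scenario$species_id, x$scenario$body_weight,
              x$scenario$dose, x$scenario$route, x$dose_ug))
  cat(sprintf("  horizon: %.4g h (%d output times); mass residual %.2e\n",
              max(x$times), length(x$times), x$mass_residual))
  cat("  terminal %ID (top organs):\n")
  last <- sort(x$percent_id[nrow(x$percent_id), ], decreasing = TRUE)[1:5]
  for (nm in names(last)) cat(sprintf("    %-16s %7.3f\n", nm, last[nm]))
  invisible(x)
}

#' @export
summary.pbpk_sim <- function(object, ...) {
  last <- nrow(object$percent_id)
  out <- data.frame(
    organ = colnames(object$organ_totals),
    terminal_ug = object$organ_totals[last, ],
    terminal_percent_id = object$percent_id[last, ],
    peak_percent_id = apply(object$percent_id, 2, max),
    row.names = NULL
  )
  structure(list(table = out,
                 excreted_ug = object$states[last, "excreted"],
                 mass_residual = object$mass_residual,
                 dose_ug = object$dose_ug),
            class = "summary.pbpk_sim")
}

#' @export
print.summary.pbpk_sim <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("excreted: %.4g ug (%.2f %%ID); mass residual %.2e\n",
              x$excreted_ug, 100 * x$excreted_ug / x$dose_ug,
              x$mass_residual))
  invisible(x)
}

#' @export
plot.pbpk_sim <- function(x, organs = c("liver", "spleen", "lungs",
                                        "kidneys", "stomach", "heart"),
                          log = "", ...) {
  pid <- x$percent_id[, organs, drop = FALSE]
  graphics::matplot(x$times / 24, pid, type = "l", lty = 1,
                    xlab = "time (days)", ylab = "% injected dose",
                    log = log, ...)
  graphics::legend("topright", legend = organs, col = seq_along(organs),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.pbpk_sim <- function(x, ...) {
  long <- expand.grid(time_h = x$times, organ = colnames(x$organ_totals),
                      stringsAsFactors = FALSE)
  long$amount_ug <- as.vector(x$organ_totals)
  long$percent_id <- as.vector(x$percent_id)
  long
}
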