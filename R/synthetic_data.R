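#' Multiplicative noise model for synthetic observations
#'
#' Lognormal multiplicative between-animal variability with a given
#' coefficient of variation. The draw is mean-preserving: the expected value
#' of a replicate equals the model prediction.
#'
#' @param type Only `"lognormal"` is implemented.
#' @param cv Coefficient of variation (default 0.40, matching the wide
#'   between-animal variability of rodent biodistribution data).
#' @param seed Optional integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(type = "lognormal", cv = 0.40, seed = NULL) {
  type <- match.arg(type)
  if (cv < 0) stop("cv must be non-negative")
  structure(list(type = type, cv = cv, seed = seed), class = "noise_model")
}

#' Default sacrifice-group study design
#'
#' Groups of animals sacrificed at 1, 7, 14, 28 and 56 days with the six
#' measured organs (liver, spleen, lungs, stomach, kidneys, heart).
#'
#' @param times_days Sacrifice days.
#' @param organs Organs measured at sacrifice.
#' @param n Animals per group (single value or one per time point).
#' @return List describing the design.
#' @export
study_design <- function(times_days = c(1, 7, 14, 28, 56),
                         organs = c("liver", "spleen", "lungs", "stomach",
                                    "kidneys", "heart"),
                         n = 6) {
  if (length(n) == 1) n <- rep(n, length(times_days))
  if (length(n) != length(times_days))
    stop("n must have length 1 or length(times_days)")
  if (!all(organs %in% .ORGANS)) stop("unknown organ in design")
  list(times_days = times_days, organs = organs, n = n)
}

#' Generate synthetic biodistribution observations
#'
#' Simulates the true model for a scenario, then draws `n` lognormal
#' multiplicative replicates per organ and sacrifice time with the stated
#' CV, and records the per-group mean, standard deviation and group size.
#' With `cv = 0` the observations equal the model predictions exactly.
#'
#' @param scenario A [pbpk_scenario()].
#' @param physiology A `species_physiology` (default from the scenario).
#' @param drug [drug_parameters()] used as the generating truth.
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param pores A [pore_system()].
#' @param keep_replicates Attach the individual replicate draws as an
#'   attribute?
#' @return An `observation_set` data frame (columns `organ`, `time_days`,
#'   `value` (ug), `value_type = "amount_ug"`, `n`, `sd`) with metadata
#'   attributes.
#' @export
generate_synthetic_observations <- function(scenario = pbpk_scenario(),
                                            physiology = NULL,
                                            drug = drug_parameters(),
                                            design = study_design(),
                                            noise = noise_model(),
                                            pores = pore_system(),
                                            keep_replicates = FALSE) {
  if (is.null(physiology))
    physiology <- load_species_physiology(scenario$species_id,
                                          scenario$body_weight)
  if (max(design$times_days) * 24 > scenario$duration)
    stop("design times exceed the simulation horizon")
  if (!is.null(noise$seed)) set.seed(noise$seed)

  sc <- scenario
  sc$output_times <- sort(unique(c(design$times_days * 24,
                                   scenario$duration)))
  sim <- simulate_pbpk(sc, physiology, drug, pores)

  sdlog <- sqrt(log(1 + noise$cv^2))
  rows <- list(); reps <- list()
  for (ti in seq_along(design$times_days)) {
    td <- design$times_days[ti]
    for (org in design$organs) {
      mu <- organ_amount(sim, org, td * 24)
      n <- design$n[ti]
      draw <- if (noise$cv > 0 && mu > 0)
        stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      else rep(mu, n)
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, time_days = td, value = mean(draw),
        value_type = "amount_ug", n = n,
        sd = if (n > 1) stats::sd(draw) else 0,
        stringsAsFactors = FALSE)
      if (keep_replicates)
        reps[[paste(org, td, sep = "@")]] <- draw
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(species = scenario$species_id,
                            dose = scenario$dose, route = scenario$route,
                            particle = scenario$particle$label,
                            source = "synthetic", cv = noise$cv,
                            seed = noise$seed)
  if (keep_replicates) attr(out, "replicates") <- reps
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Load a packaged fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`mouse_liver_means`}{The ten printed liver means (percent of
#'     injected dose at days 1, 7, 14, 28, 56 for the EGCG- and
#'     curcumin-capped arms) of the mouse 10 mg Au/kg IP study.}
#'   \item{`rat_scenario_balasubramanian`}{Rat 280 g, 0.01 mg Au/kg IV,
#'     20 nm (TEM) citrate-capped gold, 60-day horizon.}
#'   \item{`rat_scenario_fraga`}{Rat 280 g, 0.7 mg Au/kg IV, 16 nm (TEM)
#'     citrate-capped gold, 28-day horizon.}
#' }
#' The rat fixtures are scenario definitions only (no observed values are
#' packaged; the literature organ data exist only as figures). Their
#' hydrodynamic diameter is set to 46 nm, i.e. the 23 nm median evaluation
#' hydrodynamic radius.
#'
#' @param name Fixture name.
#' @return An `observation_set` or a [pbpk_scenario()].
#' @examples
#' obs <- load_fixture("mouse_liver_means")
#' obs$value[obs$time_days == 1]  # 33.11 19.28
#' @export
load_fixture <- function(name) {
  if (name == "mouse_liver_means") {
    path <- system.file("extdata", "mouse_liver_means.csv",
                        package = "goldpbpk", mustWork = TRUE)
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    attr(out, "meta") <- list(species = "mouse", dose = 10, route = "IP",
                              particle = "EGCG-AuNP / Curc-AuNP",
                              source = "in-paper liver means")
    class(out) <- c("observation_set", "data.frame")
    return(out)
  }
  if (name == "rat_scenario_balasubramanian")
    return(pbpk_scenario(
      species_id = "rat", body_weight = 280, dose = 0.01, route = "IV",
      particle = particle_properties("citrate-AuNP-20nm",
                                     hydrodynamic_diameter = 46,
                                     core_diameter = 20),
      duration = 60 * 24))
  if (name == "rat_scenario_fraga")
    return(pbpk_scenario(
      species_id = "rat", body_weight = 280, dose = 0.7, route = "IV",
      particle = particle_properties("citrate-AuNP-16nm",
                                     hydrodynamic_diameter = 46,
                                     core_diameter = 16),
      duration = 28 * 24))
  stop("unknown fixture: ", name)
}
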