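#' Absolute average fold error
#'
#' AAFE = 10 ^ ((1/n) * sum |log10(pred_i / obs_i)|). Equals 1 for perfect
#' predictions, is symmetric under prediction/observation inversion, and is
#' invariant to a common rescaling of both vectors. Non-positive pairs are
#' excluded (log undefined) and their count reported via a message.
#'
#' @param predicted,observed Positive numeric vectors of equal length.
#' @return Dimensionless fold error, >= 1.
#' @examples
#' aafe(c(2, 2), c(1, 1))  # 2
#' @export
aafe <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  keep <- predicted > 0 & observed > 0 & is.finite(predicted) &
    is.finite(observed)
  if (sum(!keep) > 0)
    message("aafe: excluded ", sum(!keep), " non-positive pair(s)")
  if (!any(keep)) stop("no positive prediction/observation pairs")
  10^(mean(abs(log10(predicted[keep] / observed[keep]))))
}

#' Default bounds for the four fitted parameters
#'
#' Pup is bounded by the literature range 0.075-40 mL/h/mL macrophages;
#' KBile, sigma_IS and F take their natural physical ranges.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function() {
  list(Pup = c(0.075, 40), KBile = c(0, 1),
       sigma_IS = c(0, 1), F = c(0, 1))
}

# Predicted organ amounts (ug) at the observation records' organs/times.
.predict_observations <- function(data, scenario, physiology, drug, pores,
                                  rtol = 1e-6) {
  t_h <- data$time_days * 24
  sc <- scenario
  sc$output_times <- sort(unique(c(t_h, scenario$duration)))
  sim <- simulate_pbpk(sc, physiology, drug, pores, rtol = rtol)
  vapply(seq_len(nrow(data)), function(i)
    organ_amount(sim, data$organ[i], t_h[i]), 0)
}

# Observed amounts in ug, converting %ID records using the scenario dose.
.observed_amounts <- function(data, dose_ug) {
  ifelse(data$value_type == "percent_id", data$value / 100 * dose_ug,
         data$value)
}

#' Sum-of-squared log residual objective
#'
#' Simulates the scenario at candidate values of the four fitted parameters
#' and returns the sum of squared log10 residuals over the liver and spleen
#' mean observations. Zero observations are excluded (with a message);
#' simulation failure returns a large finite penalty with a warning.
#'
#' @param params Named vector or list with `Pup`, `KBile`, `sigma_IS`, `F`.
#' @param data An observation set (see [read_observations()]).
#' @param scenario A [pbpk_scenario()].
#' @param physiology A `species_physiology` (default from the scenario).
#' @param drug Template [drug_parameters()] supplying the non-fitted
#'   constants.
#' @param pores A [pore_system()].
#' @param organs Organs entering the loss (default liver and spleen).
#' @return Scalar loss (lower is better); deterministic given inputs.
#' @export
pbpk_objective <- function(params, data, scenario, physiology = NULL,
                           drug = drug_parameters(), pores = pore_system(),
                           organs = c("liver", "spleen")) {
  if (is.null(physiology))
    physiology <- load_species_physiology(scenario$species_id,
                                          scenario$body_weight)
  b <- default_fit_bounds()
  for (nm in names(b)) {
    v <- params[[nm]]
    if (is.null(v) || v < b[[nm]][1] || v > b[[nm]][2])
      stop("parameter ", nm, " missing or outside bounds [",
           b[[nm]][1], ", ", b[[nm]][2], "]")
  }
  drug$Pup <- params[["Pup"]]; drug$KBile <- params[["KBile"]]
  drug$sigma_IS <- params[["sigma_IS"]]; drug$F <- params[["F"]]

  d <- data[data$organ %in% organs, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for organs: ",
                         paste(organs, collapse = ", "))
  dose_ug <- scenario$dose * scenario$body_weight
  obs <- .observed_amounts(d, dose_ug)
  keep <- obs > 0
  if (sum(!keep) > 0)
    message("objective: excluded ", sum(!keep), " zero observation(s)")
  d <- d[keep, , drop = FALSE]; obs <- obs[keep]

  pred <- tryCatch(
    .predict_observations(d, scenario, physiology, drug, pores),
    error = function(e) {
      warning("simulation failed during objective evaluation: ",
              conditionMessage(e))
      NULL
    })
  if (is.null(pred) || any(!is.finite(pred)) || any(pred < 0))
    return(1e6)
  pred <- pmax(pred, 1e-12 * dose_ug)
  sum((log10(pred / obs))^2)
}

# Bounded <-> unbounded reparameterisation for the annealing search.
# Rate constants spanning decades (Pup, KBile) are searched on a log10
# scale (a zero lower bound is floored at 1e-5 of the upper bound for the
# search; an estimate at the floor reads as "indistinguishable from 0").
.LOG_SCALE_PARAMS <- c("Pup", "KBile")

.search_bounds <- function(bmat) {
  lg <- rownames(bmat) %in% .LOG_SCALE_PARAMS
  lo <- ifelse(lg, log10(pmax(bmat[, 1], 1e-5 * bmat[, 2])), bmat[, 1])
  hi <- ifelse(lg, log10(bmat[, 2]), bmat[, 2])
  cbind(lo, hi)
}

.to_z <- function(x, bmat) {
  lg <- rownames(bmat) %in% .LOG_SCALE_PARAMS
  sb <- .search_bounds(bmat)
  u <- ifelse(lg, log10(pmax(x, 10^sb[, 1])), x)
  stats::qlogis(pmin(pmax((u - sb[, 1]) / (sb[, 2] - sb[, 1]), 1e-8),
                     1 - 1e-8))
}

.from_z <- function(z, bmat) {
  lg <- rownames(bmat) %in% .LOG_SCALE_PARAMS
  sb <- .search_bounds(bmat)
  u <- sb[, 1] + (sb[, 2] - sb[, 1]) * stats::plogis(z)
  ifelse(lg, 10^u, u)
}

#' Fit the four drug-specific parameters
#'
#' Estimates Pup, KBile, sigma_IS and F from liver and spleen observations
#' by a temperature-based simulated annealing search (in a bounded logistic
#' transform space) followed by a Nelder-Mead polish, minimising
#' [pbpk_objective()].
#'
#' @inheritParams pbpk_objective
#' @param bounds Named list of `c(lower, upper)` bounds
#'   (default [default_fit_bounds()]).
#' @param seed Integer seed making the search reproducible.
#' @param start Optional named start values (default: random within bounds).
#' @param sann_iter Annealing evaluation budget (default 150).
#' @param polish_iter Nelder-Mead iteration budget (default 400).
#' @return An object of class `pbpk_fit` with `par`, `objective`, `counts`,
#'   `bounds`, `seed`, `converged` and the fitting inputs.
#' @export
fit_pbpk <- function(data, scenario = pbpk_scenario(), physiology = NULL,
                     drug = drug_parameters(), pores = pore_system(),
                     bounds = default_fit_bounds(), seed = 1,
                     start = NULL, sann_iter = 150, polish_iter = 400) {
  if (is.null(physiology))
    physiology <- load_species_physiology(scenario$species_id,
                                          scenario$body_weight)
  bdef <- default_fit_bounds()
  for (nm in names(bdef)) {
    bb <- bounds[[nm]]
    if (is.null(bb) || length(bb) != 2 || bb[1] >= bb[2] ||
        bb[1] < bdef[[nm]][1] - 1e-12 || bb[2] > bdef[[nm]][2] + 1e-12)
      stop("invalid bounds for ", nm)
  }
  bmat <- do.call(rbind, bounds[names(bdef)])
  nms <- names(bdef)
  n_eval <- 0L
  fn <- function(z) {
    n_eval <<- n_eval + 1L
    x <- stats::setNames(.from_z(z, bmat), nms)
    suppressMessages(
      pbpk_objective(as.list(x), data, scenario, physiology, drug, pores))
  }
  set.seed(seed)
  if (is.null(start)) {
    # coarse screen: a handful of dispersed starts, keep the best
    cand <- matrix(stats::rnorm(8 * length(nms), 0, 1.5), ncol = length(nms))
    vals <- apply(cand, 1, fn)
    z0 <- cand[which.min(vals), ]
  } else {
    z0 <- .to_z(unlist(start)[nms], bmat)
  }
  sann <- stats::optim(z0, fn, method = "SANN",
                       control = list(maxit = sann_iter, temp = 2,
                                      tmax = 5, parscale = rep(1, 4)))
  pol <- stats::optim(sann$par, fn, method = "Nelder-Mead",
                      control = list(maxit = polish_iter,
                                     reltol = 1e-10))
  # one restart of the simplex from the polished point guards against
  # premature simplex collapse in the 4-parameter space
  pol2 <- stats::optim(pol$par, fn, method = "Nelder-Mead",
                       control = list(maxit = polish_iter, reltol = 1e-10))
  pol <- if (pol2$value <= pol$value) pol2 else pol
  best <- if (pol$value <= sann$value) pol else sann
  par <- stats::setNames(.from_z(best$par, bmat), nms)
  structure(list(
    par = par, objective = best$value, counts = n_eval,
    bounds = bounds, seed = seed,
    converged = isTRUE(pol$convergence == 0) || pol$value < sann$value,
    data = data, scenario = scenario, physiology = physiology,
    drug = drug, pores = pores
  ), class = "pbpk_fit")
}

#' Local identifiability diagnostics
#'
#' Finite-difference sensitivities of the log-predicted liver and spleen
#' amounts at the observation times with respect to each fitted parameter,
#' their pairwise correlations, and flags for practical non-identifiability
#' (near-zero sensitivity, or |correlation| > 0.95 between two parameters'
#' sensitivity vectors).
#'
#' @inheritParams pbpk_objective
#' @param rel_step Relative finite-difference step (default 0.01).
#' @return List with `sensitivity` (matrix, observations x parameters),
#'   `correlation` (parameter correlation matrix), `flags` (character).
#' @export
identifiability_check <- function(params, data, scenario = pbpk_scenario(),
                                  physiology = NULL,
                                  drug = drug_parameters(),
                                  pores = pore_system(), rel_step = 0.01) {
  if (is.null(physiology))
    physiology <- load_species_physiology(scenario$species_id,
                                          scenario$body_weight)
  d <- data[data$organ %in% c("liver", "spleen") & data$value > 0, ,
            drop = FALSE]
  base_drug <- drug
  for (nm in names(params)) base_drug[[nm]] <- params[[nm]]
  predfun <- function(dd) log10(pmax(
    .predict_observations(d, scenario, physiology, dd, pores), 1e-12))
  base <- predfun(base_drug)
  nms <- names(params)
  S <- sapply(nms, function(nm) {
    h <- rel_step * max(abs(params[[nm]]), 1e-6)
    up <- base_drug; up[[nm]] <- params[[nm]] + h
    dn <- base_drug; dn[[nm]] <- max(params[[nm]] - h, 0)
    (predfun(up) - predfun(dn)) / (up[[nm]] - dn[[nm]]) * params[[nm]]
  })
  flags <- character(0)
  norms <- sqrt(colSums(S^2))
  for (nm in nms[norms < 1e-6])
    flags <- c(flags, paste0(nm, ": near-zero sensitivity"))
  C <- suppressWarnings(stats::cor(S))
  C[!is.finite(C)] <- 0; diag(C) <- 1
  for (i in seq_along(nms)) for (j in seq_len(i - 1))
    if (abs(C[i, j]) > 0.95)
      flags <- c(flags, paste0(nms[i], " ~ ", nms[j],
                               ": |correlation| > 0.95"))
  list(sensitivity = S, correlation = C, flags = flags,
       identifiable = length(flags) == 0)
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("<pbpk_fit> estimates (", x$counts, " objective evaluations, seed ",
      x$seed, ")\n", sep = "")
  print(round(x$par, 5))
  cat(sprintf("objective (sum sq log10 residuals): %.6g; converged: %s\n",
              x$objective, x$converged))
  invisible(x)
}

#' @export
coef.pbpk_fit <- function(object, ...) object$par

#' @export
predict.pbpk_fit <- function(object, scenario = object$scenario, ...) {
  drug <- object$drug
  for (nm in names(object$par)) drug[[nm]] <- object$par[[nm]]
  simulate_pbpk(scenario, object$physiology, drug, object$pores, ...)
}

#' @export
residuals.pbpk_fit <- function(object, ...) {
  drug <- object$drug
  for (nm in names(object$par)) drug[[nm]] <- object$par[[nm]]
  d <- object$data[object$data$organ %in% c("liver", "spleen") &
                     object$data$value > 0, , drop = FALSE]
  dose_ug <- object$scenario$dose * object$scenario$body_weight
  pred <- .predict_observations(d, object$scenario, object$physiology,
                                drug, object$pores)
  obs <- .observed_amounts(d, dose_ug)
  stats::setNames(log10(pmax(pred, 1e-12) / obs),
                  paste0(d$organ, "@d", d$time_days))
}

#' @export
summary.pbpk_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(par = object$par, objective = object$objective,
                 aafe = 10^mean(abs(r)), n = length(r),
                 converged = object$converged, seed = object$seed),
            class = "summary.pbpk_fit")
}

#' @export
print.summary.pbpk_fit <- function(x, ...) {
  print(round(x$par, 5))
  cat(sprintf("objective %.5g | AAFE (liver+spleen) %.3f over %d points | %s\n",
              x$objective, x$aafe, x$n,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
plot.pbpk_fit <- function(x, ...) {
  drug <- x$drug
  for (nm in names(x$par)) drug[[nm]] <- x$par[[nm]]
  d <- x$data[x$data$organ %in% c("liver", "spleen") & x$data$value > 0, ]
  dose_ug <- x$scenario$dose * x$scenario$body_weight
  pred <- .predict_observations(d, x$scenario, x$physiology, drug, x$pores)
  obs <- .observed_amounts(d, dose_ug)
  rng <- range(c(pred, obs))
  graphics::plot(obs, pred, log = "xy", xlim = rng, ylim = rng,
                 col = ifelse(d$organ == "liver", 1, 2), pch = 19,
                 xlab = "observed (ug)", ylab = "predicted (ug)", ...)
  graphics::abline(0, 1)
  graphics::legend("topleft", c("liver", "spleen"), col = 1:2, pch = 19,
                   bty = "n")
  invisible(x)
}
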