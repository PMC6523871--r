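#' @useDynLib goldpbpk, .registration = TRUE
NULL

# Canonical organ order used throughout the package (lungs first: they sit in
# series with total cardiac plasma flow; liver receives the portal organs'
# venous outflow).
.ORGANS <- c("lungs", "heart", "kidneys", "muscle", "skin", "brain",
             "adipose", "gonads", "bone", "liver", "stomach", "spleen",
             "pancreas", "small_intestine", "large_intestine")

.PORTAL_ORGANS <- c("stomach", "spleen", "pancreas", "small_intestine",
                    "large_intestine")

# Reference anatomy for a 28 g mouse: total organ volumes (mL), plasma flows
# (mL/h) and sub-compartment fractions. Values assembled from the open
# literature on rodent physiology used by whole-body large-molecule PBPK
# platforms (organ weights/flows of a 28 g mouse; vascular and interstitial
# space fractions per organ). The lung plasma flow equals total cardiac
# plasma output (series arrangement) and is set programmatically.
# Lymph flow is 0.2% of organ plasma flow (liver: of total hepatic inflow,
# hepatic artery + portal vein).
.mouse_reference_table <- function() {
  tab <- data.frame(
    organ = .ORGANS,
    total_volume = c(0.204, 0.152, 0.525, 11.30, 5.02, 0.485, 1.98, 0.10,
                     2.82, 1.93, 0.11, 0.127, 0.097, 0.728, 0.314),
    plasma_flow  = c(NA,    36.5,  68.5,  86.1,  27.8, 11.8,  13.4, 2.5,
                     15.2,  10.3,  11.4,  8.18,  6.24, 58.1,  17.3),
    vascular_fraction     = c(0.260, 0.260, 0.110, 0.026, 0.019, 0.021,
                              0.010, 0.070, 0.041, 0.085, 0.032, 0.120,
                              0.060, 0.024, 0.024),
    interstitial_fraction = c(0.280, 0.100, 0.200, 0.120, 0.300, 0.170,
                              0.140, 0.200, 0.100, 0.200, 0.100, 0.200,
                              0.170, 0.190, 0.190),
    stringsAsFactors = FALSE
  )
  tab$cellular_fraction <- 1 - tab$vascular_fraction - tab$interstitial_fraction
  cardiac <- sum(tab$plasma_flow[tab$organ != "lungs"], na.rm = TRUE)
  tab$plasma_flow[tab$organ == "lungs"] <- cardiac
  portal_in <- sum(tab$plasma_flow[tab$organ %in% .PORTAL_ORGANS])
  tab$lymph_flow <- 0.002 * tab$plasma_flow
  tab$lymph_flow[tab$organ == "liver"] <-
    0.002 * (tab$plasma_flow[tab$organ == "liver"] + portal_in)
  tab$is_portal <- tab$organ %in% .PORTAL_ORGANS
  tab
}

# Macrophage content as a fraction of organ cellular volume. Liver (Kupffer
# plus stellate macrophages) 10% and spleen (white pulp) 30% are anchor
# values; the remaining organs are classed prominent (4%) or low (2%)
# according to macrophage-specific RNA-expression evidence.
.MACROPHAGE_TABLE <- c(
  lungs = 0.04, heart = 0.02, kidneys = 0.04, muscle = 0.02, skin = 0.02,
  brain = 0.02, adipose = 0.02, gonads = 0.02, bone = 0.04, liver = 0.10,
  stomach = 0.02, spleen = 0.30, pancreas = 0.02,
  small_intestine = 0.04, large_intestine = 0.04
)

#' Macrophage volume fraction of an organ's cellular volume
#'
#' Liver macrophages (Kupffer and stellate cells) occupy 10% of liver
#' cellular volume and splenic white-pulp macrophages 30% of spleen cellular
#' volume; all other organs are classed as having prominent (4%) or low (2%)
#' macrophage content.
#'
#' @param organ_id Organ name, one of the fifteen modelled organs.
#' @return Dimensionless fraction of the organ's cellular volume.
#' @examples
#' assign_macrophage_fraction("liver")   # 0.10
#' assign_macrophage_fraction("spleen")  # 0.30
#' @export
assign_macrophage_fraction <- function(organ_id) {
  if (length(organ_id) != 1L || !organ_id %in% .ORGANS)
    stop("unknown organ: ", paste(organ_id, collapse = ", "),
         " (expected one of: ", paste(.ORGANS, collapse = ", "), ")")
  unname(.MACROPHAGE_TABLE[organ_id])
}

#' Endothelium geometry constants
#'
#' @param ke Proportionality constant between organ vascular volume and
#'   capillary surface area (cm^2/mL, default 950).
#' @param de Endothelial cell layer thickness (cm, default 3e-5).
#' @return An object of class `endothelium_constants`.
#' @export
endothelium_constants <- function(ke = 950, de = 3e-5) {
  if (!is.numeric(ke) || ke <= 0 || !is.numeric(de) || de <= 0)
    stop("endothelium constants ke and de must be strictly positive")
  structure(list(ke = ke, de = de), class = "endothelium_constants")
}

#' Endothelial volume fraction of an organ
#'
#' The endothelial fraction is derived from the vascular surface area:
#' FiE = ke * FiV * de, where FiV is the organ's vascular fraction.
#'
#' @param FiV Vascular volume fraction of the organ, in [0, 1].
#' @param constants An [endothelium_constants()] object.
#' @return Dimensionless endothelial volume fraction.
#' @export
endothelial_fraction <- function(FiV, constants = endothelium_constants()) {
  if (!is.numeric(FiV) || any(FiV < 0) || any(FiV > 1))
    stop("vascular fraction FiV must lie in [0, 1]")
  constants$ke * FiV * constants$de
}

#' Load the packaged physiology for a species
#'
#' Returns the packaged anatomical/physiological parameter set (organ
#' volumes, plasma and lymph flows, sub-compartment fractions) for a mouse
#' or rat, linearly scaled to the requested body weight. Reference weights
#' are 28 g (mouse) and 280 g (rat); volumes and flows scale proportionally
#' with body weight.
#'
#' @param species_id `"mouse"` or `"rat"`.
#' @param body_weight Body weight in grams (defaults: 28 for mouse, 280 for
#'   rat).
#' @param endothelium [endothelium_constants()]; species-independent.
#' @return An object of class `species_physiology`: organ table plus
#'   whole-body scalars (venous/arterial plasma volumes, lymph node volume,
#'   blood phagocyte fraction, hepatocyte fraction of liver cellular volume).
#' @examples
#' phys <- load_species_physiology("mouse", 28)
#' nrow(phys$organs)  # 15
#' @export
load_species_physiology <- function(species_id,
                                    body_weight = c(mouse = 28, rat = 280)[[species_id]],
                                    endothelium = endothelium_constants()) {
  if (length(species_id) != 1L || !species_id %in% c("mouse", "rat"))
    stop("unsupported species: ", paste(species_id, collapse = ", "),
         " (supported: mouse, rat)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop("body_weight must be a single positive number (g)")

  ref <- .mouse_reference_table()
  ref_bw <- 28
  # The packaged rat reference is the canonical per-gram table at 280 g;
  # the same linear scaling rule therefore serves both species.
  scale <- body_weight / ref_bw
  organs <- ref
  organs$total_volume <- ref$total_volume * scale
  organs$plasma_flow <- ref$plasma_flow * scale
  organs$lymph_flow <- ref$lymph_flow * scale
  organs$macrophage_fraction <-
    unname(.MACROPHAGE_TABLE[match(organs$organ, names(.MACROPHAGE_TABLE))])

  phys <- structure(list(
    species_id = species_id,
    body_weight = body_weight,
    organs = organs,
    cardiac_plasma_flow = sum(organs$plasma_flow[organs$organ != "lungs"]),
    lymph_node_volume = 0.113 * scale,
    venous_plasma_volume = 0.35 * scale,
    arterial_plasma_volume = 0.175 * scale,
    blood_volume = 0.0585 * body_weight,
    blood_phagocyte_fraction = 0.01,
    hepatocyte_fraction_of_liver_cellular = 0.75,
    endothelium_constants = endothelium
  ), class = "species_physiology")
  validate_species_physiology(phys)
  phys
}

#' Validate a species physiology object
#'
#' Checks every organ-level invariant (positive volumes and flows, fractions
#' summing to at most one, lymph flow below plasma flow, exactly five portal
#' organs) and the whole-body flow balance (organ plasma flows summing to the
#' declared cardiac plasma output). The first violated invariant is reported.
#'
#' @param phys A `species_physiology` object.
#' @return `phys`, invisibly, if valid; otherwise an error.
#' @export
validate_species_physiology <- function(phys) {
  org <- phys$organs
  for (i in seq_len(nrow(org))) {
    o <- org[i, ]
    if (!(o$total_volume > 0))
      stop("organ ", o$organ, ": total_volume must be strictly positive")
    if (!(o$plasma_flow > 0))
      stop("organ ", o$organ, ": plasma_flow must be strictly positive")
    if (!(o$lymph_flow > 0))
      stop("organ ", o$organ, ": lymph_flow must be strictly positive")
    if (o$lymph_flow >= o$plasma_flow)
      stop("organ ", o$organ, ": lymph_flow must be below plasma_flow")
    fr <- o$vascular_fraction + o$interstitial_fraction + o$cellular_fraction
    if (fr > 1 + 1e-9)
      stop("organ ", o$organ, ": sub-compartment fractions exceed 1")
    if (any(c(o$vascular_fraction, o$interstitial_fraction,
              o$cellular_fraction) < 0))
      stop("organ ", o$organ, ": negative sub-compartment fraction")
  }
  if (sum(org$is_portal) != 5L)
    stop("exactly five organs must be flagged portal")
  co <- sum(org$plasma_flow[org$organ != "lungs"])
  if (abs(co - phys$cardiac_plasma_flow) > 1e-6 * phys$cardiac_plasma_flow)
    stop("organ plasma flows do not sum to the declared cardiac plasma output")
  if (abs(sum(org$lymph_flow) - total_lymph_flow(phys)) > 1e-9)
    stop("total lymph flow must equal the sum of organ lymph flows")
  invisible(phys)
}

#' Total lymph flow of a species
#' @param phys A `species_physiology` object.
#' @return Total lymph flow (mL/h), the sum of all organ lymph flows.
#' @export
total_lymph_flow <- function(phys) sum(phys$organs$lymph_flow)

#' Sub-compartment volumes of one organ
#'
#' Splits an organ's total volume into plasma, vascular endothelium,
#' interstitial space and macrophages; for the liver additionally the
#' hepatocyte volume (75% of cellular volume).
#'
#' @param organ One-row slice of the `organs` table of a
#'   `species_physiology`, or an organ name to look up in `species`.
#' @param species A `species_physiology` object.
#' @return Named list of volumes (mL): `plasma`, `endothelium`,
#'   `interstitial`, `macrophage`, `cellular`, and `hepatocyte` (liver only,
#'   otherwise 0).
#' @export
subcompartment_volumes <- function(organ, species) {
  if (is.character(organ)) {
    idx <- match(organ, species$organs$organ)
    if (is.na(idx)) stop("unknown organ: ", organ)
    organ <- species$organs[idx, ]
  }
  FiE <- endothelial_fraction(organ$vascular_fraction,
                              species$endothelium_constants)
  V <- organ$total_volume
  cellular <- organ$cellular_fraction * V
  hep <- if (organ$organ == "liver")
    species$hepatocyte_fraction_of_liver_cellular * cellular else 0
  list(
    plasma = organ$vascular_fraction * V,
    endothelium = FiE * V,
    interstitial = organ$interstitial_fraction * V,
    macrophage = organ$macrophage_fraction * cellular,
    cellular = cellular,
    hepatocyte = hep
  )
}

#' Read a physiology override file
#'
#' Reads a YAML physiology file (one record per organ with fields
#' `organ`, `total_volume` (mL), `plasma_flow` (mL/h), `lymph_flow` (mL/h),
#' `vascular_fraction`, `interstitial_fraction`, `cellular_fraction`,
#' optionally `macrophage_fraction`) plus optional whole-body scalars, and
#' merges it over the packaged defaults. The merged physiology is validated
#' and the first violated invariant reported.
#'
#' @param path Path to a YAML file.
#' @param base A `species_physiology` to override (default: the file's
#'   declared species at its reference weight).
#' @return A validated `species_physiology` object.
#' @export
read_physiology_file <- function(path, base = NULL) {
  spec <- yaml::read_yaml(path)
  if (is.null(base)) {
    species <- spec$species %||% "mouse"
    bw <- spec$body_weight %||% c(mouse = 28, rat = 280)[[species]]
    base <- load_species_physiology(species, bw)
  }
  if (!is.null(spec$organs)) {
    for (rec in spec$organs) {
      idx <- match(rec$organ, base$organs$organ)
      if (is.na(idx)) stop("physiology file names unknown organ: ", rec$organ)
      for (f in setdiff(names(rec), "organ")) {
        if (!f %in% names(base$organs))
          stop("physiology file has unknown field '", f, "' for organ ",
               rec$organ)
        base$organs[[f]][idx] <- rec[[f]]
      }
    }
  }
  for (f in intersect(names(spec),
                      c("lymph_node_volume", "venous_plasma_volume",
                        "arterial_plasma_volume", "blood_phagocyte_fraction",
                        "hepatocyte_fraction_of_liver_cellular")))
    base[[f]] <- spec[[f]]
  base$cardiac_plasma_flow <-
    sum(base$organs$plasma_flow[base$organs$organ != "lungs"])
  validate_species_physiology(base)
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s, %.4g g\n", x$species_id, x$body_weight))
  cat(sprintf("  cardiac plasma output: %.4g mL/h; total lymph flow: %.4g mL/h\n",
              x$cardiac_plasma_flow, total_lymph_flow(x)))
  print(x$organs[, c("organ", "total_volume", "plasma_flow", "lymph_flow",
                     "vascular_fraction", "interstitial_fraction",
                     "cellular_fraction", "macrophage_fraction")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
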