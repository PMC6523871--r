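Package: goldpbpk
Title: Whole-Body PBPK Modelling of Gold Nanoparticle Biodistribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physiologically-based pharmacokinetic (PBPK) model for the
    biodistribution of gold nanoparticles in mice and rats. Fifteen organs
    are represented as plasma / vascular-endothelium / interstitial /
    macrophage sub-compartments connected by plasma and lymph flows.
    Extravasation follows the two-pore formalism (convection plus diffusion
    through small and large capillary pores), phagocytic uptake by the
    mononuclear phagocyte system is saturable (Michaelis-Menten), hepatocytes
    take up particles by pinocytosis and excrete them into bile, and
    intraperitoneal dosing is modelled as a first-order depot releasing into
    the portal-organ interstitia and lymph. Includes simulated-annealing
    parameter estimation against organ biodistribution data, local
    sensitivity analysis of liver and spleen exposure, absolute average fold
    error (AAFE) model evaluation, mouse-to-rat extrapolation, and a
    synthetic-data generator emulating the sacrifice-group study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
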