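test_that("packaged species tables satisfy every organ invariant", {
  for (sp in c("mouse", "rat")) {
    phys <- load_species_physiology(sp)
    expect_silent(validate_species_physiology(phys))
    org <- phys$organs
    expect_equal(nrow(org), 15L)
    expect_true(all(org$total_volume > 0))
    expect_true(all(org$lymph_flow < org$plasma_flow))
    expect_true(all(org$vascular_fraction + org$interstitial_fraction +
                      org$cellular_fraction <= 1 + 1e-12))
    expect_identical(sum(org$is_portal), 5L)
    expect_setequal(org$organ[org$is_portal],
                    c("stomach", "spleen", "pancreas", "small_intestine",
                      "large_intestine"))
    co <- sum(org$plasma_flow[org$organ != "lungs"])
    expect_equal(co, phys$cardiac_plasma_flow, tolerance = 1e-9)
    expect_equal(total_lymph_flow(phys), sum(org$lymph_flow))
  }
})

test_that("macrophage fractions follow the prominence table", {
  expect_equal(assign_macrophage_fraction("liver"), 0.10)
  expect_equal(assign_macrophage_fraction("spleen"), 0.30)
  expect_equal(assign_macrophage_fraction("lungs"), 0.04)
  others <- setdiff(c("heart", "kidneys", "muscle", "skin", "brain",
                      "adipose", "gonads", "bone", "stomach", "pancreas",
                      "small_intestine", "large_intestine"), NULL)
  for (o in others)
    expect_true(assign_macrophage_fraction(o) %in% c(0.02, 0.04))
  expect_error(assign_macrophage_fraction("tumour"), "unknown organ")
  phys <- load_species_physiology("mouse")
  expect_equal(phys$organs$macrophage_fraction[phys$organs$organ == "liver"],
               0.10)
})

test_that("endothelial fraction is ke * FiV * de and linear in FiV", {
  expect_equal(endothelial_fraction(0), 0)
  expect_equal(endothelial_fraction(1), 0.0285)
  expect_equal(endothelial_fraction(0.1), 2.85e-3)
  # linearity in FiV; degree-1 homogeneity in each constant
  f <- endothelial_fraction(0.37)
  expect_equal(endothelial_fraction(2 * 0.37 / 2), f)
  expect_equal(endothelial_fraction(0.37, endothelium_constants(ke = 1900)),
               2 * f)
  expect_equal(endothelial_fraction(0.37, endothelium_constants(de = 6e-5)),
               2 * f)
  expect_error(endothelial_fraction(1.2), "\\[0, 1\\]")
  expect_error(endothelial_fraction(-0.1), "\\[0, 1\\]")
})

test_that("sub-compartment volumes follow the stated fractions", {
  phys <- mouse_phys
  liv <- subcompartment_volumes("liver", phys)
  liver_row <- phys$organs[phys$organs$organ == "liver", ]
  cellular <- liver_row$cellular_fraction * liver_row$total_volume
  expect_equal(liv$macrophage, 0.10 * cellular)
  expect_equal(liv$hepatocyte, 0.75 * cellular)
  spl <- subcompartment_volumes("spleen", phys)
  spl_row <- phys$organs[phys$organs$organ == "spleen", ]
  expect_equal(spl$macrophage,
               0.30 * spl_row$cellular_fraction * spl_row$total_volume)
  expect_equal(spl$hepatocyte, 0)
  # a synthetic liver with cellular volume exactly 1 mL
  fake <- liver_row
  fake$total_volume <- 1 / fake$cellular_fraction
  v <- subcompartment_volumes(fake, phys)
  expect_equal(v$macrophage, 0.10)
  expect_equal(v$hepatocyte, 0.75)
  # degenerate zero-volume organ
  fake$total_volume <- 0
  v0 <- subcompartment_volumes(fake, phys)
  expect_true(all(unlist(v0) == 0))
  # sub-volumes never exceed the total
  for (o in phys$organs$organ) {
    v <- subcompartment_volumes(o, phys)
    expect_lte(v$plasma + v$endothelium + v$interstitial + v$macrophage,
               phys$organs$total_volume[phys$organs$organ == o] + 1e-12)
  }
})

test_that("physiology scales linearly with body weight", {
  m <- load_species_physiology("mouse", 28)
  r <- load_species_physiology("rat", 280)
  expect_equal(r$organs$total_volume, 10 * m$organs$total_volume)
  expect_equal(r$organs$plasma_flow, 10 * m$organs$plasma_flow)
  expect_equal(r$organs$lymph_flow, 10 * m$organs$lymph_flow)
  expect_equal(r$lymph_node_volume, 10 * m$lymph_node_volume)
  m2 <- load_species_physiology("mouse", 56)
  expect_equal(m2$organs$total_volume, 2 * m$organs$total_volume)
  sv1 <- subcompartment_volumes("liver", m)
  sv2 <- subcompartment_volumes("liver", m2)
  expect_equal(unlist(sv2), 2 * unlist(sv1))
})

test_that("species and weight validation errors are explicit", {
  expect_error(load_species_physiology("dog", 10000), "unsupported species")
  expect_error(load_species_physiology("mouse", -1), "positive")
  expect_error(load_species_physiology("mouse", 0), "positive")
})

test_that("physiology override files are merged, validated and rejected", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("species: mouse", "body_weight: 28", "organs:",
               "  - organ: liver", "    total_volume: 2.5"), f)
  phys <- read_physiology_file(f)
  expect_equal(phys$organs$total_volume[phys$organs$organ == "liver"], 2.5)
  # invalid override: lymph flow above plasma flow, first violation named
  writeLines(c("organs:", "  - organ: heart", "    lymph_flow: 100"), f)
  expect_error(read_physiology_file(f), "heart.*lymph_flow")
  writeLines(c("organs:", "  - organ: heart", "    bogus_field: 1"), f)
  expect_error(read_physiology_file(f), "bogus_field")
  writeLines(c("organs:", "  - organ: gallbladder", "    total_volume: 1"), f)
  expect_error(read_physiology_file(f), "gallbladder")
  unlink(f)
})
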