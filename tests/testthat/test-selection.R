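test_that("available biomass multiplies density by female mass and filters", {
  av <- nepl_avail()
  expect_setequal(av$entries$taxon,
                  c("muntjac", "wild_pig", "sambar", "serow"))
  expect_equal(av$excluded$taxon, "gaur")
  expect_equal(av$excluded$reason, "no mass")
  expect_equal(av$entries$biomass_kg_per_km2,
               av$entries$density * av$entries$female_mass_kg)
  expect_equal(sum(av$entries$p), 1)
  # serow clears the 5% rule with little room to spare
  p_serow <- av$entries$p[av$entries$taxon == "serow"]
  expect_equal(p_serow, 0.0527429135524, tolerance = 1e-10)
  expect_gt(p_serow, 0.05)
})

test_that("rare taxa are excluded and proportions renormalized", {
  d <- data.frame(taxon = c("a", "b", "c"),
                  density = c(1, 1, 0.01),
                  female_mass_kg = c(100, 100, 10))
  av <- available_biomass(d)
  expect_setequal(av$entries$taxon, c("a", "b"))
  expect_equal(av$excluded$reason, "below availability threshold")
  expect_equal(av$entries$p, c(0.5, 0.5))

  one <- available_biomass(data.frame(taxon = "a", density = 2,
                                      female_mass_kg = 50))
  expect_equal(one$entries$p, 1)

  expect_error(available_biomass(data.frame(taxon = "a", density = 1,
                                            female_mass_kg = NA)),
               "all taxa excluded")
})

test_that("electivity has its endpoint and neutrality identities", {
  expect_equal(jacobs_D(0, 0.3), -1)
  expect_equal(jacobs_D(0, 0.999), -1)
  expect_equal(jacobs_D(0.3, 0.3), 0)
  expect_equal(jacobs_D(1, 0.5), 1)
  expect_error(jacobs_D(0.5, 0), "within \\(0, 1\\)")
  expect_error(jacobs_D(0.5, 1), "within \\(0, 1\\)")
  expect_error(jacobs_D(-0.1, 0.5), "within \\[0, 1\\]")
})

test_that("electivity is antisymmetric and monotone in use", {
  rs <- seq(0.05, 0.95, by = 0.09)
  for (p in c(0.1, 0.4, 0.8)) {
    D <- jacobs_D(rs, p)
    expect_true(all(diff(D) > 0))                    # monotone in r
    expect_equal(jacobs_D(rs, p), -jacobs_D(p, rs))  # antisymmetry
    expect_true(all(D >= -1 & D <= 1))
  }
})

test_that("preference classes use strict 0.30 thresholds", {
  expect_equal(classify_preference(c(0.61, 0.30, -0.30, -1, 0.31, -0.31)),
               c("preferred", "neutral", "neutral", "avoided",
                 "preferred", "avoided"))
  expect_error(classify_preference(1.2), "within")
})

test_that("selection on the example data matches the published electivities", {
  av <- nepl_avail()
  cl <- selection_analysis(
    diet_composition(nepl_fixture("clouded_leopard"),
                     nepl_cf("clouded_leopard")), av)
  rownames(cl) <- cl$taxon
  # taxa absent from the diet are completely avoided
  expect_equal(cl["muntjac", "D"], -1)
  expect_equal(cl["sambar", "D"], -1)
  expect_equal(cl["muntjac", "preference_class"], "avoided")

  tg <- selection_analysis(
    diet_composition(nepl_fixture("tiger"), nepl_cf("tiger")), av)
  rownames(tg) <- tg$taxon
  expect_equal(tg["wild_pig", "D"], -0.28, tolerance = 0.01 / 0.28)
  # the renormalized use vector is a proper composition
  expect_equal(sum(tg$r), 1)

  # serow is preferred by both predators under both conventions
  for (pred in c("tiger", "clouded_leopard")) {
    comp <- diet_composition(nepl_fixture(pred), nepl_cf(pred))
    for (conv in c("renormalized", "raw")) {
      sel <- selection_analysis(comp, av, use_convention = conv)
      srw <- sel[sel$taxon == "serow", ]
      expect_gt(srw$D, 0.30)
      expect_equal(srw$preference_class, "preferred")
    }
  }
})

test_that("a diet proportional to availability is pure neutrality", {
  av <- nepl_avail()
  diet <- stats::setNames(100 * av$entries$p, av$entries$taxon)
  sel <- selection_analysis(diet, av)
  expect_equal(sel$D, rep(0, 4))
  expect_equal(unique(sel$preference_class), "neutral")
})

test_that("disjoint diet and availability is an error", {
  av <- nepl_avail()
  expect_error(selection_analysis(c(pangolin = 100), av), "share no taxon")
})
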