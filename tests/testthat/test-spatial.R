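test_that("the model-selection tree picks homogeneous/mosaic/interactive", {
  expect_equal(select_spatial_model(FALSE, FALSE, FALSE), "homogeneous")
  expect_equal(select_spatial_model(FALSE, TRUE, FALSE), "mosaic")
  expect_equal(select_spatial_model(FALSE, FALSE, TRUE), "mosaic")
  # lateral fluxes dominate the decision, as for the NHLD runoff network
  expect_equal(select_spatial_model(TRUE, TRUE, TRUE), "interactive")
  expect_equal(select_spatial_model(TRUE, FALSE, FALSE), "interactive")
})

test_that("homogeneous fluxes are intensity times area, g converted to Gg", {
  ints <- nhld_intensities()
  # C precipitation onto forests: 1.8 g m-2 yr-1 over the derived forest area
  expect_equal(round(homogeneous_flux(1.8, ints$areas[["forest"]]), 1), 6.2)
  expect_equal(homogeneous_flux(5, 0), 0)
  # round-trip of the back-derived area through the GPP intensity
  expect_equal(homogeneous_flux(936, ints$areas[["forest"]]), 3233,
               tolerance = 1e-8)
  expect_equal(homogeneous_flux(490, ints$areas[["wetland"]]), 878,
               tolerance = 1e-8)
})

test_that("mosaic vertical budgets balance the atmosphere exactly", {
  ints <- nhld_intensities()
  b <- mosaic_vertical_budget(ints)
  # forest: precipitation + GPP - respiration, independent arithmetic
  expect_equal(b$F_f_v,
               (1.8 + 936 - 648) * ints$areas[["forest"]] / 1e9)
  # matches the total-flux arithmetic 6.2 + 3233 - 2238 = 1001.2 to rounding
  expect_equal(b$F_f_v, 1001.2, tolerance = 3e-4)
  expect_equal(b$F_w_v,
               (1.8 + 490 - 421 - 10) * ints$areas[["wetland"]] / 1e9)
  expect_equal(b$F_a_v + b$F_f_v + b$F_w_v + b$F_s_v, 0)
  # all-zero intensities give an all-zero budget
  zero <- intensity_set(
    areal = data.frame(
      compartment = c("all", "forest", "forest", "wetland", "wetland",
                      "wetland", "surface_waters", "surface_waters"),
      process = c("precipitation", "GPP", "respiration", "GPP", "respiration",
                  "CH4", "CO2_evasion", "CH4"),
      value = 0),
    areas = c(forest = 1e9, wetland = 1e9, surface_waters = 1e9))
  z <- mosaic_vertical_budget(zero)
  expect_equal(unlist(z[-1], use.names = FALSE), rep(0, 4))
  # a missing intensity is named in the error
  broken <- zero
  broken$areal <- broken$areal[broken$areal$process != "CH4", ]
  expect_error(mosaic_vertical_budget(broken), "rho_\\{wetland,CH4\\}")
})

test_that("lineal litter fluxes reproduce the shoreline totals", {
  ints <- nhld_intensities()
  # 300 g C m-1 yr-1 across 7805 km and 200 g C m-1 yr-1 across 3469 km
  expect_equal(round(300 * 7805 * 1000 / 1e9, 1), 2.3)
  expect_equal(round(200 * 3469 * 1000 / 1e9, 1), 0.7)
  b <- interactive_lateral_budget(ints, downstream_export = 34)
  expect_equal(round(300 * ints$lengths[["forest"]] * 1000 / 1e9, 1), 2.3)
  expect_equal(round(200 * ints$lengths[["wetland"]] * 1000 / 1e9, 1), 0.7)
  # donors negative, lateral conservation exact
  expect_lt(b$F_f_l, 0)
  expect_lt(b$F_w_l, 0)
  expect_equal(b$F_f_l + b$F_w_l + b$F_s_l + b$F_d_l, 0)
  # zero interface length kills the lineal term only
  no_len <- ints
  no_len$lengths[] <- 0
  b0 <- interactive_lateral_budget(no_len, 34)
  expect_equal(b0$F_f_l, -(3.0 + 4.0) * ints$areas[["forest"]] / 1e9)
  # missing length is a configuration error
  miss <- ints
  miss$lengths <- miss$lengths["forest"]
  expect_error(interactive_lateral_budget(miss, 34), "L_\\{wetland\\}")
})

test_that("budgets are linear in each intensity and each area", {
  ints <- nhld_intensities()
  b1 <- interactive_lateral_budget(ints, 0)
  doubled <- ints
  doubled$areal$value <- doubled$areal$value * 2
  doubled$lineal$value <- doubled$lineal$value * 2
  b2 <- interactive_lateral_budget(doubled, 0)
  expect_equal(b2$F_f_l, 2 * b1$F_f_l)
  expect_equal(b2$F_s_l, 2 * b1$F_s_l)
  half_area <- ints
  half_area$areas <- half_area$areas / 2
  bv1 <- mosaic_vertical_budget(ints)
  bv2 <- mosaic_vertical_budget(half_area)
  expect_equal(bv2$F_f_v, bv1$F_f_v / 2)
})
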