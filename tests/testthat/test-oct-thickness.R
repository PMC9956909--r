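test_that("thickness maps follow the layer definitions and add up exactly", {
  sim <- simulate_oct_volume(small_phantom(noise_sd = 5, seed = 51))
  auto <- segment_volume(sim$volume)
  trt <- thickness_map(auto, "TRT")
  ir <- thickness_map(auto, "IR")
  or <- thickness_map(auto, "OR")
  onl <- thickness_map(auto, "ONL")
  ok <- trt$valid & ir$valid & or$valid
  expect_identical(trt$values[ok], (ir$values + or$values)[ok])
  expect_true(all(trt$values[ok] >= 0))
  expect_true(all(onl$values[onl$valid] >= 0))
  expect_error(thickness_map(auto, "XYZ"), "layer")
})

test_that("a constant phantom yields a constant TRT map at the preset total", {
  spec <- phantom_preset("wt", n_bscans = 9, n_ascans = 32, axial_px = 1,
                         lateral_px = 220, bscan_spacing = 750, noise_sd = 0,
                         seed = 52)
  sim <- simulate_oct_volume(spec)
  tm <- thickness_map(sim$truth, "TRT")
  expect_true(all(tm$values[tm$valid] == 230))
  onl <- thickness_map(simulate_oct_volume(small_phantom("crx", seed = 53))$truth,
                       "ONL")
  expect_true(all(onl$values[onl$valid] == 0))
})

test_that("sector means equal an independent brute-force pixel loop", {
  sim <- simulate_oct_volume(small_phantom(noise_sd = 5, seed = 54))
  map <- thickness_map(segment_volume(sim$volume), "TRT")
  grid <- sector_grid()
  for (side in c("left", "right")) {
    got <- sector_summary(map, grid, laterality = side)
    want <- brute_force_sectors(map, grid, side)
    for (q in got$quadrant) {
      expect_equal(got$inner_mean[got$quadrant == q], want[[paste(q, "inner")]],
                   tolerance = 1e-9)
      expect_equal(got$outer_mean[got$quadrant == q], want[[paste(q, "outer")]],
                   tolerance = 1e-9)
    }
    expect_equal(got$combined, (got$inner_mean + got$outer_mean) / 2)
  }
})

test_that("a split-half map summarizes to its half values per quadrant", {
  # superior half 250 um, inferior half 210 um via a thickness function
  spec <- retina_phantom_spec(
    layer_thickness = list(
      inner = function(x, y) ifelse(y > 0, 105, 65), opl = 20, onl = 60,
      outer = 65),
    axial_px = 1, n_bscans = 16, n_ascans = 48, lateral_px = 150,
    bscan_spacing = 420, noise_sd = 0, seed = 55)
  sim <- simulate_oct_volume(spec)
  ss <- sector_summary(thickness_map(sim$truth, "TRT"), sector_grid())
  expect_equal(ss$combined[ss$quadrant == "superior"], 250)
  expect_equal(ss$combined[ss$quadrant == "inferior"], 210)
  expect_equal(ss$combined[ss$quadrant == "nasal"], 230)
  expect_equal(ss$combined[ss$quadrant == "temporal"], 230)
})

test_that("flipping laterality swaps nasal and temporal and is an involution", {
  spec <- retina_phantom_spec(
    layer_thickness = list(
      inner = function(x, y) 85 + 10 * x, opl = 20, onl = 60, outer = 65),
    axial_px = 1, n_bscans = 16, n_ascans = 48, lateral_px = 150,
    bscan_spacing = 420, noise_sd = 0, seed = 56)
  sim <- simulate_oct_volume(spec)
  map <- thickness_map(sim$truth, "TRT")
  left <- sector_summary(map, laterality = "left")
  right <- sector_summary(map, laterality = "right")
  expect_equal(left$combined[left$quadrant == "nasal"],
               right$combined[right$quadrant == "temporal"])
  expect_equal(left$combined[left$quadrant == "temporal"],
               right$combined[right$quadrant == "nasal"])
  expect_equal(left$combined[left$quadrant == "superior"],
               right$combined[right$quadrant == "superior"])
  again <- sector_summary(map, laterality = "left")
  expect_identical(left$combined, again$combined)
})

test_that("an empty sector is reported as missing, not zero", {
  sim <- simulate_oct_volume(small_phantom(seed = 57))
  map <- thickness_map(segment_volume(sim$volume), "TRT")
  map$valid[retscreen:::enface_y_mm(15, 450) > 0, ] <- FALSE  # knock out superior half
  ss <- sector_summary(map, sector_grid())
  expect_true(is.na(ss$combined[ss$quadrant == "superior"]))
  expect_identical(ss$n_inner[ss$quadrant == "superior"] +
                     ss$n_outer[ss$quadrant == "superior"], 0)
})

test_that("manual sampling reads the map at 1 and 1.5 mm on the quadrant axes", {
  spec <- phantom_preset("wt", n_bscans = 15, n_ascans = 48, axial_px = 1,
                         lateral_px = 150, bscan_spacing = 450, noise_sd = 0,
                         seed = 58)
  sim <- simulate_oct_volume(spec)
  map <- thickness_map(sim$truth, "TRT")
  s <- manual_quadrant_sample(map)
  expect_equal(nrow(s), 8L)
  expect_true(all(s$thickness_um == 230))

  # radial gradient: thickness grows 20 um per mm, so the 1.5 mm samples
  # exceed the 1.0 mm samples by ~10 um (up to pixel rounding)
  spec2 <- retina_phantom_spec(
    layer_thickness = list(
      inner = function(x, y) 85 + 20 * sqrt(x^2 + y^2), opl = 20, onl = 60,
      outer = 65),
    axial_px = 1, n_bscans = 15, n_ascans = 48, lateral_px = 150,
    bscan_spacing = 450, noise_sd = 0, seed = 59)
  map2 <- thickness_map(simulate_oct_volume(spec2)$truth, "TRT")
  s2 <- manual_quadrant_sample(map2)
  wide <- tidyr::pivot_wider(s2, names_from = "distance_mm",
                             values_from = "thickness_um")
  diffs <- wide$`1.5` - wide$`1`
  expect_true(all(abs(diffs - 10) <= 2))

  # a point beyond the scanned field is missing
  far <- manual_quadrant_sample(map, distances = c(1.0, 50))
  expect_true(all(is.na(far$thickness_um[far$distance_mm == 50])))
  expect_false(any(is.na(far$thickness_um[far$distance_mm == 1.0])))
})
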