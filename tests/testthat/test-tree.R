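test_that("degenerate one-generation tree is a single segment with one outlet", {
  tr <- generate_tree(1, 0.15, seed = 42)
  expect_identical(nrow(tr$segments), 1L)
  expect_identical(tree_outlets(tr), 1L)
  expect_equal(tr$segments$radius_cm, 0.15)
})

test_that("bifurcation radii satisfy the cube law and generation is deterministic", {
  tr <- generate_tree(2, 0.15, seed = 7)
  expect_identical(nrow(tr$segments), 3L)
  r <- tr$segments$radius_cm
  expect_lt(abs(r[1]^3 - r[2]^3 - r[3]^3), 1e-12)
  expect_identical(generate_tree(2, 0.15, seed = 7), tr)
  expect_false(identical(generate_tree(2, 0.15, seed = 8), tr))
})

test_that("every bifurcation of deeper random trees is Murray-consistent", {
  for (s in 1:20) {
    tr <- generate_tree(3, 0.15, seed = s)
    seg <- tr$segments
    for (p in setdiff(seg$id, tree_outlets(tr))) {
      ch <- seg$radius_cm[!is.na(seg$parent) & seg$parent == p]
      rp <- seg$radius_cm[seg$id == p]
      expect_lt(abs(rp^3 - sum(ch^3)) / rp^3, 1e-10)
    }
  }
})

test_that("generator rejects non-positive parameters", {
  expect_error(generate_tree(0, 0.15), "positive")
  expect_error(generate_tree(2, -0.1), "positive")
})

test_that("add_stenosis records the lesion without touching anything else", {
  tr <- generate_tree(3, seed = 1)
  tr2 <- add_stenosis(tr, 2, 0.7, 0.3)
  expect_true(is.na(tr$segments$sten_degree[2]))       # input untouched
  expect_equal(tr2$segments$sten_degree[2], 0.7)
  expect_identical(tr2$segments[-2, c("length_cm", "radius_cm")],
                   tr$segments[-2, c("length_cm", "radius_cm")])
  expect_error(add_stenosis(tr, 2, 1.0), "occlusion")
  expect_error(add_stenosis(tr, 2, 0.5, stenosis_length = 99), "longer")
  expect_error(add_stenosis(tr, 999, 0.5), "no segment")
})

test_that("a zero-degree stenosis is hemodynamically identical to the bare tree", {
  tr <- generate_tree(3, seed = 2)
  tr0 <- add_stenosis(tr, 2, 0, 0.3)
  al <- allocate_flow(4.5, murray_fractions(
    2 * tr$segments$radius_cm[match(tree_outlets(tr), tr$segments$id)]))
  s1 <- solve_baseline(tr, 93.33, al)
  s2 <- solve_baseline(tr0, 93.33, al)
  expect_equal(s2$node_pressure, s1$node_pressure, tolerance = 1e-12)
  expect_equal(s2$outlet_pressure, s1$outlet_pressure, tolerance = 1e-12)
})

test_that("measurement point lands the configured distance distal to the lesion", {
  tr <- bif_tree(L0 = 2, L1 = 3, L2 = 1)
  # stenosis mid-root: 1 cm left in root, 1.5 cm into the larger daughter
  tr2 <- add_stenosis(tr, 1, 0.5, 0.3, position = 0.5,
                      measurement_distance_cm = 2.5)
  expect_identical(tr2$measurement$segment_id, 2L)
  expect_equal(tr2$measurement$offset_cm, 1.5)
  # walk clipped at the branch end
  tr3 <- add_stenosis(tr, 2, 0.5, 0.3, position = 0.5,
                      measurement_distance_cm = 99)
  expect_identical(tr3$measurement$segment_id, 2L)
  expect_equal(tr3$measurement$offset_cm, 3)
})

test_that("guidewire insertion flags the stenotic branch and respects fit", {
  tr <- add_stenosis(generate_tree(3, seed = 1), 2, 0.5)
  trw <- insert_guidewire(tr)
  expect_equal(trw$wire_diameter_cm, 0.036)
  onpath <- trw$segments$id[trw$segments$wire]
  expect_true(2L %in% onpath)
  expect_true(trw$measurement$segment_id %in% onpath)
  expect_false(1L %in% onpath)   # stenotic-branch wire spares the root
  full <- insert_guidewire(tr, path = "inlet_to_measurement")
  expect_true(1L %in% full$segments$id[full$segments$wire])
  # empty path leaves the tree unchanged
  expect_identical(insert_guidewire(tr, path = integer(0)), tr)
  # wire thicker than the stenotic lumen: radius 0.15 * sqrt(1 - d) < 0.018
  deg <- 1 - (0.017 / 0.15)^2
  tight <- add_stenosis(tube_tree(0.15, 2), 1, deg, 0.3)
  expect_error(insert_guidewire(tight, path = 1L), "wire does not fit")
})

test_that("trees serialize to JSON and back unchanged", {
  tr <- insert_guidewire(add_stenosis(generate_tree(3, seed = 5), 2, 0.6))
  f <- tempfile(fileext = ".json")
  write_tree(tr, f)
  tr2 <- read_tree(f)
  expect_equal(tr2$segments, tr$segments)
  expect_equal(tr2$wire_diameter_cm, tr$wire_diameter_cm)
  expect_equal(tr2$measurement, tr$measurement)
})
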