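test_that("unit cell construction enforces lattice-system constraints", {
  expect_error(unit_cell("tetragonal", 100, b = 90, c = 50), "equal")
  expect_error(unit_cell("tetragonal", -1, c = 50), "positive")
  cell <- unit_cell("hexagonal", 58.01, c = 195.2)
  expect_equal(cell$gamma, 120)
  expect_equal(unit_cell("cubic", 100)$c, 100)
})

test_that("d-spacings match the quadratic forms for the screened phases", {
  catb <- unit_cell("tetragonal", 125.69, c = 54.408)
  expect_equal(d_spacing(catb, c(1, 0, 0)), 125.69)
  expect_equal(d_spacing(catb, c(1, 1, 0)), 125.69 / sqrt(2))
  expect_equal(d_spacing(catb, c(1, 1, 0)), 88.876, tolerance = 1e-4)
  expect_equal(d_spacing(catb, c(0, 0, 2)), 54.408 / 2)
  hex1 <- unit_cell("hexagonal", 58.01, c = 195.2)
  expect_equal(d_spacing(hex1, c(0, 0, 6)), 195.2 / 6)
  expect_equal(d_spacing(hex1, c(1, 0, 0)), 58.01 * sqrt(3) / 2)
  expect_error(d_spacing(catb, c(0, 0, 0)), "no d-spacing")
})

test_that("closed-form absences match the structure-factor oracle exactly", {
  set.seed(421)
  for (symbol in c("P41212", "P4212", "P42212", "P6522")) {
    sg <- space_group(symbol)
    hkl <- matrix(sample(-8:8, 3 * 500, replace = TRUE), ncol = 3)
    hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
    impl <- is_systematically_absent(sg, hkl)
    oracle <- vapply(seq_len(nrow(hkl)),
                     function(i) sf_absent_oracle(sg, hkl[i, ]), logical(1))
    expect_identical(impl, oracle, label = symbol)
  }
})

test_that("axial screw-axis conditions behave as tabulated", {
  expect_true(is_systematically_absent(space_group("P6522"), c(0, 0, 3)))
  expect_false(is_systematically_absent(space_group("P6522"), c(0, 0, 6)))
  expect_true(is_systematically_absent(space_group("P41212"), c(0, 0, 2)))
  expect_false(is_systematically_absent(space_group("P41212"), c(0, 0, 4)))
  expect_true(is_systematically_absent(space_group("P41212"), c(1, 0, 0)))
  # general reflections carry no condition in these groups
  expect_false(any(is_systematically_absent(space_group("P42212"),
                                            rbind(c(1, 2, 3), c(3, 1, 2)))))
  expect_error(space_group("Fd-3m"), "unsupported")
})

test_that("reflection generation merges families and orders by angle", {
  cub <- unit_cell("cubic", 100)
  r <- generate_reflections(cub, space_group("P-cubic"), c(0, 0.80), 1.24)
  expect_equal(nrow(r), 1)            # only the (100) family below 0.80 deg
  expect_equal(r$multiplicity, 6L)
  expect_equal(r$d, 100)
  expect_equal(r$two_theta, 2 * asin(1.24 / 200) * 180 / pi)

  # below the first reflection: empty, not an error
  empty <- generate_reflections(cub, space_group("P-cubic"), c(0, 0.1), 1.24)
  expect_equal(nrow(empty), 0)
})

test_that("generated reflections agree with brute-force enumeration", {
  hex1 <- unit_cell("hexagonal", 58.01, c = 195.2)
  sg <- space_group("P6522")
  refl <- generate_reflections(hex1, sg, c(0.4, 2.0), 1.24)
  brute <- brute_reflection_count(hex1, sg, c(0.4, 2.0), 1.24, h_max = 8)
  # multiplicity-weighted count equals the raw enumeration count
  expect_equal(sum(refl$multiplicity), brute$n)
  # multiset of d-spacings is conserved by merging
  expect_equal(sort(rep(refl$d, refl$multiplicity)), sort(brute$d),
               tolerance = 1e-12)
  # ordering invariants
  expect_true(all(diff(refl$two_theta) >= 0))
  expect_true(all(diff(refl$d) <= 0))
  # consistency of the per-row quantities
  expect_equal(refl$s, 2 * pi / refl$d, tolerance = 1e-12)
  expect_equal(refl$two_theta, two_theta_from_d(refl$d, 1.24), tolerance = 1e-12)
})

test_that("reflection multiplicities match orbit sizes for mixed classes", {
  sg <- space_group("P42212")
  expect_equal(reflection_multiplicity(sg, c(0, 0, 2)), 2L)
  expect_equal(reflection_multiplicity(sg, c(1, 0, 0)), 4L)
  expect_equal(reflection_multiplicity(sg, c(1, 1, 0)), 4L)
  expect_equal(reflection_multiplicity(sg, c(1, 2, 3)), 16L)
  sg6 <- space_group("P6522")
  expect_equal(reflection_multiplicity(sg6, c(0, 0, 6)), 2L)
  expect_equal(reflection_multiplicity(sg6, c(1, 0, 0)), 6L)
})

test_that("reflection tables export with the supplementary column set", {
  refl <- generate_reflections(unit_cell("tetragonal", 125.69, c = 54.408),
                               space_group("P42212"), c(0.4, 2.0), 1.24)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reflection_table(refl, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("hkl", "d_A", "two_theta_deg", "s_invA", "multiplicity"))
  expect_equal(nrow(tab), nrow(refl))
  expect_equal(tab$d_A, refl$d, tolerance = 1e-9)
})
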