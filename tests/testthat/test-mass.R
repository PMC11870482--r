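# Independent element-summation oracle used to freeze expected masses.
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0)
  C * 12.0 + H * 1.00782503 + N * 14.00307401 + O * 15.99491462

test_that("fragment formulas follow glycosidic condensation arithmetic", {
  f <- fragment_formula(glycan_fragment(c("GlcNAc", "anhMurNAc")))
  expect_identical(format_formula(f), "C19H30N2O12")

  f2 <- fragment_formula(glycan_fragment(c("GlcN", "anhMurNAc")))
  expect_identical(format_formula(f2), "C17H28N2O11")
  # the deacetylated disaccharide is exactly the parent minus C2H2O
  expect_identical(unname(as_formula(f) - as_formula(f2)),
                   unname(as_formula("C2H2O")))

  # single unit: no water loss
  expect_identical(fragment_formula(glycan_fragment("GlcNAc")),
                   as_formula("C8H15NO6"))

  # additivity: formula(u1,u2,u3) = formula(u1,u2) + formula(u3) - H2O
  u123 <- fragment_formula(glycan_fragment(c("GlcNAc", "MurNAc", "GlcN")))
  u12 <- fragment_formula(glycan_fragment(c("GlcNAc", "MurNAc")))
  u3 <- fragment_formula(glycan_fragment("GlcN"))
  expect_identical(u123, formula_subtract(formula_add(u12, u3), c(H = 2, O = 1)))

  expect_error(glycan_fragment(character()), "at least one")
  expect_error(glycan_fragment(c("GlcNAc", "anhMurNAc"), reduced = TRUE),
               "anhydro")
  expect_error(glycan_fragment("NotASugar"), "unknown")
})

test_that("every deacetylated unit is its parent minus one acetyl group", {
  units <- glycan_units()
  pairs <- list(c("GlcNAc", "GlcN"), c("MurNAc", "MurN"),
                c("anhMurNAc", "anhMurN"))
  for (p in pairs)
    expect_identical(unname(units[[p[1]]] - units[[p[2]]]),
                     unname(as_formula("C2H2O")))
})

test_that("monoisotopic masses match the element-table summation oracle", {
  expect_equal(monoisotopic_mass("C19H30N2O12"),
               oracle_mass(C = 19, H = 30, N = 2, O = 12), tolerance = 1e-12)
  expect_equal(monoisotopic_mass("C19H30N2O12"), 478.1799, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C17H28N2O11"), 436.1693, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(""), 0)
  expect_error(as_formula(c(Zn = 1)), "unknown element")
  expect_error(formula_subtract("CH4", "C2H2O"), "negative")
})

test_that("protonated m/z of the anhydro-disaccharides rounds to the printed peaks", {
  m_acetylated <- monoisotopic_mass(glycan_fragment(c("GlcNAc", "anhMurNAc")))
  m_deacetylated <- monoisotopic_mass(glycan_fragment(c("GlcN", "anhMurNAc")))
  expect_equal(mz_value(m_deacetylated, 1), 437.1766, tolerance = 1e-4)
  expect_equal(mz_value(m_acetylated, 1), 479.1872, tolerance = 1e-4)
  expect_identical(round(mz_value(m_deacetylated, 1)), 437)
  expect_identical(round(mz_value(m_acetylated, 1)), 479)

  expect_equal(mz_value(0, 1), 1.00727646, tolerance = 1e-8)
  expect_error(mz_value(100, 0), "charge")
  # strictly increasing in neutral mass at fixed charge
  masses <- seq(100, 2000, by = 37.7)
  expect_true(all(diff(mz_value(masses, 2)) > 0))
})

test_that("mass constants are internally consistent", {
  mc <- mass_constants()
  expect_equal(mc$acetyl_delta, 42.0105646, tolerance = 1e-6)
  expect_equal(mc$h2, 2.0156501, tolerance = 1e-6)
  expect_equal(mc$water, monoisotopic_mass("H2O"))
  # reduction adds exactly H2
  red <- glycan_fragment(c("GlcNAc", "MurNAc"), reduced = TRUE)
  unred <- glycan_fragment(c("GlcNAc", "MurNAc"))
  expect_equal(monoisotopic_mass(red) - monoisotopic_mass(unred), mc$h2,
               tolerance = 1e-9)
})

test_that("acetyl mass shift holds for every unit substitution in chains", {
  mc <- mass_constants()
  subs <- list(c("GlcNAc", "GlcN"), c("MurNAc", "MurN"),
               c("anhMurNAc", "anhMurN"))
  chains <- list(c("GlcNAc", "MurNAc"), c("GlcNAc", "anhMurNAc"),
                 c("GlcNAc", "MurNAc", "GlcNAc", "anhMurNAc"))
  for (chain in chains) for (s in subs) {
    pos <- which(chain == s[1])
    for (p in pos) {
      mod <- chain
      mod[p] <- s[2]
      expect_equal(
        monoisotopic_mass(glycan_fragment(chain)) -
          monoisotopic_mass(glycan_fragment(mod)),
        mc$acetyl_delta, tolerance = 1e-6)
    }
  }
})
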