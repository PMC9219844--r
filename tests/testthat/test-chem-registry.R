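test_that("formula parsing follows Hill-notation grammar and round-trips", {
  expect_equal(parse_formula("C5H4N4O"), c(C = 5L, H = 4L, N = 4L, O = 1L))
  expect_equal(parse_formula("C"), c(C = 1L))
  expect_equal(parse_formula("C6H14O6"), c(C = 6L, H = 14L, O = 6L))
  # repeated symbols accumulate; serialization is stable under re-parse
  expect_equal(parse_formula("CH3CH3"), c(C = 2L, H = 6L))
  for (f in c("C5H4N4O", "C57H86O4", "C20H32N6O12S2", "NaCl", "C6H5F")) {
    parsed <- parse_formula(f)
    expect_identical(parse_formula(format_formula(parsed)), parsed)
  }
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C5Xx4"), "Xx")
  expect_error(parse_formula("h2o"), "malformed")
})

test_that("monoisotopic masses match independently summed IUPAC values", {
  expect_identical(monoisotopic_mass("C"), 12.0)
  # frozen from an independent hand sum of IUPAC monoisotopic atomic masses
  expect_equal(monoisotopic_mass("C5H4N4O"), 136.0385, tolerance = 5e-4 / 136)
  expect_equal(monoisotopic_mass("C12H24O2"), 200.1776, tolerance = 5e-4 / 200)
  expect_error(monoisotopic_mass(c(Zz = 1)), "missing")
})

test_that("mass is additive over formula union", {
  set.seed(41)
  els <- names(element_masses())
  for (i in 1:50) {
    f1 <- setNames(sample(1:30, 4), sample(els, 4))
    f2 <- setNames(sample(1:30, 3), sample(els, 3))
    joint <- tapply(c(f1, f2), names(c(f1, f2)), sum)
    expect_equal(monoisotopic_mass(joint),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9 / 100)
  }
})

test_that("adduct m/z arithmetic and its inverse agree to 1e-9 u", {
  expect_equal(adduct_mz(0, "M+H[1+]"), 1.007276)
  # paper-catalogued observations, both within 10 ppm of theory
  expect_lt(abs(ppm_error(170.081, adduct_mz(monoisotopic_mass("C8H11NO3"),
                                             "M+H[1+]"))), 10)
  expect_lt(abs(ppm_error(153.1264, adduct_mz(monoisotopic_mass("C18H34O2"),
                                              "M+H+Na[2+]"))), 10)
  set.seed(7)
  adducts <- default_adducts()
  for (m in runif(20, 50, 900)) {
    for (k in seq_len(nrow(adducts))) {
      a <- adducts[k, ]
      expect_equal(neutral_mass_from_mz(adduct_mz(m, a), a), m,
                   tolerance = 1e-9 / m)
    }
  }
  expect_error(adduct_mz(-1, "M+H[1+]"), ">= 0")
  expect_error(adduct_mz(10, "M-H2O[1+]"), "nonphysical")
})

test_that("registry loading computes masses and rejects malformed tables", {
  reg <- load_registry()
  expect_s3_class(reg, "compound_registry")
  expect_true(all(c("hypoxanthine", "pyridoxine", "D-sorbitol") %in%
                    reg$compounds$name))
  i <- match("hypoxanthine", reg$compounds$name)
  expect_equal(reg$compounds$neutral_mass[i], monoisotopic_mass("C5H4N4O"))

  hdr <- "name\tformula\tcas\tkegg\tec_links\tpathways\tverified"
  two <- tempfile(fileext = ".tsv")
  writeLines(c(hdr, "a\tC2H6O\t\t\t\t\tTRUE", "b\tC6H12O6\t\t\t\t\tTRUE"), two)
  reg2 <- load_registry(two, system.file("extdata", "adducts.tsv",
                                         package = "duomics"))
  expect_equal(nrow(reg2$compounds), 2L)
  expect_equal(reg2$compounds$neutral_mass[1], monoisotopic_mass("C2H6O"))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c(hdr, "a\tC2H6O\t\t\t\t\tTRUE", "a\tC6H12O6\t\t\t\t\tTRUE"), dup)
  expect_error(load_registry(dup), "duplicate")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(hdr, "a\tC2H6O\t\t\t\t\tTRUE", "b\tQq2\t\t\t\t\tTRUE"), bad)
  expect_error(load_registry(bad), "line 3")

  badcas <- tempfile(fileext = ".tsv")
  writeLines(c(hdr, "a\tC2H6O\t12-3-45\t\t\t\tTRUE"), badcas)
  expect_error(load_registry(badcas), "CAS")
})

test_that("every verified catalogued observation is within 10 ppm of theory", {
  reg <- load_registry()
  ref <- read.delim(system.file("extdata", "reference_features.tsv",
                                package = "duomics"))
  ver <- ref[ref$verified, ]
  expect_gt(nrow(ver), 20)
  for (i in seq_len(nrow(ver))) {
    m <- reg$compounds$neutral_mass[match(ver$metabolite[i], reg$compounds$name)]
    theo <- adduct_mz(m, ver$adduct[i], reg$adducts)
    expect_lt(abs(ppm_error(ver$mz[i], theo)), 10)
  }
})
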