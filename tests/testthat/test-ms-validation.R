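test_that("peptide masses match the elemental-composition oracle", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-4 / 75)
  expect_equal(peptide_mass("GFGN"), oracle_peptide_mass("GFGN"),
               tolerance = 1e-9)
  set.seed(12)
  for (i in 1:30) {
    s <- random_protein(sample(4:25, 1L))
    expect_lt(abs(peptide_mass(s) - oracle_peptide_mass(s)), 1e-4)
  }
  expect_error(peptide_mass("AXA"), "nonstandard")
  expect_error(peptide_mass("ABZ"), "nonstandard")
})

test_that("mass additivity holds at every split point", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_protein(sample(6:20, 1L))
    k <- sample(nchar(s) - 1L, 1L)
    a <- substr(s, 1, k); b <- substr(s, k + 1L, nchar(s))
    expect_equal(peptide_mass(s),
                 peptide_mass(a) + peptide_mass(b) - 18.0105646863,
                 tolerance = 1e-10)
  }
})

test_that("modification deltas are the documented constants", {
  mods <- modification_set()
  amide <- mods$delta[mods$name == "amide"]
  expect_equal(amide, -0.98402, tolerance = 1e-5 / 1)
  base <- peptide_mass("SFAN")
  expect_equal(peptide_mass("SFAN", amide) - base, amide)
  ## applying then removing restores the base mass exactly
  expect_identical(peptide_mass("SFAN", c(amide, -amide)), base)
  expect_equal(mods$delta[mods$name == "carbamidomethyl"], 57.02146)
  expect_true(mods$fixed[mods$name == "carbamidomethyl"])
  expect_false(any(mods$fixed[mods$name != "carbamidomethyl"]))
})

test_that("m/z to neutral mass uses the proton mass", {
  z <- 2L
  mz <- (1000.0045 + z * 1.007276466812) / z
  expect_equal(mz_to_neutral(mz, z), 1000.0045, tolerance = 1e-9)
  expect_error(mz_to_neutral(500, 0L))
})

test_that("form enumeration honors the 4-residue minimum and fixed mods", {
  ## too short: excluded entirely, even though it has modifiable sites
  short <- enumerate_modified_forms(list(sequence = "ACM", amidated = FALSE))
  expect_equal(nrow(short), 0L)

  ## one variable site (M oxidation) -> 2 forms, both carbamidomethylated
  forms <- enumerate_modified_forms(list(sequence = "ACDM",
                                         amidated = FALSE))
  expect_equal(nrow(forms), 2L)
  expect_true(all(grepl("carbamidomethyl@1", forms$mods)))
  expect_equal(sort(forms$mass - peptide_mass("ACDM") - 57.02146),
               c(0, 15.99491), tolerance = 1e-9)

  ## no eligible site: exactly one (fixed-only) form
  plain <- enumerate_modified_forms(list(sequence = "GFGN",
                                         amidated = FALSE))
  expect_equal(nrow(plain), 1L)
  expect_equal(plain$mods, "")
})

test_that("amidation is forced by the precursor model, never variable", {
  amid <- enumerate_modified_forms(list(sequence = "SFAN", amidated = TRUE))
  expect_equal(nrow(amid), 1L)
  expect_equal(amid$mods, "amide@C")
  expect_equal(amid$mass, peptide_mass("SFAN") - 0.98402,
               tolerance = 1e-9)
  free <- enumerate_modified_forms(list(sequence = "SFAN",
                                        amidated = FALSE))
  expect_false(any(grepl("amide", free$mods)))
})

test_that("N-terminal acetylation applies only to protein-N-term peptides", {
  nterm <- enumerate_modified_forms(list(sequence = "SFAN",
                                         amidated = FALSE,
                                         protein_n_term = TRUE))
  expect_equal(nrow(nterm), 2L)
  expect_true(any(grepl("acetyl@N", nterm$mods)))
  internal <- enumerate_modified_forms(list(sequence = "SFAN",
                                            amidated = FALSE))
  expect_equal(nrow(internal), 1L)
})

test_that("variable-mod combinations respect max_variable", {
  ## sites: 2x M-ox, 2x Y-sulfo = 4 variable sites (internal peptide)
  pep <- list(sequence = "MYMYA", amidated = FALSE)
  f3 <- enumerate_modified_forms(pep, max_variable = 3L)
  expect_equal(nrow(f3), 1 + 4 + choose(4, 2) + choose(4, 3))
  f1 <- enumerate_modified_forms(pep, max_variable = 1L)
  expect_equal(nrow(f1), 5L)
})

test_that("ppm matching is boundary-inclusive at the 4.5 ppm tolerance", {
  theo <- data.frame(sequence = "PEP", mods = "", mass = 1000.0)
  hit <- match_masses(theo, 1000.00450, tolerance_ppm = 4.5)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 4.5, tolerance = 1e-8)
  expect_true(hit$within_tolerance)

  miss <- match_masses(theo, 1000.00460, tolerance_ppm = 4.5)
  expect_equal(nrow(miss), 0L)
  expect_error(match_masses(theo, 1000, tolerance_ppm = 0), "positive")
})

test_that("shrinking the tolerance never adds matches", {
  set.seed(14)
  theo <- data.frame(sequence = "X", mods = "",
                     mass = runif(20, 500, 1500))
  obs <- theo$mass * (1 + rnorm(20, 0, 3e-6))
  wide <- match_masses(theo, obs, tolerance_ppm = 10)
  narrow <- match_masses(theo, obs, tolerance_ppm = 2)
  key <- function(m) paste(m$mass, m$observed_mass)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("observed-mass tables accept m/z+charge or neutral masses", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tmz\tcharge", "a\t501.007276466812\t2"), path)
  obs <- read_observed_masses(path)
  expect_equal(obs$neutral_mass, 1000, tolerance = 1e-9)
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tneutral_mass", "b\t1234.5"), path2)
  expect_equal(read_observed_masses(path2)$neutral_mass, 1234.5)
})
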