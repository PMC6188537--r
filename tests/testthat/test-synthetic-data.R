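small_spec <- function(...) plant_spec(n_decoys = 60L, n_planted = 9L,
                                       seed = 3L, ...)

test_that("generation is deterministic given the seed", {
  g1 <- generate_proteome(small_spec())
  g2 <- generate_proteome(small_spec())
  expect_identical(vapply(g1$proteins, `[[`, "", "residues"),
                   vapply(g2$proteins, `[[`, "", "residues"))
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_proteome(plant_spec(n_decoys = 60L, n_planted = 9L,
                                     seed = 4L))
  expect_false(identical(vapply(g1$proteins, `[[`, "", "residues"),
                         vapply(g3$proteins, `[[`, "", "residues")))
})

test_that("the generator leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_proteome(small_spec()))
  expect_identical(.Random.seed, before)
})

test_that("record counts and ids follow the plant specification", {
  gen <- generate_proteome(plant_spec(n_decoys = 100L, n_planted = 10L,
                                      seed = 1L))
  expect_length(gen$proteins, 110L)
  ids <- vapply(gen$proteins, `[[`, "", "id")
  expect_equal(sum(grepl("^planted", ids)), 10L)
  expect_equal(sum(grepl("^decoy", ids)), 100L)
  expect_length(gen$truth, 10L)
})

test_that("ground-truth spans re-slice the emitted sequences exactly", {
  gen <- generate_proteome(small_spec())
  seqs <- vapply(gen$proteins, `[[`, "", "residues")
  names(seqs) <- vapply(gen$proteins, `[[`, "", "id")
  for (t in gen$truth) {
    s <- seqs[[t$id]]
    for (p in t$paracopies)
      expect_identical(substr(s, p$start + 1L, p$end), p$sequence)
    ## signal span starts with Met and is heuristic-compatible
    expect_identical(substr(s, 1L, 1L), "M")
  }
})

test_that("planted amidated precursors carry two non-overlapping pattern matches", {
  gen <- generate_proteome(small_spec())
  pat <- builtin_patterns()$amidated_mcp
  seqs <- vapply(gen$proteins, `[[`, "", "residues")
  names(seqs) <- vapply(gen$proteins, `[[`, "", "id")
  for (t in gen$truth) {
    m <- scan_pattern(pat, seqs[[t$id]])
    expect_gte(nrow(m), 1L)
    ## greedy selection of non-overlapping matches
    chosen <- 0L; last_end <- -1L
    for (i in seq_len(nrow(m))) if (m$start[i] >= last_end) {
      chosen <- chosen + 1L; last_end <- m$end[i]
    }
    expect_gte(chosen, 2L)
  }
})

test_that("infeasible plant specs are rejected", {
  expect_error(plant_spec(family_motifs = c(big = strrep("A", 40))),
               "infeasible")
  expect_error(plant_spec(family_motifs = c(tiny = "AB")), "3 residues")
  expect_error(plant_spec(copies_range = c(5, 2)))
})

test_that("noise-free observed masses all match at 4.5 ppm", {
  gen <- generate_proteome(small_spec())
  obs <- generate_observed_masses(gen$truth, noise_ppm_sd = 0, dropout = 0,
                                  contaminants = 0, seed = 1L)
  expect_true(all(obs$source == "planted"))
  ## each observed mass equals its peptide's modified theoretical mass
  mods <- modification_set()
  amide <- mods$delta[mods$name == "amide"]
  cam <- mods$delta[mods$name == "carbamidomethyl"]
  t1 <- gen$truth[[1]]
  forms <- vapply(t1$paracopies, function(p) {
    nC <- lengths(regmatches(p$sequence,
                             gregexpr("C", p$sequence, fixed = TRUE)))
    peptide_mass(p$sequence) + cam * nC + if (p$amidated) amide else 0
  }, 0)
  got <- obs$neutral_mass[grepl(paste0("^", t1$id, "_"), obs$id)]
  expect_equal(got, forms, tolerance = 1e-9)
  ## and therefore every observed mass matches within the 4.5 ppm window
  ## (identical paracopies may cross-match, so count observed coverage)
  theo <- data.frame(sequence = "t", mods = "", mass = forms)
  hits <- match_masses(theo, got, tolerance_ppm = 4.5)
  expect_setequal(hits$observed_id, paste0("obs", seq_along(got)))
})

test_that("full dropout leaves only contaminants", {
  gen <- generate_proteome(small_spec())
  obs <- generate_observed_masses(gen$truth, dropout = 1, contaminants = 5L,
                                  seed = 2L)
  expect_equal(nrow(obs), 5L)
  expect_true(all(obs$source == "contaminant"))
})

test_that("1-ppm noise keeps nearly all planted masses inside 4.5 ppm", {
  gen <- generate_proteome(plant_spec(n_decoys = 0L, n_planted = 30L,
                                      seed = 6L))
  clean <- generate_observed_masses(gen$truth, noise_ppm_sd = 0, seed = 8L)
  noisy <- generate_observed_masses(gen$truth, noise_ppm_sd = 1, seed = 8L)
  ppm <- 1e6 * (noisy$neutral_mass - clean$neutral_mass) /
    clean$neutral_mass
  ## 4.5 sigma two-sided tail ~ 7e-6; all of ~200 draws stay inside
  expect_gte(mean(abs(ppm) <= 4.5), 0.99)
})

test_that("ground truth serializes to JSON faithfully", {
  gen <- generate_proteome(small_spec())
  path <- tempfile(fileext = ".json")
  write_ground_truth(gen$truth, path)
  back <- jsonlite::read_json(path)
  expect_named(back, names(gen$truth))
  expect_equal(back[[1]]$paracopies[[1]]$sequence,
               gen$truth[[1]]$paracopies[[1]]$sequence)
})
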