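make_ext <- function(id, score, cleavage_pos = 22L)
  data.frame(id = id, score = score, cleavage_pos = cleavage_pos,
             stringsAsFactors = FALSE)

test_that("external predictions gate on the 0.34 score cutoff", {
  p <- protein_sequence("q1", strrep("A", 60))
  call <- call_signal_peptide(p, make_ext("q1", 0.50, 22L))
  expect_true(call$has_signal)
  expect_equal(call$cleavage_pos, 22L)
  expect_equal(call$method, "external_table")

  low <- call_signal_peptide(p, make_ext("q1", 0.10))
  expect_false(low$has_signal)

  expect_error(call_signal_peptide(p, make_ext("q1", "bogus")),
               "malformed.*q1")
})

test_that("5'-incomplete sequences are untestable for a signal peptide", {
  p <- protein_sequence("frag", "KRSFANGKR", five_prime_complete = FALSE)
  call <- call_signal_peptide(p)
  expect_equal(call$method, "untestable_partial")
  expect_true(is.na(call$has_signal))
  ## an external prediction overrides partiality
  call2 <- call_signal_peptide(p, make_ext("frag", 0.9, 3L))
  expect_true(call2$has_signal)
})

test_that("the builtin heuristic needs Met, a hydrophobic core and a small residue", {
  pos <- protein_sequence("p", "MLLLLVVVASAAKRSFANGKR")
  call <- call_signal_peptide(pos)
  expect_true(call$has_signal)
  expect_equal(call$cleavage_pos, 10L)   # mature chain starts after ...AS
  expect_gte(call$score, 0.6)

  expect_false(call_signal_peptide(
    protein_sequence("x", "ALLLLVVVASAAKR"))$has_signal)   # no Met
  expect_false(call_signal_peptide(
    protein_sequence("x", "MLALAKAKAKAKAKAK"))$has_signal) # no 6-run
})

test_that("dibasic sites follow the [R/K]-[R/K] rule with leftmost pairing", {
  s1 <- find_cleavage_sites("AAKRCC")
  expect_equal(s1$pos, 2L)
  expect_equal(s1$residues, "KR")

  expect_equal(nrow(find_cleavage_sites("AAKAA")), 0L)

  s3 <- find_cleavage_sites("KRRK")
  expect_equal(s3$pos, c(0L, 2L))
  expect_equal(s3$residues, c("KR", "RK"))

  ## KRR: leftmost pair wins, trailing R unpaired
  s4 <- find_cleavage_sites("AAKRRAA")
  expect_equal(s4$pos, 2L)
  expect_equal(s4$residues, "KR")
})

test_that("the default monobasic rule fires only in an F-G-R context", {
  m <- find_cleavage_sites("AAFGRAA")
  expect_equal(m$kind, "monobasic")
  expect_equal(m$pos, 4L)
  expect_equal(m$residues, "R")
  ## K in the same context is not a monobasic site under the default rule
  expect_equal(nrow(find_cleavage_sites("AAFGKAA")), 0L)
  ## no double-counting when the R is part of a dibasic site
  d <- find_cleavage_sites("AAFGRRAA")
  expect_equal(d$kind, "dibasic")
  ## rule can be disabled
  expect_equal(nrow(find_cleavage_sites("AAFGRAA", monobasic = "none")), 0L)
})

test_that("peptide extraction applies the Gly amidation rule", {
  ## an amidated peptide between dibasic sites loses its donor G
  p <- protein_sequence("t", "MAKRYYAIVGRPRFGKRAA")
  sites <- find_cleavage_sites(p)
  peps <- extract_peptides(p, list(has_signal = FALSE), sites)
  i <- which(peps$sequence == "YYAIVGRPRF")
  expect_length(i, 1L)
  expect_true(peps$amidated[i])

  ## terminal N, no G donor: not amidated
  q <- protein_sequence("u", "MAKRGFGNKRAA")
  peps2 <- extract_peptides(q, list(has_signal = FALSE),
                            find_cleavage_sites(q, monobasic = "none"))
  j <- which(peps2$sequence == "GFGN")
  expect_length(j, 1L)
  expect_false(peps2$amidated[j])

  ## a lone G segment is degenerate and skipped with a warning
  r <- protein_sequence("v", "AAKRGKRCC")
  expect_warning(peps3 <- extract_peptides(r, list(has_signal = FALSE),
                                           find_cleavage_sites(r)),
                 "degenerate")
  expect_false("" %in% peps3$sequence)
})

test_that("pyroglutamation candidates are flagged but unaltered", {
  p <- protein_sequence("t", "AAKRQHWSYGKRAA")
  peps <- extract_peptides(p, list(has_signal = FALSE),
                           find_cleavage_sites(p))
  i <- which(peps$sequence == "QHWSY")
  expect_true(peps$n_term_pyroglu[i])
  expect_true(peps$amidated[i])          # the G donor still applies
  expect_match(peps$sequence[i], "^Q")
})

test_that("annotation reconstructs the protein exactly (tiling invariant)", {
  set.seed(77)
  for (i in 1:150) {
    p <- protein_sequence(paste0("r", i), random_protein(sample(30:120, 1L)))
    ann <- suppressWarnings(annotate_precursor(p))
    expect_true(check_tiling(ann))
    ## amidation soundness: flag iff the pre-site residue is G
    for (k in seq_len(nrow(ann$peptides))) {
      pe <- ann$peptides[k, ]
      donor <- substr(p$residues, pe$end, pe$end)
      expect_identical(pe$amidated, donor == "G")
    }
  }
})

test_that("a protein without basic residues yields one mature peptide", {
  p <- protein_sequence("solo", "MAAAAACCCDDD")
  ann <- annotate_precursor(p)
  expect_equal(nrow(ann$peptides), 1L)
  expect_equal(ann$peptides$sequence, "MAAAAACCCDDD")
})
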