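test_that("pattern parsing handles classes, wildcards and repeat bounds", {
  p <- parse_pattern("x(5, 200)-G-[KR]-[KR]")
  expect_length(p$elements, 4L)
  expect_identical(p$elements[[1]], list(class = "x", min = 5L, max = 200L))
  expect_identical(p$elements[[2]], list(class = "G", min = 1L, max = 1L))
  expect_setequal(p$elements[[3]]$class, c("K", "R"))
  expect_identical(c(p$elements[[3]]$min, p$elements[[3]]$max), c(1L, 1L))

  q <- parse_pattern("G-[KR](0, 1)")
  expect_identical(q$elements[[2]]$min, 0L)
  expect_identical(q$elements[[2]]$max, 1L)

  a <- parse_pattern("A")
  expect_length(a$elements, 1L)
  expect_identical(a$elements[[1]], list(class = "A", min = 1L, max = 1L))
})

test_that("malformed patterns raise parse errors", {
  expect_error(parse_pattern("x(5,"), "parse")
  expect_error(parse_pattern("x(3,2)"), "bounds")
  expect_error(parse_pattern("[]"), class = "simpleError")
  expect_error(parse_pattern("[KO1]"), class = "simpleError")
  expect_error(parse_pattern("J"), "unknown residue")
  expect_error(parse_pattern("{P}-A"), "exclusion")
  expect_error(parse_pattern("A--B"), "empty")
})

test_that("the three built-in screening patterns parse faithfully", {
  pats <- builtin_patterns()
  expect_named(pats, c("amidated_mcp", "nonamidated_mcp",
                       "rfamide_monobasic"))
  expect_match(pats$amidated_mcp$source_text, "x(5, 200)-G-[KR]-[KR]",
               fixed = TRUE)
  ## element count equals the hyphen-separated token count of each string
  for (p in pats) {
    tokens <- strsplit(p$source_text, "-", fixed = TRUE)[[1]]
    expect_length(p$elements, length(tokens))
  }
  expect_equal(vapply(pats, function(p) length(p$elements), 0L),
               c(amidated_mcp = 11L, nonamidated_mcp = 12L,
                 rfamide_monobasic = 15L))
  ## re-serializing reproduces the element structure
  for (p in pats)
    expect_length(parse_pattern(format(p))$elements, length(p$elements))
})

test_that("scan reports spec'd example matches", {
  m <- scan_pattern(parse_pattern("R-F-G-[KR]"), "AARFGKAA")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(2L, 6L))
  expect_equal(m$matched, "RFGK")

  m2 <- scan_pattern(parse_pattern("x(2, 3)-G"), "AAG")
  expect_equal(c(m2$start, m2$end), c(0L, 3L))
  expect_equal(unname(m2$element_spans[[1]][1, ]), c(0L, 2L))

  p <- parse_pattern("x(5, 200)-G-[KR]-[KR]")
  expect_equal(nrow(scan_pattern(p, "")), 0L)
  expect_equal(nrow(scan_pattern(p, "AA")), 0L)
})

test_that("X matches the wildcard but never a residue class", {
  p <- parse_pattern("x-G")
  expect_equal(nrow(scan_pattern(p, "XG")), 1L)
  q <- parse_pattern("[GA]-K")
  expect_equal(nrow(scan_pattern(q, "XK")), 0L)
})

test_that("scan equals the brute-force oracle on random cases", {
  set.seed(101)
  for (case in 1:80) {
    pat <- parse_pattern(random_pattern_text())
    s <- random_protein(sample(5:60, 1L))
    exp <- oracle_scan_shortest(pat$elements, s)
    got <- scan_pattern(pat, s)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp))
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(exp))
    ## all-expansions policy equals the full enumeration's match set
    all_o <- oracle_scan_all(pat$elements, s)
    got_all <- scan_pattern(pat, s, policy = "all")
    oset <- if (length(all_o))
      sort(unique(vapply(all_o, paste, "", collapse = ":"))) else character()
    gset <- if (nrow(got_all))
      sort(unique(paste(got_all$start, got_all$end, sep = ":")))
    else character()
    expect_identical(gset, oset)
  }
})

test_that("every reported match re-validates against its pattern", {
  set.seed(202)
  for (case in 1:30) {
    pat <- parse_pattern(random_pattern_text())
    s <- random_protein(sample(10:60, 1L))
    m <- scan_pattern(pat, s)
    for (i in seq_len(nrow(m))) {
      spans <- m$element_spans[[i]]
      expect_equal(spans[1, "start"], m$start[i])
      expect_equal(spans[nrow(spans), "end"], m$end[i])
      ## spans tile contiguously and satisfy class/bounds
      for (j in seq_len(nrow(spans))) {
        if (j > 1) expect_equal(spans[j, "start"], spans[j - 1, "end"])
        e <- pat$elements[[j]]
        len <- spans[j, "end"] - spans[j, "start"]
        expect_gte(len, e$min)
        expect_lte(len, e$max)
        if (!identical(e$class, "x") && len > 0) {
          piece <- substr(s, spans[j, "start"] + 1L, spans[j, "end"])
          expect_true(all(strsplit(piece, "")[[1]] %in% e$class))
        }
      }
    }
  }
})

test_that("widening repeat bounds never removes a match start", {
  set.seed(303)
  for (case in 1:20) {
    els <- random_pattern_text(max_elements = 3L)
    pat <- parse_pattern(els)
    s <- random_protein(40)
    before <- scan_pattern(pat, s)$start
    ## widen one random element's max bound
    k <- sample(length(pat$elements), 1L)
    pat$elements[[k]]$max <- pat$elements[[k]]$max + 2L
    after <- scan_pattern(pat, s)$start
    expect_true(all(before %in% after))
  }
})

test_that("pattern flat files round-trip names and patterns", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# builtins subset",
               "amide\tx(5, 200)-G-[KR]-[KR]",
               "simple\tR-F-G-[KR]"), path)
  pats <- read_pattern_file(path)
  expect_named(pats, c("amide", "simple"))
  expect_length(pats$amide$elements, 4L)
  expect_error(read_pattern_file(write_temp_fasta(c(x = "A"))), "TAB")
})
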