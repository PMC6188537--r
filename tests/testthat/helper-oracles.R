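# Independent oracles used to cross-check the production implementations.
# These are deliberately naive re-derivations: exhaustive enumeration for
# the motif scanner, a quadratic affine-gap DP for Smith-Waterman, and
# elemental-composition arithmetic for peptide masses.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# ---- motif oracle: enumerate every (start, repeat assignment) ----------

oracle_scan_all <- function(elements, s) {
  n <- nchar(s)
  chars <- strsplit(s, "")[[1L]]
  res <- list()
  rec <- function(ei, pos, st) {
    if (ei > length(elements)) {
      res[[length(res) + 1L]] <<- c(st, pos)
      return(invisible())
    }
    e <- elements[[ei]]
    for (k in e$min:e$max) {
      if (pos + k > n) break
      ok <- k == 0L || identical(e$class, "x") ||
        all(chars[(pos + 1L):(pos + k)] %in% e$class)
      if (!ok) break
      rec(ei + 1L, pos + k, st)
    }
  }
  minlen <- sum(vapply(elements, `[[`, 0L, "min"))
  if (n >= minlen) for (st in 0:(n - minlen)) rec(1L, st, st)
  res
}

# per-start shortest matches, as (start, end) matrix sorted by start
oracle_scan_shortest <- function(elements, s) {
  o <- oracle_scan_all(elements, s)
  if (!length(o)) return(matrix(integer(), ncol = 2L))
  om <- do.call(rbind, o)
  sh <- tapply(om[, 2L], om[, 1L], min)
  out <- cbind(as.integer(names(sh)), as.integer(sh))
  out[order(out[, 1L]), , drop = FALSE]
}

random_pattern_text <- function(max_elements = 4L, max_repeat = 5L) {
  ne <- sample(seq_len(max_elements), 1L)
  paste(vapply(seq_len(ne), function(i) {
    head <- if (runif(1) < 0.3) "x" else
      paste0("[", paste(sample(AA20, sample(1:3, 1L)), collapse = ""), "]")
    m <- sample(0:(max_repeat - 1L), 1L)
    mx <- m + sample(0:(max_repeat - m), 1L)
    if (runif(1) < 0.6) paste0(head, "(", m, ",", mx, ")") else head
  }, ""), collapse = "-")
}

.get_blosum <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  e[[name]]
}

# ---- Smith-Waterman affine-gap DP oracle -------------------------------

# gap of length L costs open + L * ext (matching the production aligner's
# convention); returns the best local score
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)   # gap in a (consume b)
  F <- matrix(-Inf, n + 1L, m + 1L)   # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + mat[ac[i - 1L], bc[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# ---- elemental-composition mass oracle ---------------------------------

# residue formulas (amino acid minus water) and monoisotopic element masses
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0))

.element_mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)

oracle_peptide_mass <- function(sequence) {
  ch <- strsplit(sequence, "")[[1L]]
  total <- Reduce(`+`, .residue_formula[ch])
  total["H"] <- total["H"] + 2   # + H2O
  total["O"] <- total["O"] + 1
  sum(total * .element_mono[names(total)])
}

# ---- small fixtures ----------------------------------------------------

write_temp_fasta <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(Map(function(id, s) c(paste0(">", id), s),
                        names(entries), entries)), path)
  path
}
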