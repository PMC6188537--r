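## PROSITE-dialect motif engine.
##
## The dialect needed here: hyphen-separated elements; `x` wildcard; `[KR]`
## residue classes; `(m,n)` / `(m, n)` repeat bounds; bare element = (1,1);
## optional leading `<` / trailing `>` anchors are parsed and honoured.
## Exclusion classes `{X}` are rejected explicitly.

#' Parse a PROSITE-style pattern
#'
#' Parses a variable-gap protein motif in PROSITE syntax into an ordered
#' list of elements, each a residue class (or wildcard) with repeat bounds.
#'
#' @param text Pattern string, e.g. \code{"x(5, 200)-G-[KR]-[KR]"}.
#' @param name Optional pattern name.
#' @return An object of class \code{PrositePattern} with fields
#'   \code{name}, \code{elements} (list of \code{list(class, min, max)} where
#'   \code{class} is a character vector of residues or \code{"x"} for the
#'   wildcard), \code{anchor_start}, \code{anchor_end}, and
#'   \code{source_text}.
#' @export
parse_pattern <- function(text, name = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  src <- text
  s <- gsub("[.]$", "", trimws(text))   # PROSITE terminal period
  anchor_start <- grepl("^<", s)
  anchor_end <- grepl(">$", s)
  s <- sub("^<", "", sub(">$", "", s))
  if (grepl("[{}]", s))
    stop("exclusion classes {..} are not supported (offset ",
         regexpr("[{}]", s), ")")
  toks <- strsplit(s, "-", fixed = TRUE)[[1L]]
  if (!length(toks) || any(!nzchar(trimws(toks))))
    stop("empty pattern element in '", src, "'")
  offset <- 0L
  elements <- lapply(toks, function(tok) {
    tok0 <- tok
    tok <- trimws(tok)
    m <- regexec("^(x|\\[([A-Za-z]+)\\]|[A-Za-z])(\\(\\s*(\\d+)\\s*(,\\s*(\\d+)\\s*)?\\))?$",
                 tok)
    g <- regmatches(tok, m)[[1L]]
    if (!length(g))
      stop("cannot parse pattern element '", tok0, "' in '", src, "'")
    head <- g[2L]
    if (identical(head, "x")) {
      cls <- "x"
    } else {
      residues <- if (nzchar(g[3L])) g[3L] else head
      cls <- unique(strsplit(toupper(residues), "")[[1L]])
      unknown <- setdiff(cls, PROTEIN_ALPHABET)
      if (length(unknown))
        stop("unknown residue symbol '", unknown[1L], "' in '", tok0, "'")
    }
    if (nzchar(g[4L])) {
      mn <- as.integer(g[5L])
      mx <- if (nzchar(g[7L])) as.integer(g[7L]) else mn
    } else {
      mn <- 1L; mx <- 1L
    }
    if (mn > mx) stop("repeat bounds (", mn, ",", mx, ") invalid in '",
                      tok0, "'")
    list(class = cls, min = mn, max = mx)
  })
  structure(list(name = name, elements = elements,
                 anchor_start = anchor_start, anchor_end = anchor_end,
                 source_text = src),
            class = "PrositePattern")
}

#' @export
print.PrositePattern <- function(x, ...) {
  cat(sprintf("PrositePattern %s: %s (%d elements)\n",
              if (is.na(x$name)) "<unnamed>" else x$name,
              x$source_text, length(x$elements)))
  invisible(x)
}

#' @export
format.PrositePattern <- function(x, ...) {
  vapply(x$elements, function(e) {
    head <- if (identical(e$class, "x")) "x"
            else if (length(e$class) == 1L) e$class
            else paste0("[", paste(e$class, collapse = ""), "]")
    if (e$min == 1L && e$max == 1L) head
    else if (e$min == e$max) sprintf("%s(%d)", head, e$min)
    else sprintf("%s(%d,%d)", head, e$min, e$max)
  }, "") |> paste(collapse = "-")
}

## Regex fragment for one element. Wildcard matches any residue symbol
## (including X/B/Z/U); a class matches only its own residues, so X and
## other ambiguity codes never satisfy a class.
.element_regex <- function(e, lazy = TRUE) {
  head <- if (identical(e$class, "x")) "."
          else if (length(e$class) == 1L) e$class
          else paste0("[", paste(e$class, collapse = ""), "]")
  rep <- if (e$min == 1L && e$max == 1L) ""
         else sprintf("{%d,%d}", e$min, e$max)
  paste0("(", head, rep, if (nzchar(rep) && lazy) "?" else "", ")")
}

.pattern_regex <- function(pattern, lazy = TRUE) {
  paste0(vapply(pattern$elements, .element_regex, "", lazy = lazy),
         collapse = "")
}

.min_pattern_len <- function(pattern)
  sum(vapply(pattern$elements, `[[`, 0L, "min"))

#' Scan a protein sequence with a parsed pattern
#'
#' Locates occurrences of a variable-gap motif. Under the default policy a
#' single match is reported per distinct start position, using the shortest
#' total extension (lazy repeats); \code{policy = "all"} enumerates every
#' distinct repeat-count assignment. Wildcard elements match any residue
#' symbol (including \code{X}); residue classes match only their listed
#' residues, so \code{X}, \code{B}, \code{Z}, \code{U} never satisfy a
#' class.
#'
#' @param pattern A \code{\link{parse_pattern}} result.
#' @param sequence A \code{\link{protein_sequence}} or plain residue string.
#' @param policy \code{"per_start"} (default: shortest match per start) or
#'   \code{"all"} (every expansion).
#' @return Data frame with one row per match: \code{sequence_id},
#'   \code{start}, \code{end} (0-based half-open), \code{matched}, and an
#'   \code{element_spans} list-column of per-element \code{(start, end)}
#'   matrices tiling \code{[start, end)}.
#' @export
scan_pattern <- function(pattern, sequence, policy = c("per_start", "all")) {
  policy <- match.arg(policy)
  stopifnot(inherits(pattern, "PrositePattern"))
  if (inherits(sequence, "ProteinSequence")) {
    seq_id <- sequence$id; s <- sequence$residues
  } else {
    seq_id <- "seq"; s <- toupper(as.character(sequence))
  }
  n <- nchar(s)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  empty$element_spans <- list()
  if (n < .min_pattern_len(pattern) || n == 0L) return(empty)
  if (policy == "all") {
    rows <- .scan_all(pattern, s, seq_id)
  } else {
    rows <- .scan_per_start(pattern, s, seq_id)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sequence_id = seq_id, start = r$start, end = r$end,
               matched = substr(s, r$start + 1L, r$end),
               stringsAsFactors = FALSE)))
  out$element_spans <- lapply(rows, `[[`, "spans")
  o <- order(out$start, out$end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Shortest match anchored at each start, via a lazy PCRE with one capture
## group per element.
.scan_per_start <- function(pattern, s, seq_id) {
  rx <- paste0("^", .pattern_regex(pattern, lazy = TRUE))
  n <- nchar(s)
  starts <- if (pattern$anchor_start) 0L else 0:(n - .min_pattern_len(pattern))
  rows <- list()
  for (st in starts) {
    sub <- substr(s, st + 1L, n)
    m <- regexpr(rx, sub, perl = TRUE)
    if (m < 0L) next
    cs <- attr(m, "capture.start")[1L, ]
    cl <- attr(m, "capture.length")[1L, ]
    end <- st + attr(m, "match.length")
    if (pattern$anchor_end && end != n) {
      hit <- .anchored_end_match(pattern, s, st)
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <- hit
      next
    }
    spans <- cbind(start = st + cs - 1L, end = st + cs - 1L + cl)
    ## zero-width captures of skipped optional elements report position 0
    zero <- cl == 0L
    if (any(zero)) {
      pos <- st
      for (i in seq_along(cl)) {
        if (zero[i]) { spans[i, ] <- c(pos, pos) } else pos <- spans[i, 2L]
      }
    }
    rows[[length(rows) + 1L]] <- list(start = st, end = end, spans = spans)
  }
  rows
}

## End-anchored fallback: take the shortest expansion ending exactly at the
## sequence end, by exhaustive enumeration from this start.
.anchored_end_match <- function(pattern, s, st) {
  all <- .expand_matches(pattern$elements, s, st, nchar(s))
  all <- Filter(function(r) r$end == nchar(s), all)
  if (!length(all)) return(NULL)
  all[[which.min(vapply(all, function(r) r$end - r$start, 0L))]]
}

## Exhaustive enumeration of repeat assignments by depth-first search.
.expand_matches <- function(elements, s, st, n) {
  out <- list()
  chars <- strsplit(s, "")[[1L]]
  rec <- function(ei, pos, spans) {
    if (ei > length(elements)) {
      out[[length(out) + 1L]] <<- list(start = st, end = pos,
                                       spans = do.call(rbind, spans))
      return(invisible())
    }
    e <- elements[[ei]]
    for (k in e$min:e$max) {
      if (pos + k > n) break
      if (k > 0L && !identical(e$class, "x")) {
        if (!all(chars[(pos + 1L):(pos + k)] %in% e$class)) {
          if (k == 0L) next else break
        }
      }
      rec(ei + 1L, pos + k,
          c(spans, list(matrix(c(pos, pos + k), 1L,
                               dimnames = list(NULL, c("start", "end"))))))
    }
  }
  rec2 <- rec  # keep name for clarity
  rec2(1L, st, list())
  out
}

.scan_all <- function(pattern, s, seq_id) {
  n <- nchar(s)
  starts <- if (pattern$anchor_start) 0L else 0:(n - .min_pattern_len(pattern))
  rows <- list()
  for (st in starts) {
    hits <- .expand_matches(pattern$elements, s, st, n)
    if (pattern$anchor_end) hits <- Filter(function(r) r$end == n, hits)
    rows <- c(rows, hits)
  }
  rows
}

#' Built-in multicopy-precursor patterns
#'
#' The three motifs used to screen translated transcriptomes for recurrent
#' cleavage and amidation sites of multicopy neuropeptide precursors:
#' amidated dibasic repeats, non-amidated dibasic repeats, and RFamides with
#' monobasic cleavage.
#'
#' @return Named list of three \code{\link{parse_pattern}} results:
#'   \code{amidated_mcp}, \code{nonamidated_mcp}, \code{rfamide_monobasic}.
#' @export
builtin_patterns <- function() {
  defs <- c(
    amidated_mcp =
      "x(5, 200)-G-[KR]-[KR]-x(2, 35)-G-[KR]-[KR]-x(2, 35)-G-[KR](0, 1)",
    nonamidated_mcp =
      "x(5, 200)-[KR]-[KR]-x(2, 35)-[KR]-[KR]-x(2, 35)-[KR]-[KR]-x(2, 35)-[KR]-[KR]",
    rfamide_monobasic =
      "x(5, 200)-R-F-G-[KR]-x(2, 35)-R-F-G-[KR]-x(2, 35)-R-F-G-[KR](0, 1)")
  out <- Map(parse_pattern, defs, names(defs))
  names(out) <- names(defs)
  out
}

#' Read a pattern flat file
#'
#' One \code{name<TAB>pattern} per line; \code{#} starts a comment.
#'
#' @param path Path to the flat file.
#' @return Named list of \code{PrositePattern} objects.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) stop("expected name<TAB>pattern, got: ", l)
    parse_pattern(f[2L], f[1L])
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

## Fast vectorised candidate test: does each sequence contain >= 1 match?
## Used by the pipeline to prefilter large decoy sets before full scanning.
.has_motif_match <- function(pattern, residues) {
  rx <- .pattern_regex(pattern, lazy = TRUE)
  if (pattern$anchor_start) rx <- paste0("^", rx)
  if (pattern$anchor_end) rx <- paste0(rx, "$")
  grepl(rx, residues, perl = TRUE)
}
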