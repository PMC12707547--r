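#' Compile a PROSITE-syntax pattern into a matcher
#'
#' Supports the PROSITE pattern language used by signature entries such as the
#' serpin signature: single residues, `x` wildcards, `[ALLOWED]` sets,
#' `{FORBIDDEN}` sets, repeat counts `(n)` and ranges `(n,m)`, the `<` and `>`
#' anchors and an optional trailing period.
#'
#' The compiled object matches by explicit per-position constraint evaluation
#' with backtracking over variable-length repeats (shortest match reported per
#' start), so it can later report which element failed; it is not a regex
#' translation.
#'
#' @param pattern PROSITE pattern string, e.g. `"[ST]-x(2)-G"`
#' @return object of class `prosite_matcher`; use [prosite_match()] to scan
#' @export
compile_prosite <- function(pattern) {
  raw <- sub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(raw, "<")
  anchor_end <- endsWith(raw, ">")
  body <- sub(">$", "", sub("^<", "", raw))
  tokens <- strsplit(body, "-", fixed = TRUE)[[1]]
  offset <- if (anchor_start) 1L else 0L
  elements <- vector("list", length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (!nzchar(tok)) stop2("PROSITE syntax error at offset ", offset,
                            ": empty element", class = "prosite_syntax_error")
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
      tok))[[1]]
    if (length(m) == 0) {
      stop2("PROSITE syntax error at offset ", offset, ": cannot parse '",
            tok, "'", class = "prosite_syntax_error")
    }
    core <- m[2]
    lo <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
    if (hi < lo) stop2("PROSITE syntax error at offset ", offset,
                       ": repeat range (", lo, ",", hi, ") inverted",
                       class = "prosite_syntax_error")
    allowed <-
      if (core == "x") LETTERS
      else if (startsWith(core, "[")) seq_chars(substr(core, 2, nchar(core) - 1))
      else if (startsWith(core, "{")) setdiff(LETTERS,
                                              seq_chars(substr(core, 2, nchar(core) - 1)))
      else core
    elements[[k]] <- list(allowed = allowed, lo = lo, hi = hi, token = tok)
    offset <- offset + nchar(tok) + 1L
  }
  structure(list(pattern = pattern, elements = elements,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "prosite_matcher")
}

# does the pattern match starting at 0-based position `pos`? returns the
# 0-based end of the shortest match, or -1L
.prosite_match_from <- function(chars, elements, pos, k, anchor_end) {
  if (k > length(elements)) {
    if (anchor_end && pos != length(chars)) return(-1L)
    return(pos)
  }
  el <- elements[[k]]
  # consume the mandatory lo repeats, then try extensions shortest-first
  p <- pos
  for (i in seq_len(el$lo)) {
    if (p >= length(chars) || !(chars[p + 1L] %in% el$allowed)) return(-1L)
    p <- p + 1L
  }
  for (extra in 0:(el$hi - el$lo)) {
    if (extra > 0) {
      if (p >= length(chars) || !(chars[p + 1L] %in% el$allowed)) return(-1L)
      p <- p + 1L
    }
    res <- .prosite_match_from(chars, elements, p, k + 1L, anchor_end)
    if (res >= 0L) return(res)
  }
  -1L
}

#' Scan a protein with a compiled PROSITE matcher
#'
#' Reports every start position at which the pattern matches (overlaps
#' allowed); for variable-length patterns the shortest match at each start is
#' returned.
#'
#' @param matcher object from [compile_prosite()]
#' @param protein protein sequence string
#' @return data frame with 0-based half-open `start`, `end` and the `matched`
#'   subsequence; zero rows when there is no match
#' @export
prosite_match <- function(matcher, protein) {
  stopifnot(inherits(matcher, "prosite_matcher"))
  chars <- seq_chars(toupper(protein))
  n <- length(chars)
  starts <- if (matcher$anchor_start) 0L else seq_len(n) - 1L
  hits <- list()
  for (s in starts) {
    e <- .prosite_match_from(chars, matcher$elements, s, 1L, matcher$anchor_end)
    if (e >= 0L) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = e,
        matched = substr(protein, s + 1L, e), stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' The shipped serpin signature pattern (PROSITE PS00284)
#'
#' Read from package data rather than hard-coded, so it can be swapped for a
#' newer PROSITE release via the `prosite_pattern` config key.
#'
#' @return the pattern string
#' @export
serpin_signature_pattern <- function() {
  path <- system.file("extdata", "ps00284.txt", package = "serpinscope")
  lines <- readLines(path, warn = FALSE)
  pa <- sub("^PA\\s+", "", grep("^PA\\s", lines, value = TRUE))
  paste(pa, collapse = "")
}

#' Approximate motif search by Hamming distance
#'
#' Slides a fixed-length motif over the protein and reports every window whose
#' Hamming distance is at most `max_mismatches`, ranked by (mismatches,
#' start). With `max_mismatches = 0` this is exact substring search.
#'
#' @param protein protein record (list/one-row data frame with `sequence`) or
#'   a plain sequence string
#' @param motif motif string, e.g. `"NAVYFKG"`
#' @param max_mismatches maximum Hamming distance
#' @return data frame with `start`, `end` (0-based half-open),
#'   `mismatch_count`, `matched`
#' @export
find_motif <- function(protein, motif, max_mismatches = 0) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  seqstr <- toupper(seqstr)
  motif <- toupper(motif)
  m <- nchar(motif)
  n <- nchar(seqstr)
  if (m > n) stop2("motif longer than protein")
  sc <- seq_chars(seqstr)
  mc <- seq_chars(motif)
  starts0 <- 0:(n - m)
  mism <- vapply(starts0, function(s) {
    sum(sc[(s + 1):(s + m)] != mc)
  }, integer(1))
  keep <- which(mism <= max_mismatches)
  if (length(keep) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      mismatch_count = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    start = starts0[keep], end = starts0[keep] + m,
    mismatch_count = mism[keep],
    matched = substring(seqstr, starts0[keep] + 1, starts0[keep] + m),
    stringsAsFactors = FALSE)
  out <- out[order(out$mismatch_count, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
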