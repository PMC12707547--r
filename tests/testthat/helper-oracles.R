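# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by a different route than the package code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]), collapse = "")
}

# --- ORF oracle: regex-based six-frame scan -------------------------------
orf_oracle_frame <- function(fs, min_codons) {
  n3 <- nchar(fs) - nchar(fs) %% 3
  fs3 <- substr(fs, 1, n3)
  out <- list()
  consumed <- 0L
  # complete ORFs: lazily skip whole codons, then ATG .. first in-frame stop
  repeat {
    rest <- substring(fs3, consumed + 1L)
    m <- regexec("^((?:[ACGTN]{3})*?)(ATG(?:[ACGTN]{3})*?(?:TAA|TAG|TGA))",
                 rest, perl = TRUE)[[1]]
    if (m[1] == -1) break
    pre <- attr(m, "match.length")[2]
    len <- attr(m, "match.length")[3]
    st <- consumed + pre
    if (len / 3 - 1 >= min_codons) {
      out[[length(out) + 1L]] <- list(start = st, end = st + len,
                                      partial3 = FALSE)
    }
    consumed <- st + len
  }
  # trailing partial ORF: first remaining in-frame ATG, no stop to the end
  rest <- substring(fs3, consumed + 1L)
  a <- regexec("^((?:[ACGTN]{3})*?)(ATG(?:[ACGTN]{3})*)$", rest, perl = TRUE)[[1]]
  if (a[1] != -1) {
    st <- consumed + attr(a, "match.length")[2]
    if ((n3 - st) / 3 >= min_codons) {
      out[[length(out) + 1L]] <- list(start = st, end = n3, partial3 = TRUE)
    }
  }
  out
}

orf_oracle <- function(seqstr, min_codons, both_strands = TRUE) {
  L <- nchar(seqstr)
  rows <- list()
  for (fr in if (both_strands) c(1, 2, 3, -1, -2, -3) else 1:3) {
    src <- if (fr > 0) seqstr else revcomp(seqstr)
    off <- abs(fr) - 1L
    fs <- substr(src, off + 1L, nchar(src))
    for (o in orf_oracle_frame(fs, min_codons)) {
      st <- off + o$start; en <- off + o$end
      if (fr < 0) { tmp <- st; st <- L - en; en <- L - tmp }
      rows[[length(rows) + 1L]] <- data.frame(frame = fr, start = st, end = en,
                                              partial3 = o$partial3)
    }
  }
  if (length(rows) == 0) return(data.frame(frame = integer(), start = integer(),
                                           end = integer(), partial3 = logical()))
  do.call(rbind, rows)
}

# --- PROSITE oracle: translate the pattern to a regular expression --------
prosite_to_regex <- function(pattern) {
  raw <- sub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(raw, "<")
  anchor_end <- endsWith(raw, ">")
  body <- sub(">$", "", sub("^<", "", raw))
  parts <- vapply(strsplit(body, "-", fixed = TRUE)[[1]], function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
      tok))[[1]]
    core <- m[2]
    re <- if (core == "x") "[A-Z]"
          else if (startsWith(core, "{")) paste0("[^", substr(core, 2, nchar(core) - 1), "]")
          else core
    rep <- if (nzchar(m[4])) paste0("{", m[3], ",", m[4], "}?")
           else if (nzchar(m[3])) paste0("{", m[3], "}")
           else ""
    paste0(re, rep)
  }, character(1))
  list(re = paste(parts, collapse = ""), anchor_start = anchor_start,
       anchor_end = anchor_end)
}

prosite_oracle_starts <- function(pattern, seqstr) {
  o <- prosite_to_regex(pattern)
  n <- nchar(seqstr)
  starts <- if (o$anchor_start) 1L else seq_len(n)
  hits <- vapply(starts, function(s) {
    grepl(paste0("^", o$re, if (o$anchor_end) "$" else ""),
          substring(seqstr, s), perl = TRUE)
  }, logical(1))
  starts[hits] - 1L
}

# --- Hamming motif oracle -------------------------------------------------
hamming_oracle <- function(seqstr, motif, max_mm) {
  sc <- strsplit(seqstr, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  m <- length(mc); n <- length(sc)
  res <- data.frame(start = integer(), mismatch_count = integer())
  for (s in 0:(n - m)) {
    d <- sum(sc[(s + 1):(s + m)] != mc)
    if (d <= max_mm) res <- rbind(res, data.frame(start = s, mismatch_count = d))
  }
  res[order(res$mismatch_count, res$start), , drop = FALSE]
}

# --- hinge oracle: direct per-window evaluation of the consensus ----------
hinge_oracle_starts <- function(seqstr, window = 80, budget = 2) {
  allowed <- list(P17 = "E", P16 = c("E", "K", "R"), P15 = "G",
                  P14 = c("T", "S"), P13 = NULL, P12 = c("A", "G", "S"),
                  P11 = c("A", "G", "S"), P10 = c("A", "G", "S"),
                  P9 = c("A", "G", "S"))
  critical <- c(1, 3, 4, 6)
  chars <- strsplit(seqstr, "")[[1]]
  n <- length(chars)
  ok <- integer(0)
  for (pos in 0:(n - 21)) {
    if (pos < n - window) next
    crit_ok <- TRUE; noncrit_mm <- 0L
    for (k in 1:9) {
      if (is.null(allowed[[k]])) next
      hit <- chars[pos + k] %in% allowed[[k]]
      if (!hit) {
        if (k %in% critical) crit_ok <- FALSE else noncrit_mm <- noncrit_mm + 1L
      }
    }
    if (crit_ok && noncrit_mm <= budget) ok <- c(ok, pos)
  }
  ok
}

# --- exhaustive affine-gap global alignment (tiny sequences) --------------
brute_align_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= n) {
      cost <- if (last == "ga") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "ga"))
    }
    if (j <= m) {
      cost <- if (last == "gb") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# additive distances of a fixed 5-taxon tree, for NJ exactness checks
additive_5taxon <- function() {
  labs <- c("A", "B", "C", "D", "E")
  D <- matrix(0, 5, 5, dimnames = list(labs, labs))
  d <- function(i, j, v) { D[i, j] <<- v; D[j, i] <<- v }
  d("A", "B", 3); d("A", "C", 7); d("A", "D", 5); d("A", "E", 6)
  d("B", "C", 8); d("B", "D", 6); d("B", "E", 7)
  d("C", "D", 4); d("C", "E", 9); d("D", "E", 7)
  D
}
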