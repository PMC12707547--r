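#' Read a FASTA file into a record table
#'
#' Records are returned in file order as a data frame with one row per
#' sequence. Sequences are upper-cased and whitespace-stripped; the header is
#' split at the first space into `id` and `description`.
#'
#' @param path path to a FASTA file (wrapped or single-line sequences)
#' @param type `"dna"`, `"protein"` or `"auto"` (guess from residue content).
#'   Controls alphabet validation: DNA allows A/C/G/T/N, protein allows the 20
#'   standard residues plus X (and a terminal `*`).
#' @return data frame with columns `id`, `description`, `sequence`
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop2("malformed FASTA: expected '>' header at line ", nonblank[1])
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop2("duplicate record id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (type == "auto") {
    type <- if (all(grepl("^[ACGTN]*$", seqs))) "dna" else "protein"
  }
  allowed <- if (type == "dna") "^[ACGTN]*$" else "^[ARNDCQEGHILKMFPSTWYVX]*\\*?$"
  bad <- which(!grepl(allowed, seqs))
  if (length(bad) > 0) {
    i <- bad[1]
    chars <- setdiff(seq_chars(seqs[i]),
                     if (type == "dna") DNA_ALPHABET else c(AA_STANDARD, "X", "*"))
    # locate the first offending line for the diagnostic
    hdr_lines <- grep("^>", lines)
    from <- hdr_lines[i] + 1
    to <- if (i < length(hdr_lines)) hdr_lines[i + 1] - 1 else length(lines)
    ln <- from
    for (l in from:to) {
      if (grepl(paste0("[", paste(chars, collapse = ""), "]"),
                toupper(lines[l]), fixed = FALSE)) { ln <- l; break }
    }
    stop2("illegal ", type, " character(s) ", paste(chars, collapse = ","),
          " in record '", ids[i], "' at line ", ln)
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    stop2("empty sequence for record '", ids[empty[1]], "'")
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a record table to FASTA
#'
#' @param records data frame with columns `id`, `sequence` and optionally
#'   `description`
#' @param path output path
#' @param width line-wrap width for sequences
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate a DNA sequence with the standard genetic code
#'
#' Codons containing an ambiguous `N` translate to `X`; stop codons are
#' rendered `*`. A trailing partial codon is dropped with a warning. The codon
#' table is the standard nuclear code.
#'
#' @param nt DNA string (A/C/G/T/N)
#' @param include_stop keep a terminal `*`? Internal stops are always kept so
#'   the caller can detect them.
#' @return protein string
#' @export
translate_dna <- function(nt, include_stop = FALSE) {
  nt <- toupper(nt)
  if (!grepl("^[ACGTN]*$", nt)) {
    bad <- setdiff(seq_chars(nt), DNA_ALPHABET)
    stop2("illegal nucleotide(s): ", paste(unique(bad), collapse = ","))
  }
  n <- nchar(nt)
  if (n %% 3 != 0) {
    warning("sequence length not divisible by 3; trailing partial codon dropped")
    nt <- substr(nt, 1, n - n %% 3)
    n <- nchar(nt)
  }
  if (n == 0) return("")
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  prot <- paste(aa, collapse = "")
  if (!include_stop) prot <- sub("\\*$", "", prot)
  prot
}

reverse_complement <- function(nt) {
  paste(rev(seq_chars(chartr("ACGTN", "TGCAN", toupper(nt)))), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs in one frame string; returns codon-index spans
.orfs_in_frame <- function(codons, min_codons) {
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  out <- list()
  prev_stop <- 0L
  stops <- which(is_stop)
  for (s in stops) {
    if (s - 1L >= prev_stop + 1L) {
      cand <- which(is_atg[(prev_stop + 1L):(s - 1L)])
      if (length(cand) > 0) {
        a <- prev_stop + cand[1]
        if (s - a >= min_codons) {
          out[[length(out) + 1L]] <- list(a = a, s = s, partial3 = FALSE)
        }
      }
    }
    prev_stop <- s
  }
  n <- length(codons)
  if (prev_stop < n) {
    cand <- which(is_atg[(prev_stop + 1L):n])
    if (length(cand) > 0) {
      a <- prev_stop + cand[1]
      if (n - a + 1L >= min_codons) {
        out[[length(out) + 1L]] <- list(a = a, s = NA_integer_, partial3 = TRUE)
      }
    }
  }
  out
}

#' Find open reading frames in a transcript
#'
#' Scans all three reading frames of the forward strand (and, optionally, the
#' reverse complement) for maximal ATG-to-stop spans: within each
#' stop-delimited block of a frame, the ORF starts at the first ATG. ORFs
#' running off the 3' end without a stop are flagged `partial3`. Coordinates
#' are 0-based half-open on the forward strand of the input; for reverse-frame
#' ORFs they are mapped back through the reverse complement. The stop codon,
#' when present, is included in `[start, end)` but not in the protein.
#'
#' @param record one-row data frame (or list) with `id` and `sequence`
#' @param min_codons minimum protein length in codons (default 100; serpins
#'   run ~350-450 aa so this removes noise while keeping truncated fragments)
#' @param both_strands also scan frames -1/-2/-3?
#' @return data frame with columns `transcript_id`, `frame`, `start`, `end`,
#'   `partial3`, `length_aa`, `protein`, sorted by decreasing protein length,
#'   ties broken by frame (+1,+2,+3,-1,-2,-3) then start
#' @export
find_orfs <- function(record, min_codons = 100, both_strands = TRUE) {
  stopifnot(min_codons >= 1)
  id <- record$id
  S <- toupper(record$sequence)
  L <- nchar(S)
  frames <- if (both_strands) c(1, 2, 3, -1, -2, -3) else c(1, 2, 3)
  rows <- list()
  for (fr in frames) {
    src <- if (fr > 0) S else reverse_complement(S)
    off <- abs(fr) - 1L
    ncod <- (nchar(src) - off) %/% 3L
    if (ncod < 1) next
    codons <- substring(src, off + 3L * (seq_len(ncod) - 1L) + 1L,
                        off + 3L * seq_len(ncod))
    for (orf in .orfs_in_frame(codons, min_codons)) {
      a <- orf$a
      last_prot <- if (orf$partial3) length(codons) else orf$s - 1L
      prot <- {
        aa <- unname(Biostrings::GENETIC_CODE[codons[a:last_prot]])
        aa[is.na(aa)] <- "X"
        paste(aa, collapse = "")
      }
      st <- off + 3L * (a - 1L)
      en <- off + 3L * (if (orf$partial3) length(codons) else orf$s)
      if (fr < 0) { tmp <- st; st <- L - en; en <- L - tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, frame = fr, start = st, end = en,
        partial3 = orf$partial3, length_aa = nchar(prot), protein = prot,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(), frame = integer(),
                      start = integer(), end = integer(), partial3 = logical(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  frame_rank <- match(out$frame, c(1, 2, 3, -1, -2, -3))
  out <- out[order(-out$length_aa, frame_rank, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Longest ORF per transcript, as a protein record table
#'
#' @param transcripts data frame of nucleotide records
#' @inheritParams find_orfs
#' @return data frame of protein records (`id`, `description`, `sequence`)
#'   with the parent transcript, frame and span recorded in the description
#' @export
predict_proteins <- function(transcripts, min_codons = 100, both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    orfs <- find_orfs(transcripts[i, ], min_codons = min_codons,
                      both_strands = both_strands)
    if (nrow(orfs) == 0) return(NULL)
    top <- orfs[1, ]
    data.frame(
      id = top$transcript_id,
      description = sprintf("frame=%+d span=%d-%d%s", top$frame,
                            top$start + 1L, top$end,
                            if (top$partial3) " partial3" else ""),
      sequence = top$protein, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
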