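#' Hinge-region constraint pattern for the serpin reactive center loop
#'
#' Encodes the per-subsite allowed residues of the RCL hinge consensus,
#' P17 \[E\] - P16 \[E/K/R\] - P15 \[G\] - P14 \[T/S\] - P13 \[X\] -
#' P12..P9 \[A/G/S\], with P8..P1 and P1'..P4' unconstrained. Subsites whose
#' conservation is required for inhibitory loop insertion (P17, P15, P14,
#' P12) are critical and must match; the remaining constrained subsites
#' (P16, P11, P10, P9) may mismatch up to `max_noncritical_mismatches` in
#' total, since natural inhibitory serpins are known to deviate there.
#'
#' @param max_noncritical_mismatches mismatch budget over non-critical
#'   constrained subsites (default 2)
#' @return object of class `hinge_pattern`
#' @export
hinge_pattern <- function(max_noncritical_mismatches = 2) {
  subsites <- c("P17", "P16", "P15", "P14", "P13", "P12", "P11", "P10", "P9")
  allowed <- list(
    P17 = "E", P16 = c("E", "K", "R"), P15 = "G", P14 = c("T", "S"),
    P13 = AA_STANDARD,
    P12 = c("A", "G", "S"), P11 = c("A", "G", "S"),
    P10 = c("A", "G", "S"), P9 = c("A", "G", "S"))
  critical <- c(P17 = TRUE, P16 = FALSE, P15 = TRUE, P14 = TRUE, P13 = FALSE,
                P12 = TRUE, P11 = FALSE, P10 = FALSE, P9 = FALSE)
  # P13 is a wildcard: constrained set is everything, never a mismatch
  constrained <- subsites[subsites != "P13"]
  structure(list(subsites = subsites, allowed = allowed, critical = critical,
                 constrained = constrained,
                 max_noncritical_mismatches = max_noncritical_mismatches),
            class = "hinge_pattern")
}

# evaluate the hinge constraints at 0-based position `pos` (P17 index);
# returns list(ok, score, mismatched) where score counts matched constrained
# subsites (max 8)
.hinge_eval <- function(chars, pattern, pos) {
  mismatched <- character(0)
  score <- 0L
  for (k in seq_along(pattern$subsites)) {
    ss <- pattern$subsites[k]
    if (ss == "P13") next
    res <- chars[pos + k]
    hit <- res %in% pattern$allowed[[ss]]
    if (hit) score <- score + 1L else mismatched <- c(mismatched, ss)
  }
  crit_fail <- mismatched[pattern$critical[mismatched]]
  ok <- length(crit_fail) == 0 &&
    (length(mismatched) - length(crit_fail)) <= pattern$max_noncritical_mismatches
  list(ok = ok, score = score, mismatched = mismatched)
}

#' Scan the C-terminal region of a protein for RCL hinge candidates
#'
#' Only the last `window` residues are scanned (the RCL sits near the
#' C-terminus); a candidate position must satisfy all critical subsites, stay
#' within the non-critical mismatch budget, and leave at least 21 residues
#' from P17 to the sequence end so a full P17-P4' loop can be extracted.
#'
#' @param protein protein record or sequence string
#' @param pattern a [hinge_pattern()]
#' @param window number of C-terminal residues to scan (default 80)
#' @return data frame of candidates with 0-based `hinge_start`, `score`
#'   (matched constrained subsites, of 8) and `mismatched` subsites
#'   (comma-separated), ranked by score descending then position descending
#'   (most C-terminal first among ties)
#' @export
scan_hinge <- function(protein, pattern = hinge_pattern(), window = 80) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  chars <- seq_chars(toupper(seqstr))
  n <- length(chars)
  if (n < 21) return(data.frame(hinge_start = integer(), score = integer(),
                                mismatched = character(), stringsAsFactors = FALSE))
  lo <- max(0L, n - as.integer(window))       # first scannable P17 (0-based)
  hi <- n - 21L                               # need 21 residues from P17
  if (hi < lo) return(data.frame(hinge_start = integer(), score = integer(),
                                 mismatched = character(), stringsAsFactors = FALSE))
  rows <- list()
  for (pos in lo:hi) {
    ev <- .hinge_eval(chars, pattern, pos)
    if (ev$ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        hinge_start = pos, score = ev$score,
        mismatched = paste(ev$mismatched, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(hinge_start = integer(), score = integer(),
                      mismatched = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, -out$hinge_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

P1_CLASSES <- list(
  "polar basic" = c("K", "R", "H"),
  "polar uncharged" = c("S", "T", "C", "Y", "N", "Q"),
  "polar acidic" = c("D", "E"),
  # G and P are grouped with the hydrophobics so the table is total
  "hydrophobic" = c("A", "V", "I", "L", "M", "F", "W", "P", "G"))

P1_TARGETS <- c(
  "polar basic" = "Trypsin- or thrombin-like proteases",
  "polar uncharged" = "Elastase- or chymotrypsin-like proteases",
  "polar acidic" = "Not specified",
  "hydrophobic" = "Not specified")

#' Classify a P1 residue and predict the target protease family
#'
#' The chemistry class of the residue at the scissile P1 position is the main
#' determinant of which protease family a serpin inhibits: basic P1 residues
#' point to trypsin/thrombin-like targets, polar uncharged ones to
#' elastase/chymotrypsin-like targets.
#'
#' @param residue one-letter amino acid code (standard residues only)
#' @return list with `p1_class` and `predicted_target`
#' @export
classify_p1 <- function(residue) {
  residue <- toupper(residue)
  if (!(residue %in% AA_STANDARD)) {
    stop2("non-standard P1 residue: '", residue, "'")
  }
  cls <- names(P1_CLASSES)[vapply(P1_CLASSES, function(s) residue %in% s,
                                  logical(1))]
  list(p1_class = cls, predicted_target = unname(P1_TARGETS[cls]))
}

#' Extract the 21-residue P17-P4' reactive center loop
#'
#' Given the hinge start (the P17 position), takes the 21-residue window
#' P17..P1, P1'..P4'. The scissile P1 sits 17 residues into the loop counting
#' P17 as the first, i.e. at offset 16 from the hinge start.
#'
#' @param protein protein record or sequence string
#' @param hinge_start 0-based index of P17
#' @return object of class `rcl_annotation`: `hinge_start`, `rcl_seq` (21
#'   residues), `p1_index` (0-based), `p1_residue`, `p1_class`,
#'   `predicted_target`
#' @export
extract_rcl <- function(protein, hinge_start) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  n <- nchar(seqstr)
  if (hinge_start + 21 > n) {
    stop2("fewer than 21 residues remain from the hinge start (position ",
          hinge_start, ", length ", n, "); sequence is C-terminally truncated",
          class = "rcl_extraction_error")
  }
  rcl_seq <- substr(seqstr, hinge_start + 1, hinge_start + 21)
  p1_index <- hinge_start + 16L
  p1_residue <- substr(rcl_seq, 17, 17)
  cls <- classify_p1(p1_residue)
  structure(list(hinge_start = as.integer(hinge_start), rcl_seq = rcl_seq,
                 p1_index = p1_index, p1_residue = p1_residue,
                 p1_class = cls$p1_class,
                 predicted_target = cls$predicted_target),
            class = "rcl_annotation")
}

#' Summarise P1 chemistry across a set of RCL annotations
#'
#' @param annotations list of `rcl_annotation` objects (or a character vector
#'   of P1 residues)
#' @return list with `n`, `counts` and `percentages` (named by class,
#'   round-half-up to 2 decimals) and `distinct_residues`
#' @export
p1_summary <- function(annotations) {
  residues <- if (is.character(annotations)) annotations
              else vapply(annotations, function(a) a$p1_residue, character(1))
  if (length(residues) == 0) stop2("no annotations to summarise")
  cls <- vapply(residues, function(r) classify_p1(r)$p1_class, character(1))
  counts <- vapply(names(P1_CLASSES), function(k) sum(cls == k), integer(1))
  pct <- round_half_up(100 * counts / length(residues), 2)
  list(n = length(residues), counts = counts, percentages = pct,
       distinct_residues = length(unique(toupper(residues))))
}

SUBSITE_LABELS <- c(paste0("P", 17:1), paste0("P", 1:4, "'"))

#' Per-subsite conservation of aligned RCLs
#'
#' @param annotations list of `rcl_annotation` objects or character vector of
#'   21-residue loops
#' @param pattern the [hinge_pattern()] whose constraints define conservation
#' @return data frame, one row per subsite P17..P4', with the residue
#'   frequency table (`freqs`, a list column of named numeric vectors), the
#'   modal residue, and `conserved`: for hinge-constrained subsites, whether
#'   every observed residue satisfies the consensus constraint; for
#'   unconstrained subsites, whether a single residue is observed
#' @export
hinge_conservation_report <- function(annotations, pattern = hinge_pattern()) {
  loops <- if (is.character(annotations)) annotations
           else vapply(annotations, function(a) a$rcl_seq, character(1))
  if (length(loops) == 0) stop2("no annotations")
  if (any(nchar(loops) != 21)) stop2("all RCLs must be 21 residues")
  mat <- do.call(rbind, strsplit(loops, ""))
  rows <- lapply(seq_len(21), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    freqs <- as.numeric(tab) / length(loops)
    names(freqs) <- names(tab)
    ss <- SUBSITE_LABELS[j]
    conserved <- if (ss %in% pattern$constrained) {
      all(names(freqs) %in% pattern$allowed[[ss]])
    } else {
      length(freqs) == 1
    }
    data.frame(subsite = ss, modal_residue = names(freqs)[1],
               modal_freq = unname(freqs[1]), conserved = conserved,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$freqs <- lapply(seq_len(21), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    stats::setNames(as.numeric(tab) / length(loops), names(tab))
  })
  rownames(out) <- NULL
  out
}

#' Information-content-weighted frequency matrix for a sequence logo
#'
#' For each of the 21 RCL columns the information content is
#' `IC = log2(20) - H`, with `H` the Shannon entropy (bits) of the observed
#' residue frequencies; each cell holds `frequency * IC`, the stack height a
#' logo would draw for that residue. No small-sample correction is applied.
#'
#' @param annotations list of `rcl_annotation` objects or character vector of
#'   equal-length loops (>= 2)
#' @return numeric matrix, positions x 20 standard residues
#' @export
logo_matrix <- function(annotations) {
  loops <- if (is.character(annotations)) annotations
           else vapply(annotations, function(a) a$rcl_seq, character(1))
  if (length(loops) < 2) stop2("need at least 2 sequences for a logo")
  if (length(unique(nchar(loops))) != 1) stop2("unequal sequence lengths")
  width <- nchar(loops[1])
  mat <- do.call(rbind, strsplit(loops, ""))
  out <- matrix(0, nrow = width, ncol = length(AA_STANDARD),
                dimnames = list(
                  if (width == 21) SUBSITE_LABELS else paste0("pos", seq_len(width)),
                  AA_STANDARD))
  for (j in seq_len(width)) {
    freqs <- table(factor(mat[, j], levels = AA_STANDARD)) / length(loops)
    f <- as.numeric(freqs)
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic <- log2(20) - h
    out[j, ] <- f * ic
  }
  out
}
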