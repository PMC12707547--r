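# Average (isotope-abundance-weighted) residue masses in Da, as used by the
# Expasy ProtParam tool; a free chain adds one water.
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.01524 Da), reported to
#' two decimals. Ambiguous residues (X) are disallowed: a mass cannot be
#' assigned.
#'
#' @param protein protein record or sequence string of standard residues
#' @return molecular weight in Da
#' @export
molecular_weight <- function(protein) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  seqstr <- toupper(seqstr)
  if (!nzchar(seqstr)) stop2("empty sequence has no molecular weight")
  chars <- seq_chars(seqstr)
  if (!all(chars %in% names(AA_MASS))) {
    stop2("non-standard residue(s): ",
          paste(unique(setdiff(chars, names(AA_MASS))), collapse = ","))
  }
  round(sum(AA_MASS[chars]) + WATER_MASS, 2)
}

#' Potential N-glycosylation sequons
#'
#' Reports every N-X-S/T sequon with X != P, the necessary (not sufficient)
#' condition for N-linked glycosylation. These are sequon sites, not
#' occupancy predictions.
#'
#' @param protein protein record or sequence string
#' @return integer vector of 1-based positions of the sequon N
#' @export
find_nglyc <- function(protein) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  chars <- seq_chars(toupper(seqstr))
  n <- length(chars)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  which(chars[i] == "N" & chars[i + 1] != "P" &
          chars[i + 2] %in% c("S", "T"))
}

#' Ingest external predictor annotations (signal peptide, O-glycosylation)
#'
#' Signal peptides and O-glycosylation calls come from third-party neural
#' predictors and are ingested from a TSV rather than computed. Expected
#' columns: `id`, `sp_present` (SP/NSP), `sp_length`, `oglyc_positions`
#' (semicolon-separated 1-based positions; may be empty).
#'
#' @param path TSV file path
#' @return named list keyed by id; each element has `sp_present` (logical),
#'   `sp_length` (integer or NA) and `oglyc` (integer vector)
#' @export
ingest_external_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  start <- 1L
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (identical(first[1], "id")) start <- 2L
  out <- list()
  for (ln in seq(start, length.out = length(lines) - start + 1L)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    length(f) <- 4L
    f[is.na(f)] <- ""
    if (!nzchar(f[1]) || !(f[2] %in% c("SP", "NSP"))) {
      stop2("malformed annotation row at line ", ln,
            ": expected id<TAB>SP|NSP<TAB>sp_length<TAB>oglyc_positions")
    }
    sp <- f[2] == "SP"
    sp_len <- if (sp) {
      v <- suppressWarnings(as.integer(f[3]))
      if (is.na(v)) stop2("malformed sp_length at line ", ln)
      v
    } else NA_integer_
    oglyc <- if (nzchar(f[4])) {
      v <- suppressWarnings(as.integer(strsplit(f[4], ";", fixed = TRUE)[[1]]))
      if (anyNA(v)) stop2("malformed oglyc_positions at line ", ln)
      v
    } else integer(0)
    if (f[1] %in% names(out)) stop2("duplicate annotation id at line ", ln)
    out[[f[1]]] <- list(sp_present = sp, sp_length = sp_len, oglyc = oglyc)
  }
  out
}

#' Write external annotations in the ingestible TSV layout
#'
#' @param annotations list as returned by [ingest_external_annotations()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_external_annotations <- function(annotations, path) {
  rows <- vapply(names(annotations), function(id) {
    a <- annotations[[id]]
    paste(id, if (a$sp_present) "SP" else "NSP",
          if (a$sp_present) a$sp_length else "",
          paste(a$oglyc, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c("id\tsp_present\tsp_length\toglyc_positions", rows), path)
  invisible(path)
}
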