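#' Specification for the synthetic serpin generator
#'
#' Captures every knob of the generator: how many sequences, how many carry
#' the complete serpin architecture (initiator Met, N-terminal NAVYFKG,
#' serpin signature, hinge-conforming 21-residue RCL near the C-terminus),
#' which P1 residues are planted, the two-sex expression structure, and the
#' count model. Everything is reproducible from `seed`.
#'
#' @param n_total total number of transcripts/sequences
#' @param n_full_length how many carry the full planted architecture
#' @param sex_counts named vector `c(female_only=, male_only=, shared=)`
#'   summing to `n_total`
#' @param p1_residues optional explicit vector of P1 residues (length
#'   `n_full_length`); overrides `p1_distribution`
#' @param p1_distribution named probability vector over P1 residues (default
#'   uniform over the eight residues seen in tick serpin loops)
#' @param length_range full-length protein length range (default 350-450 aa)
#' @param tail_range residues retained downstream of the 21-residue RCL
#'   (default 10-40, placing the loop near the C-terminus)
#' @param signal_fraction fraction of full-length sequences marked as
#'   carrying a signal peptide in the emitted external-annotation table
#' @param nb_mean,nb_dispersion negative-binomial count model for expressed
#'   cells (mean 200, dispersion 0.5: over-dispersed, RNA-seq-like)
#' @param seed integer RNG seed
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_total = 110, n_full_length = 17,
                           sex_counts = c(female_only = 4, male_only = 15,
                                          shared = 91),
                           p1_residues = NULL,
                           p1_distribution = NULL,
                           length_range = c(350, 450),
                           tail_range = c(10, 40),
                           signal_fraction = 0.35,
                           nb_mean = 200, nb_dispersion = 0.5,
                           seed = 7) {
  if (is.null(p1_distribution)) {
    p1_distribution <- stats::setNames(
      rep(1 / 8, 8), c("K", "R", "C", "S", "T", "Y", "I", "L"))
  }
  stopifnot(n_full_length <= n_total,
            sum(sex_counts) == n_total,
            abs(sum(p1_distribution) - 1) < 1e-8,
            length_range[1] >= 100, length_range[2] >= length_range[1])
  if (!is.null(p1_residues)) stopifnot(length(p1_residues) == n_full_length)
  if (length_range[1] < 21 + tail_range[2] + 40) {
    stop2("length range too small to host the planted motifs and loop")
  }
  structure(list(n_total = n_total, n_full_length = n_full_length,
                 sex_counts = sex_counts, p1_residues = p1_residues,
                 p1_distribution = p1_distribution,
                 length_range = length_range, tail_range = tail_range,
                 signal_fraction = signal_fraction, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, seed = seed),
            class = "synthetic_spec")
}

#' Named generator presets
#'
#' The `"paper"` preset mirrors the structure of the *H. dromedarii*
#' sialotranscriptome serpin set: 110 transcripts, 17 of them full-length,
#' a 4/15/91 female-only/male-only/shared expression partition, and the 17
#' P1 residues of the published full-length serpins planted in id order.
#'
#' @param name preset name (currently `"paper"`)
#' @param seed RNG seed
#' @return a [synthetic_spec()]
#' @export
synth_preset <- function(name = "paper", seed = 7) {
  if (name != "paper") stop2("unknown preset '", name, "'")
  synthetic_spec(
    n_total = 110, n_full_length = 17,
    sex_counts = c(female_only = 4, male_only = 15, shared = 91),
    p1_residues = c("K", "C", "C", "K", "K", "C", "R", "I", "L", "S", "R",
                    "R", "Y", "Y", "T", "R", "K"),
    seed = seed)
}

.rand_aa <- function(n) sample(AA_STANDARD, n, replace = TRUE)

# draw one residue per element of a fixed-length PROSITE pattern
.sample_signature <- function(matcher) {
  vapply(matcher$elements, function(el) {
    pool <- intersect(el$allowed, AA_STANDARD)
    sample(pool, 1)
  }, character(1))
}

.sample_rcl <- function(p1) {
  c("E", sample(c("E", "K", "R"), 1), "G", sample(c("T", "S"), 1),
    .rand_aa(1), sample(c("A", "G", "S"), 4, replace = TRUE),
    .rand_aa(7), p1, .rand_aa(4))
}

# one full-length scaffold; returns chars and the planted 0-based hinge start
.build_full <- function(spec, p1, matcher, hp) {
  for (try in 1:200) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1)
    tail_len <- sample(spec$tail_range[1]:spec$tail_range[2], 1)
    hinge0 <- len - 21L - tail_len
    chars <- .rand_aa(len)
    chars[1] <- "M"
    m0 <- sample(10:(len %/% 3 - 7), 1)                 # NAVYFKG, N-term third
    chars[(m0 + 1):(m0 + 7)] <- seq_chars("NAVYFKG")
    sig <- .sample_signature(matcher)
    s0 <- sample((m0 + 12):(hinge0 - length(sig) - 5), 1)
    chars[(s0 + 1):(s0 + length(sig))] <- sig
    chars[(hinge0 + 1):(hinge0 + 21)] <- .sample_rcl(p1)
    seqstr <- paste(chars, collapse = "")
    cand <- scan_hinge(seqstr, hp, 80)
    if (nrow(cand) > 0 && cand$hinge_start[1] == hinge0) {
      return(list(chars = chars, hinge0 = hinge0))
    }
  }
  stop2("could not build a scaffold whose planted hinge is the top candidate")
}

# truncate a full scaffold upstream of its hinge so no hinge candidate remains
.build_partial <- function(spec, matcher, hp) {
  for (try in 1:200) {
    full <- .build_full(spec, sample(names(spec$p1_distribution), 1,
                                     prob = spec$p1_distribution), matcher, hp)
    cut <- sample(60:full$hinge0, 1)
    seqstr <- paste(full$chars[1:cut], collapse = "")
    if (nrow(scan_hinge(seqstr, hp, 80)) == 0) return(seqstr)
  }
  stop2("could not build a hinge-free truncated sequence")
}

.CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

.back_translate <- function(protein) {
  aa <- seq_chars(protein)
  paste(vapply(aa, function(r) {
    pool <- .CODONS_BY_AA[[r]]
    pool[sample.int(length(pool), 1)]
  }, character(1)), collapse = "")
}

.random_utr <- function(n, forbid_atg = FALSE) {
  repeat {
    u <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!forbid_atg || !grepl("ATG", u, fixed = TRUE)) return(u)
  }
}

#' Generate synthetic serpin sequences with a ground-truth table
#'
#' Emits protein records, exact back-translated nucleotide records (25-nt
#' UTRs, in-frame TAA stop, no ATG in the 5' UTR so the planted ORF is the
#' longest), an external-annotation table for the signal-peptide fraction,
#' and a truth table recording the planted structure of every sequence.
#' Full-length sequences carry the complete architecture; partial sequences
#' are the same scaffolds truncated uniformly upstream of the hinge, so they
#' lack any RCL. Scaffolds are rejection-sampled so that the planted hinge is
#' the unique top-ranked candidate (full) or no candidate survives (partial),
#' making recovery of the planted structure exact by construction.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `proteins`, `transcripts` (record tables), `truth`
#'   (data frame: id, completeness, hinge_start, rcl_seq, p1_residue,
#'   p1_class, length_aa, sp_present) and `annotations` (external-annotation
#'   list for [write_external_annotations()])
#' @export
generate_serpins <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  matcher <- compile_prosite(serpin_signature_pattern())
  hp <- hinge_pattern()
  withr::with_seed(spec$seed, {
    ids <- sprintf("HDS%03d", seq_len(spec$n_total))
    full_ids <- sort(sample(ids, spec$n_full_length))
    p1s <- if (!is.null(spec$p1_residues)) spec$p1_residues
           else sample(names(spec$p1_distribution), spec$n_full_length,
                       replace = TRUE, prob = spec$p1_distribution)
    seqs <- character(spec$n_total)
    names(seqs) <- ids
    truth <- data.frame(id = ids, completeness = "partial",
                        hinge_start = NA_integer_, rcl_seq = NA_character_,
                        p1_residue = NA_character_, p1_class = NA_character_,
                        length_aa = NA_integer_, sp_present = FALSE,
                        stringsAsFactors = FALSE)
    seen_rcl <- character(0)
    for (k in seq_along(full_ids)) {
      repeat {
        built <- .build_full(spec, p1s[k], matcher, hp)
        rcl <- paste(built$chars[(built$hinge0 + 1):(built$hinge0 + 21)],
                     collapse = "")
        if (!(rcl %in% seen_rcl)) break
      }
      seen_rcl <- c(seen_rcl, rcl)
      id <- full_ids[k]
      seqs[id] <- paste(built$chars, collapse = "")
      i <- match(id, ids)
      truth$completeness[i] <- "full"
      truth$hinge_start[i] <- built$hinge0
      truth$rcl_seq[i] <- rcl
      truth$p1_residue[i] <- p1s[k]
      truth$p1_class[i] <- classify_p1(p1s[k])$p1_class
    }
    for (id in setdiff(ids, full_ids)) {
      seqs[id] <- .build_partial(spec, matcher, hp)
    }
    truth$length_aa <- nchar(seqs)
    n_sp <- round(spec$signal_fraction * spec$n_full_length)
    sp_ids <- sort(sample(full_ids, n_sp))
    truth$sp_present <- truth$id %in% sp_ids
    annotations <- stats::setNames(lapply(ids, function(id) {
      list(sp_present = id %in% sp_ids,
           sp_length = if (id %in% sp_ids) sample(16:30, 1) else NA_integer_,
           oglyc = integer(0))
    }), ids)
    transcripts <- data.frame(
      id = ids, description = "synthetic transcript",
      sequence = vapply(ids, function(id) {
        paste0(.random_utr(25, forbid_atg = TRUE),
               .back_translate(seqs[[id]]), "TAA", .random_utr(25))
      }, character(1)),
      stringsAsFactors = FALSE)
    proteins <- data.frame(id = ids, description = "synthetic protein",
                           sequence = unname(seqs), stringsAsFactors = FALSE)
    list(proteins = proteins, transcripts = transcripts, truth = truth,
         annotations = annotations)
  })
}

#' Generate a two-sex expression table with known partition structure
#'
#' Counts for expressed transcript/sex pairs are negative-binomial; the
#' non-expressed sex gets exact zeros, so the zero-TPM rule recovers the
#' planted partition exactly. Two samples per sex (F1/F2, M1/M2); at least
#' one positive count per expressed sex is enforced.
#'
#' @param spec a [synthetic_spec()]
#' @param lengths optional named vector of effective transcript lengths (nt);
#'   defaults to random lengths in 900-1500
#' @return list with `counts` (data frame: transcript_id, length, F1, F2,
#'   M1, M2), `sex_map`, and `truth` (id sets `female_only`, `male_only`,
#'   `shared`)
#' @export
generate_expression <- function(spec, lengths = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed + 1L, {
    ids <- sprintf("HDS%03d", seq_len(spec$n_total))
    shuffled <- sample(ids)
    fo <- spec$sex_counts[["female_only"]]
    mo <- spec$sex_counts[["male_only"]]
    female_only <- sort(shuffled[seq_len(fo)])
    male_only <- sort(shuffled[fo + seq_len(mo)])
    shared <- sort(shuffled[-(seq_len(fo + mo))])
    if (is.null(lengths)) {
      lengths <- stats::setNames(sample(900:1500, spec$n_total, replace = TRUE),
                                 ids)
    }
    size <- 1 / spec$nb_dispersion
    draw <- function() {
      v <- stats::rnbinom(2, mu = spec$nb_mean, size = size)
      if (all(v == 0)) v[1] <- 1L
      v
    }
    counts <- data.frame(transcript_id = ids, length = unname(lengths[ids]),
                         F1 = 0L, F2 = 0L, M1 = 0L, M2 = 0L,
                         stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (id %in% c(female_only, shared)) counts[i, c("F1", "F2")] <- draw()
      if (id %in% c(male_only, shared)) counts[i, c("M1", "M2")] <- draw()
    }
    sex_map <- data.frame(sample = c("F1", "F2", "M1", "M2"),
                          sex = c("female", "female", "male", "male"),
                          stringsAsFactors = FALSE)
    list(counts = counts, sex_map = sex_map,
         truth = list(female_only = female_only, male_only = male_only,
                      shared = shared))
  })
}
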