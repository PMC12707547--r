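#' Default screening configuration
#'
#' Bundles the tunable screening parameters: the serpin signature pattern
#' (PROSITE syntax, shipped with the package but replaceable), the N-terminal
#' consensus motif with its mismatch tolerance, the full-length length range
#' and the hinge-scan settings. Values can be overridden individually or read
#' from a YAML file with [read_config()].
#'
#' @param ... named overrides of the defaults
#' @return named list of configuration values
#' @export
serpin_config <- function(...) {
  cfg <- list(
    prosite_pattern = serpin_signature_pattern(),
    nterm_motif = "NAVYFKG",
    nterm_max_mismatches = 2,
    full_length_min = 350,
    full_length_max = 450,
    hinge_max_noncritical_mismatches = 2,
    hinge_scan_window = 80,
    orf_min_codons = 100)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop2("unknown config key(s): ",
                                 paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a screening configuration from YAML
#'
#' @param path YAML file; keys as in [serpin_config()]
#' @return configuration list with unspecified keys at their defaults
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(serpin_config, vals)
}

#' Full-length versus partial classification of a candidate serpin
#'
#' A sequence is called `full` when all four criteria pass: it begins with an
#' initiator methionine, its length falls in the configured range (350-450 aa
#' by default), an RCL could be annotated, and that RCL is unique within the
#' run. Anything else is `partial`, with the failed criteria recorded.
#' Sequences lacking an RCL are additionally tagged as C-terminally
#' truncated.
#'
#' @param protein protein record or sequence string
#' @param rcl an `rcl_annotation` or `NULL` when no hinge was found
#' @param config a [serpin_config()]
#' @param rcl_is_unique is this sequence the representative of its RCL string
#'   within the run? (Identical loops collapse to one full-length
#'   representative; see [screen_serpins()].)
#' @return list with `status` ("full"/"partial"), logical `reasons`
#'   (`has_start_met`, `length_in_range`, `has_rcl`, `rcl_unique`) and
#'   `tags`
#' @export
classify_completeness <- function(protein, rcl, config = serpin_config(),
                                  rcl_is_unique = TRUE) {
  seqstr <- if (is.character(protein)) protein else protein$sequence
  reasons <- c(
    has_start_met = startsWith(seqstr, "M"),
    length_in_range = nchar(seqstr) >= config$full_length_min &&
      nchar(seqstr) <= config$full_length_max,
    has_rcl = !is.null(rcl),
    rcl_unique = !is.null(rcl) && rcl_is_unique)
  tags <- character(0)
  if (!reasons[["has_rcl"]]) tags <- c(tags, "truncated C-terminus")
  if (reasons[["has_start_met"]] && reasons[["has_rcl"]] &&
      reasons[["rcl_unique"]] && !reasons[["length_in_range"]]) {
    tags <- c(tags, "length outside configured range")
  }
  list(status = if (all(reasons)) "full" else "partial",
       reasons = reasons, tags = tags)
}

#' Screen a protein set for serpins and annotate their RCLs
#'
#' Runs the whole per-sequence screen: serpin signature match, N-terminal
#' NAVYFKG motif search (Hamming-tolerant, restricted to the N-terminal
#' half), C-terminal hinge scan with RCL extraction and P1 classification,
#' then the run-level full/partial call. Identical 21-mer RCL strings
#' collapse to a single full-length representative: the one with the highest
#' summed TPM when `tpm_sums` is given, ties (and the no-TPM case) broken by
#' lexicographic id.
#'
#' @param proteins protein record table (`id`, `sequence`)
#' @param config a [serpin_config()]
#' @param tpm_sums optional named numeric vector of per-transcript summed TPM
#'   used for duplicate-RCL tie-breaking
#' @return data frame, one row per input protein: motif/signature evidence,
#'   hinge and RCL columns, `status`, per-criterion logicals and `tags`
#' @export
screen_serpins <- function(proteins, config = serpin_config(), tpm_sums = NULL) {
  stopifnot(nrow(proteins) >= 1)
  matcher <- compile_prosite(config$prosite_pattern)
  hp <- hinge_pattern(config$hinge_max_noncritical_mismatches)
  n <- nrow(proteins)
  rcls <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- proteins[i, ]
    sig <- prosite_match(matcher, p$sequence)
    half <- substr(p$sequence, 1, max(nchar(config$nterm_motif),
                                      nchar(p$sequence) %/% 2))
    nm <- if (nchar(half) >= nchar(config$nterm_motif)) {
      find_motif(half, config$nterm_motif, config$nterm_max_mismatches)
    } else {
      data.frame(start = integer(), mismatch_count = integer())
    }
    cand <- scan_hinge(p$sequence, hp, config$hinge_scan_window)
    rcl <- if (nrow(cand) > 0) {
      # an X at P1 (non-standard residue) voids the annotation
      tryCatch(extract_rcl(p$sequence, cand$hinge_start[1]),
               error = function(e) NULL)
    } else NULL
    rcls[i] <- list(rcl)
    rows[[i]] <- data.frame(
      id = p$id, length_aa = nchar(p$sequence),
      signature_match = nrow(sig) > 0,
      signature_start = if (nrow(sig) > 0) sig$start[1] else NA_integer_,
      nterm_motif_match = nrow(nm) > 0,
      nterm_motif_mismatches = if (nrow(nm) > 0) nm$mismatch_count[1] else NA_integer_,
      hinge_start = if (!is.null(rcl)) rcl$hinge_start else NA_integer_,
      rcl_seq = if (!is.null(rcl)) rcl$rcl_seq else NA_character_,
      p1_index = if (!is.null(rcl)) rcl$p1_index else NA_integer_,
      p1_residue = if (!is.null(rcl)) rcl$p1_residue else NA_character_,
      p1_class = if (!is.null(rcl)) rcl$p1_class else NA_character_,
      predicted_target = if (!is.null(rcl)) rcl$predicted_target else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  # representative selection among identical RCL strings
  is_unique <- rep(TRUE, n)
  with_rcl <- which(!is.na(out$rcl_seq))
  for (loop in unique(out$rcl_seq[with_rcl])) {
    grp <- with_rcl[out$rcl_seq[with_rcl] == loop]
    if (length(grp) <= 1) next
    tpm <- if (is.null(tpm_sums)) rep(0, length(grp))
           else ifelse(out$id[grp] %in% names(tpm_sums),
                       tpm_sums[out$id[grp]], 0)
    rep_idx <- grp[order(-tpm, out$id[grp])][1]
    is_unique[setdiff(grp, rep_idx)] <- FALSE
  }

  calls <- lapply(seq_len(n), function(i) {
    classify_completeness(proteins[i, ], rcls[[i]], config, is_unique[i])
  })
  out$status <- vapply(calls, `[[`, character(1), "status")
  rs <- do.call(rbind, lapply(calls, function(cc) as.data.frame(t(cc$reasons))))
  out <- cbind(out, rs)
  out$tags <- vapply(calls, function(cc) paste(cc$tags, collapse = "; "),
                     character(1))
  rownames(out) <- NULL
  out
}
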