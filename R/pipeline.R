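.log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[%s] %d record(s) in, %d out", stage, n_in, n_out))
}

#' Run the whole serpin annotation pipeline
#'
#' Orchestrates the stages in order: ORF prediction (when transcripts are
#' given), serpin screening with RCL annotation and full/partial calls,
#' sequence-derived features, expression metrics with the zero-TPM sex
#' partition, and -- over the full-length set -- the pairwise comparison
#' matrices, a midpoint-rooted neighbor-joining tree and the RCL logo
#' matrix. Writes the report bundle to `out_dir`: `serpin_table.tsv` (one
#' row per sequence), `summary.json`, `pairwise_identity.tsv` /
#' `pairwise_similarity.tsv` / `pairwise_coverage.tsv`, `tree.nwk`,
#' `logo_matrix.tsv`.
#'
#' @param proteins_fasta protein FASTA path (used directly), or `NULL` to
#'   predict proteins from `transcripts_fasta`
#' @param transcripts_fasta nucleotide FASTA path (optional when
#'   `proteins_fasta` is given)
#' @param counts_tsv counts TSV path (optional; enables expression stages)
#' @param sex_map_tsv TSV with columns `sample`, `sex` (required with
#'   `counts_tsv`)
#' @param annotations_tsv optional external-annotation TSV (signal peptide,
#'   O-glycosylation)
#' @param out_dir output directory, created if needed
#' @param config a [serpin_config()]
#' @return (invisibly) list with the screen table, feature columns,
#'   partition, matrices, tree and summary
#' @export
run_pipeline <- function(proteins_fasta = NULL, transcripts_fasta = NULL,
                         counts_tsv = NULL, sex_map_tsv = NULL,
                         annotations_tsv = NULL, out_dir = ".",
                         config = serpin_config()) {
  if (is.null(proteins_fasta) && is.null(transcripts_fasta)) {
    stop2("need a protein or transcript FASTA")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(proteins_fasta)) {
    proteins <- read_fasta(proteins_fasta, type = "protein")
    .log_stage("input", nrow(proteins), nrow(proteins))
  } else {
    transcripts <- read_fasta(transcripts_fasta, type = "dna")
    proteins <- predict_proteins(transcripts,
                                 min_codons = config$orf_min_codons)
    .log_stage("orfs", nrow(transcripts), nrow(proteins))
  }
  if (nrow(proteins) == 0) {
    stop2("no input sequences; nothing to screen",
          class = "serpinscope_empty_input")
  }

  tpm <- NULL; partition <- NULL; tpm_sums <- NULL
  if (!is.null(counts_tsv)) {
    if (is.null(sex_map_tsv)) stop2("counts given without a sex map")
    counts <- read_counts(counts_tsv)
    sex_map <- utils::read.delim(sex_map_tsv, stringsAsFactors = FALSE)
    tpm <- compute_tpm(counts)
    tpm_sums <- stats::setNames(
      rowSums(as.matrix(tpm[setdiff(names(tpm), "transcript_id")])),
      tpm$transcript_id)
    partition <- partition_by_sex(tpm, sex_map)
    .log_stage("expression", nrow(counts), partition$n_expressed)
  }

  screen <- screen_serpins(proteins, config, tpm_sums)
  .log_stage("screen", nrow(proteins), sum(screen$status == "full"))

  ext <- if (!is.null(annotations_tsv)) {
    ingest_external_annotations(annotations_tsv)
  } else list()
  screen$molecular_weight_da <- vapply(seq_len(nrow(proteins)), function(i) {
    tryCatch(molecular_weight(proteins$sequence[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  screen$nglyc_sites <- vapply(proteins$sequence, function(s) {
    paste(find_nglyc(s), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  screen$signal_peptide <- vapply(screen$id, function(id) {
    a <- ext[[id]]
    if (is.null(a)) NA_character_
    else if (a$sp_present) sprintf("SP (%d)", a$sp_length) else "NSP"
  }, character(1), USE.NAMES = FALSE)
  screen$oglyc_sites <- vapply(screen$id, function(id) {
    a <- ext[[id]]
    if (is.null(a)) NA_character_ else paste(a$oglyc, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(partition)) {
    screen$expression_sexes <- vapply(screen$id, function(id) {
      if (id %in% partition$shared) "M/F"
      else if (id %in% partition$female_only) "F"
      else if (id %in% partition$male_only) "M"
      else "-"
    }, character(1), USE.NAMES = FALSE)
  }
  .log_stage("features", nrow(screen), nrow(screen))

  full <- proteins[screen$status == "full", , drop = FALSE]
  report <- NULL; tree <- NULL; logo <- NULL
  if (nrow(full) >= 2) {
    report <- pairwise_report(full)
    utils::write.table(round(report$identity, 2),
                       file.path(out_dir, "pairwise_identity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(round(report$similarity, 2),
                       file.path(out_dir, "pairwise_similarity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(round(report$coverage, 2),
                       file.path(out_dir, "pairwise_coverage.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    rcls <- screen$rcl_seq[screen$status == "full"]
    logo <- logo_matrix(rcls)
    utils::write.table(logo, file.path(out_dir, "logo_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (nrow(full) >= 3) {
      d <- 1 - report$identity / 100
      diag(d) <- 0
      tree <- root_midpoint(nj_tree(d))
      write_newick(tree, file.path(out_dir, "tree.nwk"))
    }
    .log_stage("compare", nrow(full), nrow(full))
  }

  summary <- list(
    n_input = nrow(proteins),
    n_full_length = sum(screen$status == "full"),
    n_partial = sum(screen$status == "partial"))
  if (sum(screen$status == "full") > 0) {
    ps <- p1_summary(screen$p1_residue[screen$status == "full"])
    summary$p1_class_percentages <- as.list(ps$percentages)
    summary$p1_distinct_residues <- ps$distinct_residues
  }
  if (!is.null(partition)) {
    summary$sex_partition <- list(
      female_only = length(partition$female_only),
      male_only = length(partition$male_only),
      shared = length(partition$shared),
      expressed_in_female = partition$n_female,
      expressed_in_male = partition$n_male,
      percentages = as.list(partition$percentages))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(screen, file.path(out_dir, "serpin_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(screen = screen, partition = partition, pairwise = report,
                 tree = tree, logo = logo, summary = summary))
}
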