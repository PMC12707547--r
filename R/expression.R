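#' Read a counts table (TSV)
#'
#' Layout: `transcript_id`, `length`, then one column per sample.
#'
#' @param path TSV path
#' @return counts data frame
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "length") %in% names(df))) {
    stop2("counts table must have 'transcript_id' and 'length' columns")
  }
  if (anyDuplicated(df$transcript_id)) stop2("duplicate transcript ids")
  df
}

.sample_cols <- function(counts) setdiff(names(counts), c("transcript_id", "length"))

.check_counts <- function(counts) {
  samples <- .sample_cols(counts)
  if (length(samples) == 0) stop2("no sample columns")
  if (any(counts$length <= 0)) stop2("effective lengths must be > 0")
  if (any(as.matrix(counts[samples]) < 0)) stop2("negative counts")
  samples
}

#' Transcripts per million
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j(c_j / l_j)` per sample. Samples with no
#' reads at all get all-zero TPM with a warning.
#'
#' @param counts counts data frame (`transcript_id`, `length`, sample columns)
#' @return data frame `transcript_id` plus one TPM column per sample
#' @export
compute_tpm <- function(counts) {
  samples <- .check_counts(counts)
  out <- data.frame(transcript_id = counts$transcript_id,
                    stringsAsFactors = FALSE)
  for (s in samples) {
    rate <- counts[[s]] / counts$length
    tot <- sum(rate)
    if (tot == 0) {
      warning("sample '", s, "' has no reads; TPM set to 0")
      out[[s]] <- rep(0, nrow(counts))
    } else {
      out[[s]] <- 1e6 * rate / tot
    }
  }
  out
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM_i = 1e9 * c_i / (l_i * N)` with `N` the sample's total mapped count.
#'
#' @inheritParams compute_tpm
#' @return data frame `transcript_id` plus one FPKM column per sample
#' @export
compute_fpkm <- function(counts) {
  samples <- .check_counts(counts)
  out <- data.frame(transcript_id = counts$transcript_id,
                    stringsAsFactors = FALSE)
  for (s in samples) {
    N <- sum(counts[[s]])
    if (N == 0) {
      warning("sample '", s, "' has no reads; FPKM set to 0")
      out[[s]] <- rep(0, nrow(counts))
    } else {
      out[[s]] <- 1e9 * counts[[s]] / (counts$length * N)
    }
  }
  out
}

#' Isoform percentage of gene expression
#'
#' `IsoPct_i = 100 * TPM_i / sum(TPM over the gene)`, 0 when the gene's TPM
#' is 0. Without a gene map every transcript is its own gene (IsoPct 100
#' where expressed).
#'
#' @param tpm TPM table from [compute_tpm()]
#' @param gene_map optional data frame (`transcript_id`, `gene_id`)
#' @return data frame of per-sample isoform percentages
#' @export
compute_isopct <- function(tpm, gene_map = NULL) {
  samples <- setdiff(names(tpm), "transcript_id")
  genes <- if (is.null(gene_map)) tpm$transcript_id
           else gene_map$gene_id[match(tpm$transcript_id, gene_map$transcript_id)]
  if (anyNA(genes)) stop2("gene map does not cover all transcripts")
  out <- data.frame(transcript_id = tpm$transcript_id,
                    stringsAsFactors = FALSE)
  for (s in samples) {
    gene_tot <- as.numeric(tapply(tpm[[s]], genes, sum)[genes])
    out[[s]] <- ifelse(gene_tot > 0, 100 * tpm[[s]] / gene_tot, 0)
  }
  out
}

#' Partition transcripts by sex under the zero-TPM presence rule
#'
#' A transcript is expressed in a sex iff its TPM exceeds zero in at least
#' one sample of that sex; transcripts with zero TPM throughout a sex are
#' deemed non-expressed there. Yields the disjoint female-only / male-only /
#' shared sets and their percentages of all expressed transcripts
#' (round-half-up, 2 decimals).
#'
#' @param tpm TPM table from [compute_tpm()]
#' @param sex_map data frame with columns `sample` and `sex` ("female" or
#'   "male"; "F"/"M" accepted)
#' @return object of class `sex_partition`: id sets `female_only`,
#'   `male_only`, `shared`; counts `n_expressed`, `n_female`, `n_male`;
#'   `percentages`
#' @export
partition_by_sex <- function(tpm, sex_map) {
  sex <- tolower(as.character(sex_map$sex))
  sex[sex == "f"] <- "female"
  sex[sex == "m"] <- "male"
  if (!all(sex %in% c("female", "male"))) stop2("sex must be female/male")
  if (!all(c("female", "male") %in% sex)) {
    stop2("need at least one sample per sex")
  }
  f_samples <- sex_map$sample[sex == "female"]
  m_samples <- sex_map$sample[sex == "male"]
  if (!all(c(f_samples, m_samples) %in% names(tpm))) {
    stop2("sex map names samples absent from the TPM table")
  }
  in_f <- rowSums(as.matrix(tpm[f_samples]) > 0) > 0
  in_m <- rowSums(as.matrix(tpm[m_samples]) > 0) > 0
  ids <- tpm$transcript_id
  female_only <- ids[in_f & !in_m]
  male_only <- ids[in_m & !in_f]
  shared <- ids[in_f & in_m]
  n_exp <- sum(in_f | in_m)
  pct <- round_half_up(100 * c(female_only = length(female_only),
                               male_only = length(male_only),
                               shared = length(shared)) / n_exp, 2)
  structure(list(
    female_only = female_only, male_only = male_only, shared = shared,
    n_expressed = n_exp,
    n_female = length(female_only) + length(shared),
    n_male = length(male_only) + length(shared),
    percentages = pct), class = "sex_partition")
}

#' @export
print.sex_partition <- function(x, ...) {
  cat("Sex partition of", x$n_expressed, "expressed transcripts\n")
  cat(sprintf("  female-only: %d (%.2f%%)\n", length(x$female_only),
              x$percentages[["female_only"]]))
  cat(sprintf("  male-only:   %d (%.2f%%)\n", length(x$male_only),
              x$percentages[["male_only"]]))
  cat(sprintf("  shared:      %d (%.2f%%)\n", length(x$shared),
              x$percentages[["shared"]]))
  cat(sprintf("  expressed in female: %d; in male: %d\n", x$n_female, x$n_male))
  invisible(x)
}

#' log2-transformed TPM matrix
#'
#' `log2(TPM + pseudocount)`; the pseudocount (default 1) keeps the zeros
#' that the presence-absence rule guarantees finite.
#'
#' @param tpm TPM table from [compute_tpm()]
#' @param pseudocount positive offset added before the log
#' @return numeric matrix, transcripts x samples
#' @export
log2_matrix <- function(tpm, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  samples <- setdiff(names(tpm), "transcript_id")
  m <- log2(as.matrix(tpm[samples]) + pseudocount)
  rownames(m) <- tpm$transcript_id
  m
}
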