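.get_submat <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  e <- new.env()
  utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
  get(substitution_matrix, envir = e)
}

#' Optimal global alignment with affine gaps and percent statistics
#'
#' Needleman-Wunsch/Gotoh global alignment (via
#' [Biostrings::pairwiseAlignment()]); a gap of length L costs
#' `gap_open + L * gap_extend`. Reported statistics: identity = identical
#' columns / alignment length; similarity = columns whose substitution score
#' is positive / alignment length (gap columns count as dissimilar); coverage
#' = columns aligned in both sequences / length of the shorter sequence, all
#' as percentages.
#'
#' @param a,b protein records or sequence strings
#' @param substitution_matrix matrix or the name of a Biostrings matrix
#'   (default `"BLOSUM62"`)
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 0.5)
#' @return object of class `alignment_result`: `score`, `aligned_a`,
#'   `aligned_b`, `identity`, `similarity`, `coverage`
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  sa <- toupper(if (is.character(a)) a else a$sequence)
  sb <- toupper(if (is.character(b)) b else b$sequence)
  if (!nzchar(sa) || !nzchar(sb)) stop2("empty sequence cannot be aligned")
  mat <- .get_submat(substitution_matrix)
  resid <- unique(c(seq_chars(sa), seq_chars(sb)))
  missing <- setdiff(resid, rownames(mat))
  if (length(missing) > 0) {
    stop2("residue(s) absent from the substitution matrix: ",
          paste(missing, collapse = ","))
  }
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pw))
  al_b <- as.character(Biostrings::alignedSubject(pw))
  ca <- seq_chars(al_a); cb <- seq_chars(al_b)
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb
  simil <- both
  simil[both] <- mat[cbind(ca[both], cb[both])] > 0
  structure(list(
    id_a = if (is.character(a)) NA_character_ else a$id,
    id_b = if (is.character(b)) NA_character_ else b$id,
    score = as.numeric(Biostrings::score(pw)),
    aligned_a = al_a, aligned_b = al_b, length = len,
    identity = 100 * sum(ident) / len,
    similarity = 100 * sum(simil) / len,
    coverage = 100 * sum(both) / min(nchar(sa), nchar(sb))),
    class = "alignment_result")
}

#' All-against-all alignment statistics
#'
#' @param proteins protein record table (>= 2 rows)
#' @inheritParams global_align
#' @return list of three symmetric matrices (`identity`, `similarity`,
#'   `coverage`) with 100 on the diagonal
#' @export
pairwise_report <- function(proteins, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  n <- nrow(proteins)
  stopifnot(n >= 2)
  ids <- proteins$id
  mk <- function() matrix(100, n, n, dimnames = list(ids, ids))
  identity <- mk(); similarity <- mk(); coverage <- mk()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(proteins[i, ], proteins[j, ], substitution_matrix,
                         gap_open, gap_extend)
      identity[i, j] <- identity[j, i] <- al$identity
      similarity[i, j] <- similarity[j, i] <- al$similarity
      coverage[i, j] <- coverage[j, i] <- al$coverage
    }
  }
  list(identity = identity, similarity = similarity, coverage = coverage)
}

#' Pairwise p-distance matrix from global alignments
#'
#' `d = 1 - identity/100` for each pair.
#'
#' @inheritParams pairwise_report
#' @return symmetric distance matrix with zero diagonal
#' @export
distance_matrix <- function(proteins, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  stopifnot(nrow(proteins) >= 3)
  rep <- pairwise_report(proteins, substitution_matrix, gap_open, gap_extend)
  d <- 1 - rep$identity / 100
  diag(d) <- 0
  d
}

.fmt_len <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining under the Q-criterion. Taxa are processed in
#' sorted label order so the topology does not depend on input order.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sibling branch, preserving the path length through the new node.
#'
#' @param dm symmetric distance matrix with row/column names (>= 3 taxa)
#' @return unrooted `phylo` tree (ape)
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop2("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) stop2("distance matrix must be labelled")
  if (max(abs(dm - t(dm))) > 1e-8) stop2("distance matrix must be symmetric")
  ord <- order(rownames(dm))
  D <- dm[ord, ord, drop = FALSE]
  labels <- rownames(D)
  frags <- as.list(labels)   # newick fragment per active cluster
  while (length(frags) > 3) {
    k <- nrow(D)
    r <- rowSums(D)
    best <- NULL; bestq <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      q <- (k - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newfrag <- paste0("(", frags[[i]], ":", .fmt_len(li), ",",
                      frags[[j]], ":", .fmt_len(lj), ")")
    du <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    D <- D2
    frags <- c(frags[keep], list(newfrag))
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frags[[1]], ":", .fmt_len(la), ",",
                frags[[2]], ":", .fmt_len(lb), ",",
                frags[[3]], ":", .fmt_len(lc), ");")
  ape::read.tree(text = nwk)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree a `phylo` tree
#' @return rooted `phylo` tree
#' @export
root_midpoint <- function(tree) {
  if (ape::Ntip(tree) == 2) {
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, length(tree$edge.length))
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Root a tree on an outgroup taxon
#'
#' The root is placed on the outgroup's pendant edge, splitting its length
#' equally between the two sides of the root.
#'
#' @param tree a `phylo` tree
#' @param taxon outgroup tip label
#' @return rooted `phylo` tree
#' @export
root_outgroup <- function(tree, taxon) {
  if (!(taxon %in% tree$tip.label)) stop2("outgroup '", taxon, "' not in tree")
  rt <- ape::root(tree, outgroup = taxon, resolve.root = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  root_edges <- which(rt$edge[, 1] == root_node)
  if (length(root_edges) == 2) {
    tot <- sum(rt$edge.length[root_edges])
    rt$edge.length[root_edges] <- tot / 2
  }
  rt
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser/serialiser.
#'
#' @param path file path
#' @param tree a `phylo` tree
#' @return `read_newick()` returns a `phylo`; `write_newick()` its path,
#'   invisibly
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
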