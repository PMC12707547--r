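test_that("alignment statistics on trivial pairs", {
  id10 <- "MKVLAWPQRS"
  al <- global_align(id10, id10)
  expect_equal(al$identity, 100)
  expect_equal(al$similarity, 100)
  expect_equal(al$coverage, 100)

  al2 <- global_align("AAAA", "AATA")
  expect_equal(al2$identity, 75)
  expect_equal(al2$coverage, 100)

  expect_error(global_align("AAAA", "AA-A"), "absent")
  expect_error(global_align("", "AA"), "empty")
})

test_that("alignment score is symmetric and equals exhaustive enumeration", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- get("BLOSUM62", envir = e)
  withr::local_seed(12)
  for (i in 1:40) {
    a <- rand_protein(sample(1:6, 1), alphabet = c("A", "C", "D", "E"))
    b <- rand_protein(sample(1:6, 1), alphabet = c("A", "C", "D", "E"))
    got <- global_align(a, b)$score
    expect_equal(got, brute_align_score(a, b, B62, 10, 0.5))
    expect_equal(got, global_align(b, a)$score)
  }
})

test_that("a 95-residue pair differing at two sites aligns near 97.9% identity", {
  withr::local_seed(77)
  a <- rand_protein(95)
  ch <- strsplit(a, "")[[1]]
  for (p in c(30, 60)) ch[p] <- setdiff(AA20, ch[p])[1]
  b <- paste(ch, collapse = "")
  al <- global_align(a, b)
  expect_equal(al$identity, 100 * 93 / 95, tolerance = 1e-9)
  expect_equal(al$coverage, 100)
})

test_that("pairwise report is symmetric with a 100 diagonal", {
  withr::local_seed(6)
  prots <- data.frame(id = paste0("p", 1:4), description = "",
                      sequence = replicate(4, rand_protein(50)),
                      stringsAsFactors = FALSE)
  rep_ <- pairwise_report(prots)
  for (m in rep_) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(100, 4))
  }
  d <- distance_matrix(prots[1:3, ])
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0))
})

test_that("NJ solves the 3-taxon closed form with clamped branches", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces an additive 5-taxon matrix exactly", {
  D <- additive_5taxon()
  tr <- nj_tree(D)
  patristic <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(patristic, D, tolerance = 1e-9)
  expect_true(all(tr$edge.length >= 0))
  # ape's NJ is the independent topology cross-check
  ref <- ape::nj(as.dist(D))
  expect_equal(phangorn::RF.dist(tr, ref), 0)
})

test_that("NJ topology does not depend on taxon input order", {
  withr::local_seed(10)
  n <- 7
  labs <- paste0("t", 1:n)
  m <- matrix(runif(n * n, 0.1, 1), n, n, dimnames = list(labs, labs))
  D <- (m + t(m)) / 2; diag(D) <- 0
  t1 <- nj_tree(D)
  perm <- sample(n)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("midpoint and outgroup rooting place the root as specified", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  m2 <- root_midpoint(two)
  expect_equal(m2$edge.length, c(2, 2))

  tr <- nj_tree(additive_5taxon())
  mid <- root_midpoint(tr)
  expect_true(ape::is.rooted(mid))
  # midpoint bisects the longest leaf-to-leaf path (C..E = 9 here)
  cm <- ape::cophenetic.phylo(mid)
  expect_equal(max(cm), 9)
  depths <- ape::node.depth.edgelength(mid)
  expect_equal(max(depths[1:5]), 4.5, tolerance = 1e-9)

  og <- root_outgroup(tr, "E")
  expect_true(ape::is.rooted(og))
  root_children <- og$edge[og$edge[, 1] == ape::Ntip(og) + 1, 2]
  expect_true(which(og$tip.label == "E") %in% root_children)
  # pendant edge (length 4) split in half around the root
  root_edges <- which(og$edge[, 1] == ape::Ntip(og) + 1)
  expect_equal(sort(og$edge.length[root_edges]), c(2, 2))
  expect_error(root_outgroup(tr, "nope"), "not in tree")
})

test_that("Newick write/read/write is idempotent", {
  tr <- nj_tree(additive_5taxon())
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  s1 <- readLines(f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  write_newick(back, f)
  expect_equal(readLines(f), s1)
})
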