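test_that("closure applies the pseudo-count to every entry and renormalizes", {
  x <- close_counts(matrix(c(1, 1, 2), 1), pseudo_count = 0.5)
  expect_equal(as.numeric(x), c(1.5, 1.5, 2.5) / 5.5)
  # all-zero row becomes the uniform composition
  x0 <- close_counts(matrix(0, 1, 3), pseudo_count = 0.5)
  expect_equal(as.numeric(x0), rep(1 / 3, 3))
  expect_equal(formals(close_counts)$pseudo_count, 0.5)
  expect_error(close_counts(matrix(c(0, 1), 1), pseudo_count = 0),
               "pseudo_count")
  expect_error(close_counts(matrix(c(-1, 2), 1)), "negative")
})

test_that("rows of a closed table sum to one and stay strictly positive", {
  set.seed(1)
  w <- matrix(rpois(60, 3), 10, 6)
  x <- close_counts(w)
  expect_true(all(abs(rowSums(x) - 1) < 1e-10))
  expect_true(all(x > 0))
})

test_that("CLR of the uniform composition is zero and rows sum to zero", {
  z <- clr_transform(matrix(0.25, 2, 4))
  expect_equal(as.numeric(z), rep(0, 8))
  z2 <- clr_transform(matrix(c(0.5, 0.25, 0.25), 1))
  expect_equal(round(as.numeric(z2), 4), c(0.4621, -0.2310, -0.2310))
  expect_equal(sum(z2), 0, tolerance = 1e-12)
  expect_error(clr_transform(matrix(c(0.5, 0, 0.5), 1)), "row 1, column 2")
})

test_that("closure then CLR yields zero-sum rows for any positive table", {
  set.seed(42)
  for (rep in 1:5) {
    w <- matrix(rpois(80, 10), 8, 10)
    z <- clr_transform(close_counts(w))
    expect_true(all(abs(rowSums(z)) < 1e-8))
  }
})

test_that("CLR is invariant to row-wise rescaling of the counts", {
  set.seed(5)
  w <- matrix(rpois(40, 20) + 1, 4, 10)
  z1 <- clr_transform(close_counts(w, pseudo_count = 0))
  k <- c(2, 0.5, 10, 1.7)
  z2 <- clr_transform(close_counts(w * k, pseudo_count = 0))
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("count tables round-trip through file I/O with orientation flag", {
  w <- matrix(c(5, 0, 2, 1, 3, 4), 2, 3,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  tf <- tempfile(fileext = ".tsv")
  write.table(w, tf, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(read_counts(tf), `storage.mode<-`(w, "double"))
  tf2 <- tempfile(fileext = ".tsv")
  write.table(t(w), tf2, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(read_counts(tf2, transpose = TRUE),
               `storage.mode<-`(w, "double"))
})

test_that("taxonomy parsing builds lineage-keyed internal nodes", {
  tax <- data.frame(taxon = c("t1", "t2", "t3"),
                    Family = c("F1", "F1", "F2"),
                    Genus = c("G1", "G2", "G3"))
  tree <- taxonomy_tree(tax)
  sets <- tree$nodes$members
  expect_true(list(1:2) %in% sets)        # F1
  expect_true(list(3L) %in% sets)         # F2
  expect_true(list(1:3) %in% sets)        # root
  # count-table taxa missing from the taxonomy are rejected
  expect_error(taxonomy_tree(tax, taxa = c("t1", "t2", "t4")), "absent")
  expect_error(taxonomy_tree(tax[c(1, 1, 3), ]), "duplicate")
})

test_that("a single-rank taxonomy degenerates to one internal group", {
  tax <- data.frame(taxon = c("a", "b", "c"), Family = "F1")
  tree <- taxonomy_tree(tax)
  gs <- build_groups(tree)
  expect_equal(length(gs$members), 1)
  expect_equal(gs$members[[1]], 1:3)
})

test_that("missing ranks create distinct placeholders per parent", {
  tax <- data.frame(taxon = c("t1", "t2"),
                    Family = c("F1", "F2"), Genus = c("", ""))
  tree <- taxonomy_tree(tax)
  # the two unclassified genera must not merge across families
  genus_sets <- tree$nodes$members[tree$nodes$rank == "Genus"]
  expect_equal(genus_sets, list(1L, 2L))
})

test_that("Newick parsing extracts clades and respects taxon order", {
  tree <- read_newick("((A,B),C);")
  expect_true(list(1:2) %in% tree$nodes$members)
  expect_true(list(1:3) %in% tree$nodes$members)
  star <- read_newick("(A,B,C);")
  expect_equal(star$nodes$members, list(1:3))
  # same topology, different leaf input order: memberships map consistently
  t1 <- read_newick("((A,B),C);", taxa = c("A", "B", "C"))
  t2 <- read_newick("((A,B),C);", taxa = c("C", "A", "B"))
  named_sets <- function(tr) {
    s <- lapply(tr$nodes$members, function(m) sort(tr$leaves[m]))
    s[order(vapply(s, paste, character(1), collapse = ","))]
  }
  expect_equal(named_sets(t1), named_sets(t2))
  expect_error(read_newick("((A,B),C);", taxa = c("A", "B", "D")), "match")
})

test_that("taxonomy and Newick encodings of one topology agree", {
  tax <- data.frame(taxon = c("t1", "t2", "t3", "t4"),
                    Family = c("F1", "F1", "F2", "F2"))
  g1 <- build_groups(taxonomy_tree(tax))
  g2 <- build_groups(read_newick("((t1,t2),(t3,t4));",
                                 taxa = paste0("t", 1:4)))
  expect_equal(g1$members, g2$members)
  expect_equal(g1$weights, g2$weights)
})

test_that("the packaged example dataset loads coherently", {
  cf <- system.file("extdata", "example_counts.tsv", package = "tcvs")
  tf <- system.file("extdata", "example_taxonomy.tsv", package = "tcvs")
  mf <- system.file("extdata", "example_metadata.tsv", package = "tcvs")
  counts <- read_counts(cf)
  tree <- read_taxonomy(tf, taxa = colnames(counts))
  md <- read_metadata(mf)
  expect_equal(dim(counts), c(12, 8))
  expect_equal(length(tree$leaves), 8)
  expect_equal(md$sample, rownames(counts))
  gs <- build_groups(tree)
  expect_true(all(gs$weights == lengths(gs$members)))
})
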