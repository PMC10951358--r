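test_that("NJ recovers additive trees with exact branch lengths", {
  set.seed(101)
  tr <- random_additive_tree(4)
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_true(same_topology(nj, tr))
  # additive input: NJ reproduces the generating path lengths
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("three leaves solve the three-point closed form", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.3
  d["a", "c"] <- d["c", "a"] <- 0.5
  d["b", "c"] <- d["c", "b"] <- 0.6
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(lens[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(lens[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ input validation and tie determinism", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d2), "at least 3")
  d3 <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "non-finite")

  # fully equidistant matrix: output is deterministic across calls
  labs <- letters[1:4]
  deq <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(deq) <- 0
  t1 <- nj_tree(deq); t2 <- nj_tree(deq)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("UPGMA reconstructs ultrametric trees and is always ultrametric", {
  labs <- c("a", "b", "c", "d")
  d <- matrix(0.8, 4, 4, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["c", "d"] <- d["d", "c"] <- 0.3
  diag(d) <- 0
  tr <- upgma_tree(d)
  expect_true(ape::is.rooted(tr))
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs], d, tolerance = 1e-12)

  two <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma_tree(two)
  expect_equal(sort(t2$edge.length), c(0.1, 0.1))

  set.seed(55)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    labs <- paste0("x", 1:n)
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
    m <- m + t(m)
    tr <- upgma_tree(m)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("outgroup rooting splits the stem edge and preserves topology", {
  tr <- ape::read.tree(text = "((a:1,b:2):0.5,(c:1,o:4):0.5);")
  un <- ape::unroot(tr)
  rt <- root_with_outgroup(un, "o")
  expect_true(ape::is.rooted(rt))
  root_children <- rt$edge[rt$edge[, 1] == ape::Ntip(rt) + 1L, 2]
  og_side <- vapply(root_children, function(nd) {
    tips <- if (nd <= ape::Ntip(rt)) rt$tip.label[nd] else
      ape::extract.clade(rt, nd)$tip.label
    "o" %in% tips
  }, logical(1))
  expect_equal(sum(og_side), 1L)
  # the two basal branches share the split stem length equally
  basal <- rt$edge.length[rt$edge[, 1] == ape::Ntip(rt) + 1L]
  expect_equal(basal[1], basal[2])
  # unrooting recovers the unrooted topology
  expect_true(same_topology(ape::unroot(rt), un))

  # two-accession outgroup clade roots on its stem
  tr2 <- ape::unroot(ape::read.tree(
    text = "((i1:1,i2:1):1,(i3:1,(o1:1,o2:1):2):1);"))
  rt2 <- root_with_outgroup(tr2, c("o1", "o2"))
  expect_true(is_monophyletic(rt2, c("o1", "o2")))

  expect_error(root_with_outgroup(tr, "zz"), "labelling error")
  # non-separable outgroup
  tr3 <- ape::unroot(ape::read.tree(text = "((o1:1,i1:1):1,(o2:1,i2:1):1);"))
  expect_error(root_with_outgroup(tr3, c("o1", "o2")), "rooting error")
})

test_that("monophyly follows the MRCA-descendant definition", {
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_true(is_monophyletic(good, c("a1", "a2")))
  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_false(is_monophyletic(mixed, c("a1", "a2")))
  expect_true(is_monophyletic(mixed, "a1"))
  expect_error(is_monophyletic(good, "zz"), "labelling error")
  expect_error(is_monophyletic(ape::unroot(good), c("a1", "a2")), "state error")

  # invariant under child rotation
  rot <- ape::rotate(good, ape::Ntip(good) + 1L)
  expect_true(is_monophyletic(rot, c("a1", "a2")))
})

test_that("discrimination success rate is the monophyletic-taxon percentage", {
  tm <- tibble::tibble(
    accession = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    outgroup = FALSE
  )
  full <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep_full <- discrimination_success_rate(full, tm)
  expect_equal(rep_full$rate_percent, 100)
  expect_equal(glance(rep_full)$n_monophyletic, 2L)

  inter <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(discrimination_success_rate(inter, tm)$rate_percent, 0)

  td <- tidy(rep_full)
  expect_named(td, c("taxon", "n_accessions", "monophyletic"))
  expect_equal(nrow(td), 2L)

  tm_extra <- dplyr::bind_rows(tm, tibble::tibble(accession = "c1",
                                                  taxon = "C",
                                                  outgroup = FALSE))
  expect_error(discrimination_success_rate(full, tm_extra), "mapping error")
})

test_that("bootstrap supports are reproducible, bounded, and saturate on clean signal", {
  # alignment of repeated diagnostic columns: every replicate sees the same
  # patterns, so every split has 100% support
  block <- c(a1 = "A", a2 = "A", b1 = "C", b2 = "C", c1 = "G", c2 = "G")
  m <- matrix(rep(block, 40), nrow = 6, dimnames = list(names(block), NULL))
  extra <- c(a1 = "T", a2 = "T", b1 = "T", b2 = "T", c1 = "A", c2 = "A")
  m <- cbind(m, matrix(rep(extra, 40), nrow = 6))
  a <- alignment(m)
  tr <- bootstrap_support(a, model = "p", method = "nj", replicates = 50,
                          seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  set.seed(77)
  b <- related_alignment(6, 80, sub_rate = 0.1)
  t1 <- bootstrap_support(b, model = "k2p", method = "nj", replicates = 30,
                          seed = 42)
  t2 <- bootstrap_support(b, model = "k2p", method = "nj", replicates = 30,
                          seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  s1 <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(s1[!is.na(s1)] >= 0 & s1[!is.na(s1)] <= 100))
})

test_that("Newick trees round-trip and malformed input errors", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2):0.5,c:3);", p)
  tr <- parse_newick(p)
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p2)
  tr2 <- parse_newick(p2)
  expect_true(same_topology(tr, tr2))
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))

  # integer support values are serialized as internal node labels
  tr$node.label <- c("", "87")
  write_newick(tr, p2)
  expect_match(paste(readLines(p2), collapse = ""), "87")
  expect_equal(parse_newick(p2)$node.label, c("", "87"))

  p3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2:0.5,c:3;", p3)
  expect_error(parse_newick(p3), "format error")
})
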