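two_taxa_map <- function() {
  tibble::tibble(
    accession = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    outgroup = FALSE
  )
}

test_that("column classification implements the site definitions", {
  tm <- two_taxa_map()
  aln <- alignment(c(a1 = "AAAA", a2 = "AAAC", b1 = "GAAA", b2 = "GAAA"))
  s <- classify_columns(aln, tm)
  # column 1: A,A,G,G -> variable, parsimony-informative
  expect_true(s$variable[1] && s$parsimony_informative[1])
  # column 2: invariant
  expect_true(s$invariant[2] && !s$variable[2])
  # column 4: A,C,A,A -> variable singleton, not informative
  expect_true(s$variable[4] && s$singleton[4] && !s$parsimony_informative[4])
  # invariant and variable flags partition every column
  expect_true(all(xor(s$invariant, s$variable)))

  expect_equal(count_informative_sites(s), 1L)
})

test_that("classification tallies gaps as missing and excludes the outgroup", {
  tm <- dplyr::bind_rows(two_taxa_map(),
                         tibble::tibble(accession = "og", taxon = "OG",
                                        outgroup = TRUE))
  aln <- alignment(c(a1 = "A-", a2 = "AA", b1 = "GA", b2 = "GA", og = "TT"))
  s <- classify_columns(aln, tm)
  expect_equal(s$n_defined, c(4L, 3L))
  # outgroup T never appears in the state counts
  counts <- attr(s, "state_counts")
  expect_false(any(counts$state == "T" & counts$n > 0))
})

test_that("unmapped ingroup accessions are a mapping error", {
  tm <- two_taxa_map()[1:3, ]
  aln <- alignment(c(a1 = "AA", a2 = "AA", b1 = "AA", b2 = "AA"))
  expect_error(classify_columns(aln, tm), "mapping error")
})

test_that("species-specific SNP calling enforces the specificity predicate", {
  tm <- two_taxa_map()
  # col 1 diagnostic for A (and symmetric two-state partition for B),
  # col 2 shared states, col 3 invariant, col 4 has a gap in a non-target
  aln <- alignment(c(a1 = "CAGA", a2 = "CAGA", b1 = "TCG-", b2 = "TAGA"))
  sites <- call_species_specific_snps(aln, tm)
  # two-state partition at column 1: both internally fixed taxa are reported
  col1 <- sites[sites$column == 1, ]
  expect_setequal(col1$taxon, c("A", "B"))
  expect_equal(col1$state[col1$taxon == "A"], "C")
  expect_equal(col1$others[col1$taxon == "A"], "T")
  # col 2: b1 carries C uniquely but taxon B is not fixed -> no site
  expect_false(any(sites$column == 2))
  # col 3 invariant -> no site; col 4 disqualified by the gap
  expect_false(any(sites$column %in% c(3, 4)))
})

test_that("emitted diagnostic sites survive brute-force verification", {
  set.seed(13)
  for (k in 1:20) {
    n_tax <- sample(2:4, 1)
    per <- sample(2:3, 1)
    tm <- tibble::tibble(
      accession = sprintf("t%da%d", rep(seq_len(n_tax), each = per),
                          rep(seq_len(per), n_tax)),
      taxon = sprintf("T%d", rep(seq_len(n_tax), each = per)),
      outgroup = FALSE
    )
    a <- random_alignment(n_tax * per, 30, gap_prob = 0.08)
    rownames(a) <- tm$accession
    sites <- call_species_specific_snps(a, tm)
    m <- unclass(a)
    for (r in seq_len(nrow(sites))) {
      col <- sites$column[r]
      target <- tm$accession[tm$taxon == sites$taxon[r]]
      others <- setdiff(tm$accession, target)
      expect_true(all(m[target, col] == sites$state[r]))
      expect_true(all(m[others, col] %in% c("A", "C", "G", "T")))
      expect_false(any(m[others, col] == sites$state[r]))
    }
    # and no qualifying column was missed
    for (col in seq_len(ncol(m))) {
      for (tx in unique(tm$taxon)) {
        target <- tm$accession[tm$taxon == tx]
        others <- setdiff(tm$accession, target)
        qualifies <- length(unique(m[target, col])) == 1 &&
          m[target[1], col] %in% c("A", "C", "G", "T") &&
          all(m[others, col] %in% c("A", "C", "G", "T")) &&
          !any(m[others, col] == m[target[1], col])
        expect_equal(any(sites$column == col & sites$taxon == tx), qualifies)
      }
    }
  }
})

three_taxa_map <- function() {
  tibble::tibble(
    accession = c("a1", "a2", "b1", "b2", "c1", "c2"),
    taxon = rep(c("A", "B", "C"), each = 2),
    outgroup = FALSE
  )
}

test_that("indel events merge contiguous columns with identical patterns", {
  tm <- three_taxa_map()
  # two adjacent gap columns, same pattern -> one deletion event of length 2
  aln <- alignment(c(a1 = "A--T", a2 = "A--T", b1 = "AGCT", b2 = "AGCT",
                     c1 = "AGCT", c2 = "AGCT"))
  ev <- call_indel_events(aln, tm)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 2L)
  expect_equal(ev$taxon, "A")
  expect_equal(ev$polarity, "deletion")
  expect_false(ev$edge)

  # adjacent gap columns with different patterns -> two events
  aln2 <- alignment(c(a1 = "A-CT", a2 = "A-CT", b1 = "AG-T", b2 = "AG-T",
                      c1 = "AGCT", c2 = "AGCT"))
  ev2 <- call_indel_events(aln2, tm)
  expect_equal(nrow(ev2), 2L)

  # gap-free alignment -> no events
  expect_equal(nrow(call_indel_events(alignment(c(a1 = "ACGT", b1 = "ACGT")))),
               0L)
})

test_that("insertion polarity requires exactly one sequence-bearing taxon", {
  tm <- three_taxa_map()
  aln <- alignment(c(a1 = "AGGT", a2 = "AGGT", b1 = "A--T", b2 = "A--T",
                     c1 = "A--T", c2 = "A--T"))
  ev <- call_indel_events(aln, tm)
  expect_equal(ev$polarity, "insertion")
  expect_equal(ev$taxon, "A")
  expect_equal(ev$sequence, "GG")

  # pattern splitting a taxon -> no taxon, unpolarized
  aln2 <- alignment(c(a1 = "A--T", a2 = "AGGT", b1 = "AGGT", b2 = "AGGT",
                      c1 = "AGGT", c2 = "AGGT"))
  ev2 <- call_indel_events(aln2, tm)
  expect_true(is.na(ev2$taxon))
  expect_equal(ev2$polarity, "unpolarized")
})

test_that("terminal events carry the edge flag", {
  tm <- two_taxa_map()
  aln <- alignment(c(a1 = "--GT", a2 = "--GT", b1 = "ACGT", b2 = "ACG-"))
  ev <- call_indel_events(aln, tm)
  expect_true(all(ev$edge))
})

test_that("planted diagnostics are recovered exactly without noise", {
  taxa <- paste0("T", 1:4)
  plan <- private_snp_plan(taxa, "loc", 300L, per_taxon = 2L)
  cfg <- simulation_config(taxa, 3L, c(loc = 300L), planted_snps = plan,
                           planted_indels = tibble::tibble(
                             locus = "loc", start = 110L, length = 24L,
                             taxon = "T2", type = "insertion",
                             sequence = "GAAGGGGTATGTTATTATTTTATT"),
                           background_rate = 0, outgroup_divergence = 0.05,
                           seed = 99L)
  sim <- simulate_dataset(cfg)
  sites <- call_species_specific_snps(sim$alignments$loc, sim$taxon_map)
  expect_equal(nrow(sites), nrow(sim$truth$snps))
  merged <- dplyr::inner_join(sites, sim$truth$snps,
                              by = c("column", "taxon", "state"))
  expect_equal(nrow(merged), nrow(sim$truth$snps))

  ev <- call_indel_events(sim$alignments$loc, sim$taxon_map)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 110L)
  expect_equal(ev$length, 24L)
  expect_equal(ev$taxon, "T2")
  expect_equal(ev$polarity, "insertion")
  expect_equal(ev$sequence, "GAAGGGGTATGTTATTATTTTATT")
})

test_that("intra-taxon noise at a planted column suppresses the site", {
  taxa <- c("T1", "T2")
  cfg <- simulation_config(taxa, 3L, c(loc = 50L),
                           planted_snps = tibble::tibble(
                             locus = "loc", column = 25L, taxon = "T1",
                             state = NA_character_),
                           background_rate = 0, outgroup_divergence = 0,
                           seed = 3L)
  sim <- simulate_dataset(cfg)
  m <- unclass(sim$alignments$loc)
  # corrupt one target accession at the planted column
  planted_state <- sim$truth$snps$state[1]
  other <- setdiff(c("A", "C", "G", "T"), planted_state)[1]
  m["S01_01", 25] <- other
  sites <- call_species_specific_snps(alignment(m), sim$taxon_map)
  expect_false(any(sites$column == 25 & sites$taxon == "T1"))
})

test_that("diagnostic reports map concatenated columns to locus coordinates", {
  fx <- table2_fixture()
  cc <- concatenate(fx$alignments[c("atpB", "petA")])
  sites <- call_species_specific_snps(cc$alignment, fx$taxon_map)
  rep <- diagnostic_report(sites, partition = cc$partition)
  het <- rep[rep$taxon == "Patrinia heterophylla", ]
  expect_setequal(paste(het$locus, het$position), c("atpB 212", "petA 194"))

  expect_error(
    diagnostic_report(tibble::tibble(column = 5000L, taxon = "x", state = "A",
                                     others = "T", kind = "species_specific_snp"),
                      partition = cc$partition),
    "coordinate error")

  empty <- diagnostic_report(sites[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("locus", "position", "taxon", "kind", "state", "others"))
})
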