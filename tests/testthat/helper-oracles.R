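# Independent oracles and small random-data generators used across the suite.

# Brute-force nucleotide diversity: explicit double loop over sequence pairs
# and columns, counting per-column mismatch fractions over gap-free,
# ambiguity-free columns.
naive_pi <- function(m, columns = seq_len(ncol(m))) {
  bases <- c("A", "C", "G", "T")
  usable <- columns[vapply(columns, function(cc) all(m[, cc] %in% bases),
                           logical(1))]
  if (length(usable) == 0L) return(NA_real_)
  n <- nrow(m)
  tot <- 0
  for (cc in usable) {
    diffs <- 0L
    np <- 0L
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        np <- np + 1L
        if (m[i, cc] != m[j, cc]) diffs <- diffs + 1L
      }
    }
    tot <- tot + diffs / np
  }
  tot / length(usable)
}

random_alignment <- function(n, L, gap_prob = 0.05, name = "rand") {
  chars <- sample(c("A", "C", "G", "T", "-"), n * L, replace = TRUE,
                  prob = c(rep((1 - gap_prob) / 4, 4), gap_prob))
  m <- matrix(chars, nrow = n,
              dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
  alignment(m, name = name)
}

# Exhaustive least-squares topology oracle: enumerate every unrooted binary
# topology on the tip set, fit branch lengths by ordinary least squares on the
# pairwise distances, and return the minimum-SSQ topology.
path_edge_matrix <- function(tr) {
  n <- length(tr$tip.label)
  pairs <- utils::combn(n, 2)
  A <- matrix(0L, ncol(pairs), nrow(tr$edge))
  for (p in seq_len(ncol(pairs))) {
    np <- ape::nodepath(tr, pairs[1, p], pairs[2, p])
    for (k in seq_len(length(np) - 1L)) {
      e <- which((tr$edge[, 1] == np[k] & tr$edge[, 2] == np[k + 1]) |
                   (tr$edge[, 2] == np[k] & tr$edge[, 1] == np[k + 1]))
      A[p, e] <- 1L
    }
  }
  A
}

make_ls_oracle <- function(n) {
  labs <- paste0("t", seq_len(n))
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  qrs <- lapply(topos, function(tr) qr(path_edge_matrix(tr)))
  list(labs = labs, topos = topos, qrs = qrs)
}

ls_best_topology <- function(oracle, d) {
  d <- d[oracle$labs, oracle$labs]
  # as.dist vector order equals the combn(n, 2) pair order used in
  # path_edge_matrix (column-major lower triangle)
  dvec <- as.vector(as.dist(d))
  ssq <- vapply(oracle$qrs, function(q) {
    sum(qr.resid(q, dvec)^2)
  }, numeric(1))
  oracle$topos[[which.min(ssq)]]
}

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

same_topology <- function(t1, t2) {
  isTRUE(all.equal(phangorn::RF.dist(t1, t2), 0))
}

# Closely related sequences: ancestor plus per-sequence substitutions, so that
# correction formulas stay away from saturation.
related_alignment <- function(n, L, sub_rate = 0.05, gap_prob = 0,
                              name = "rel") {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n,
              dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
  for (i in seq_len(n)) {
    hit <- which(runif(L) < sub_rate)
    if (length(hit)) {
      m[i, hit] <- vapply(m[i, hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    gaps <- which(runif(L) < gap_prob)
    if (length(gaps)) m[i, gaps] <- "-"
  }
  alignment(m, name = name)
}
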