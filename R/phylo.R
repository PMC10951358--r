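#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()], followed by a negative-branch
#' adjustment: any negative branch length is clamped to zero and the deficit
#' moved to a sibling branch, preserving the sum of branch lengths (standard
#' practice for distance trees).
#'
#' @param d Symmetric distance matrix with >= 3 labelled rows and finite
#'   entries (see [distance_matrix()]).
#' @return An unrooted `phylo` tree with all input leaves.
#' @export
nj_tree <- function(d) {
  check_matrix_input(d, min_n = 3L)
  tr <- ape::nj(as.dist(d))
  clamp_negative_branches(tr)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance, so
#' the output is rooted and ultrametric.
#'
#' @param d Symmetric distance matrix with >= 2 labelled rows.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(d) {
  check_matrix_input(d, min_n = 2L)
  phangorn::upgma(as.dist(d))
}

check_matrix_input <- function(d, min_n) {
  if (!is.matrix(d) || nrow(d) < min_n) {
    stop("input error: need a distance matrix with at least ", min_n,
         " labels", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    stop("input error: distance matrix must have labels", call. = FALSE)
  }
  if (any(!is.finite(d))) {
    stop("input error: non-finite distance entries", call. = FALSE)
  }
  invisible(d)
}

clamp_negative_branches <- function(tr) {
  for (pass in 1:3) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      if (tr$edge.length[e] >= 0) next
      parent <- tr$edge[e, 1L]
      sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sibs)) {
        tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree on the outgroup stem edge
#'
#' Places the root on the edge separating the outgroup accessions from the
#' ingroup, splitting that edge's length equally between the two sides of the
#' root. A rooted input is unrooted first.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Character vector of outgroup leaf labels.
#' @return A rooted `phylo` tree with a degree-2 root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("labelling error: outgroup leaf/leaves not in tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(outgroup) >= length(tree$tip.label)) {
    stop("rooting error: outgroup cannot contain every leaf", call. = FALSE)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rt <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) stop("rooting error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!ape::is.monophyletic(rt, outgroup)) {
    stop("rooting error: outgroup does not form a separable subtree",
         call. = FALSE)
  }
  # split the stem edge length equally across the root
  root_node <- ape::Ntip(rt) + 1L
  basal <- which(rt$edge[, 1L] == root_node)
  if (length(basal) == 2L) {
    tot <- sum(rt$edge.length[basal])
    rt$edge.length[basal] <- tot / 2
  }
  rt
}

#' Test whether a leaf set is monophyletic
#'
#' True when the most recent common ancestor of the set has exactly that set
#' as its leaf descendants. Requires a rooted tree; a singleton set is always
#' monophyletic.
#'
#' @param tree A rooted `phylo` tree.
#' @param accession_set Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, accession_set) {
  if (!ape::is.rooted(tree)) {
    stop("state error: monophyly requires a rooted tree", call. = FALSE)
  }
  unknown <- setdiff(accession_set, tree$tip.label)
  if (length(unknown)) {
    stop("labelling error: unknown accession(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(accession_set) <= 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, accession_set)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  setequal(clade_tips, accession_set)
}

#' Discrimination success rate of a rooted tree
#'
#' The percentage of ingroup taxa whose accessions form a monophyletic clade
#' in the rooted tree: `100 * n_monophyletic / n_taxa`. Outgroup accessions
#' are excluded from the evaluation (they serve only to root the tree).
#'
#' @param tree A rooted `phylo` tree whose leaves include every ingroup
#'   accession of `tm`.
#' @param tm Taxon map tibble.
#' @return A `discrimination_report` object; see [tidy.discrimination_report()]
#'   and [glance.discrimination_report()].
#' @export
discrimination_success_rate <- function(tree, tm) {
  tm_in <- tm[!tm$outgroup, ]
  missing <- setdiff(tm_in$accession, tree$tip.label)
  if (length(missing)) {
    stop("mapping error: ingroup accession(s) absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  taxa <- sort(unique(tm_in$taxon))
  per <- purrr::map_dfr(taxa, function(tx) {
    accs <- tm_in$accession[tm_in$taxon == tx]
    tibble::tibble(taxon = tx, n_accessions = length(accs),
                   monophyletic = is_monophyletic(tree, accs))
  })
  n_mono <- sum(per$monophyletic)
  structure(
    list(per_taxon = per, n_monophyletic = n_mono, n_taxa = length(taxa),
         rate_percent = 100 * n_mono / length(taxa)),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Discrimination success rate: ", format(x$rate_percent, digits = 4),
      "% (", x$n_monophyletic, "/", x$n_taxa, " taxa monophyletic)\n", sep = "")
  print(x$per_taxon)
  invisible(x)
}

#' Tidy a discrimination report
#'
#' @param x A `discrimination_report`.
#' @param ... Unused.
#' @return One row per ingroup taxon: `taxon`, `n_accessions`, `monophyletic`.
#' @export
tidy.discrimination_report <- function(x, ...) x$per_taxon

#' One-row summary of a discrimination report
#'
#' @param x A `discrimination_report`.
#' @param ... Unused.
#' @return Tibble with `n_taxa`, `n_monophyletic`, `rate_percent`.
#' @export
glance.discrimination_report <- function(x, ...) {
  tibble::tibble(n_taxa = x$n_taxa, n_monophyletic = x$n_monophyletic,
                 rate_percent = x$rate_percent)
}

#' Bootstrap support for a distance tree
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times, rebuilds a tree per
#' replicate, and labels each internal node of the point tree with the
#' percentage of replicate trees containing the same (unrooted) bipartition.
#' Replicates whose resampled columns leave some sequence pair with no
#' comparable site are skipped with a warning and excluded from the
#' denominator.
#'
#' @param x A `dna_alignment`.
#' @param model Distance model (see [seq_distance()]).
#' @param method `"nj"` or `"upgma"`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param gamma_shape Optional gamma shape for the distance model.
#' @return The point-estimate `phylo` tree with integer support percentages in
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(x, model = "k2p", method = c("nj", "upgma"),
                              replicates = 1000L, seed, gamma_shape = NULL) {
  method <- match.arg(method)
  if (replicates < 1L) stop("input error: replicates must be >= 1", call. = FALSE)
  build <- function(aln) {
    d <- suppressWarnings(distance_matrix(aln, model, gamma_shape))
    if (method == "nj") nj_tree(d) else upgma_tree(d)
  }
  point <- build(x)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
    rep_aln <- alignment(unclass(x)[, cols, drop = FALSE], name = locus_name(x))
    reps[[r]] <- tryCatch(build(rep_aln), error = function(e) NULL)
    if (is.null(reps[[r]])) skipped <- skipped + 1L
  }
  if (skipped > 0L) {
    warning(skipped, " bootstrap replicate(s) skipped (no comparable sites ",
            "for some pair)", call. = FALSE)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  n_used <- length(reps)
  if (n_used == 0L) stop("input error: all bootstrap replicates failed",
                         call. = FALSE)
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(round(100 * counts / n_used))
  point
}

#' Newick input/output
#'
#' Standard Newick with branch lengths; integer support values are carried as
#' internal-node labels. `parse_newick(write_newick(tree))` is the identity on
#' canonical trees.
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `parse_newick` returns a
#'   `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
parse_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close || !grepl(";", txt, fixed = TRUE)) {
    stop("format error: malformed Newick in ", path, call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("format error: malformed Newick in ", path, call. = FALSE)
  }
  tr
}
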