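#' Enumerate loci combinations
#'
#' @param loci Character vector of locus names.
#' @param policy `"single"`, `"pairs"`, `"triples"`, `"all"` (all non-empty
#'   subsets, by size then lexicographic order), or `"explicit"` with
#'   `explicit` given.
#' @param explicit List of character vectors naming loci (for
#'   `policy = "explicit"`).
#' @return A list of character vectors, each a sorted loci subset, in
#'   deterministic order.
#' @export
combinations <- function(loci, policy = c("single", "pairs", "triples", "all",
                                          "explicit"),
                         explicit = NULL) {
  policy <- match.arg(policy)
  if (length(loci) < 1L) stop("config error: need at least one locus",
                              call. = FALSE)
  loci <- sort(loci)
  subsets_of <- function(k) {
    if (k > length(loci)) return(list())
    cols <- utils::combn(loci, k, simplify = FALSE)
    cols[order(vapply(cols, paste, character(1), collapse = "\r"))]
  }
  switch(policy,
    single = subsets_of(1L),
    pairs = subsets_of(2L),
    triples = subsets_of(3L),
    all = purrr::flatten(lapply(seq_along(loci), subsets_of)),
    explicit = {
      if (is.null(explicit)) stop("config error: explicit policy needs a list",
                                  call. = FALSE)
      lapply(explicit, function(s) {
        unknown <- setdiff(s, loci)
        if (length(unknown)) {
          stop("config error: unknown locus in combination: ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        sort(s)
      })
    }
  )
}

#' Run the full authentication workflow
#'
#' For each requested loci combination: concatenates the constituent
#' alignments, counts parsimony-informative and species-specific nucleotides
#' (summed per constituent locus, so positions stay locus-local), builds the
#' distance matrix and requested tree(s), roots NJ trees with the outgroup
#' (UPGMA trees carry their own root), and computes the discrimination
#' success rate. Diagnostics and per-combination summaries are returned as
#' tibbles and, when `out_dir` is given, written as TSV alongside Newick
#' trees and a run log. A failing combination is logged and skipped; the
#' others proceed.
#'
#' @param alignments Named list of per-locus `dna_alignment` objects.
#' @param tm Taxon map tibble with a flagged outgroup accession.
#' @param model Global distance model (default `"t3p"`).
#' @param gamma_shape Optional gamma shape for the distance model.
#' @param methods Tree methods, subset of `c("nj", "upgma")`.
#' @param policy Combination policy passed to [combinations()].
#' @param explicit Explicit combination list (see [combinations()]).
#' @param bootstrap Bootstrap replicates for the final trees (0 = none).
#' @param seed Integer seed (bootstrap resampling).
#' @param out_dir Optional output directory.
#' @return A list: `combination_report` (one row per combination x method),
#'   `diagnostics` (marker table over all loci), `per_locus` (counts per
#'   locus), `trees` (named list of rooted `phylo`), `log` (character).
#' @export
run_pipeline <- function(alignments, tm, model = "t3p", gamma_shape = NULL,
                         methods = "nj", policy = "all", explicit = NULL,
                         bootstrap = 0L, seed = 1L, out_dir = NULL) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  methods <- match.arg(methods, c("nj", "upgma"), several.ok = TRUE)
  og <- outgroup_accessions(tm)
  if (length(og) == 0L) stop("config error: taxon map has no outgroup",
                             call. = FALSE)
  log_lines <- c(
    paste0("diagmark ", as.character(utils::packageVersion("diagmark"))),
    paste0("model=", model,
           if (!is.null(gamma_shape)) paste0("+G(", gamma_shape, ")") else ""),
    paste0("methods=", paste(methods, collapse = ",")),
    paste0("seed=", seed),
    paste0("loci=", paste(sort(names(alignments)), collapse = ","))
  )

  per_locus <- purrr::map_dfr(names(alignments), function(lc) {
    a <- alignments[[lc]]
    tryCatch({
      summ <- classify_columns(a, tm)
      snps <- call_species_specific_snps(a, tm)
      indels <- call_indel_events(a, tm)
      sp_ind <- indels[!is.na(indels$taxon), , drop = FALSE]
      tibble::tibble(
        locus = lc,
        length = aln_length(a),
        n_informative = count_informative_sites(summ),
        n_species_specific = nrow(snps) + nrow(sp_ind),
        taxa_with_specific = list(sort(unique(c(snps$taxon, sp_ind$taxon))))
      )
    }, error = function(e) {
      log_lines <<- c(log_lines,
                      paste0("ERROR [", lc, " diagnostics]: ",
                             conditionMessage(e)))
      tibble::tibble(locus = lc, length = aln_length(a),
                     n_informative = NA_integer_,
                     n_species_specific = NA_integer_,
                     taxa_with_specific = list(character()))
    })
  })

  diagnostics <- purrr::map_dfr(names(alignments), function(lc) {
    a <- alignments[[lc]]
    tryCatch(
      diagnostic_report(call_species_specific_snps(a, tm),
                        call_indel_events(a, tm), locus = lc),
      error = function(e) NULL
    )
  })

  combos <- combinations(names(alignments), policy, explicit)
  trees <- list()
  rows <- list()
  for (cb in combos) {
    combo_id <- paste(cb, collapse = "+")
    res <- tryCatch({
      cat_res <- if (length(cb) == 1L) {
        list(alignment = alignments[[cb]], partition = tibble::tibble(
          locus = cb, start = 1L, end = aln_length(alignments[[cb]])))
      } else {
        concatenate(alignments[cb], name = combo_id)
      }
      d <- distance_matrix(cat_res$alignment, model, gamma_shape)
      # evaluate discrimination over the accessions this combination carries
      tm_combo <- tm[tm$accession %in% accessions(cat_res$alignment), ]
      pl <- per_locus[per_locus$locus %in% cb, ]
      taxa_with <- sort(unique(unlist(pl$taxa_with_specific)))
      purrr::map_dfr(methods, function(me) {
        tr <- if (me == "nj") {
          root_with_outgroup(nj_tree(d), og)
        } else {
          upgma_tree(d)
        }
        if (bootstrap > 0L) {
          bs <- bootstrap_support(cat_res$alignment, model = model, method = me,
                                  replicates = bootstrap, seed = seed,
                                  gamma_shape = gamma_shape)
          # carry supports on the unrooted point tree alongside
          trees[[paste(combo_id, me, "bootstrap", sep = ".")]] <<- bs
        }
        trees[[paste(combo_id, me, sep = ".")]] <<- tr
        rep <- discrimination_success_rate(tr, tm_combo)
        tibble::tibble(
          combination = combo_id,
          n_loci = length(cb),
          length = aln_length(cat_res$alignment),
          n_informative = sum(pl$n_informative),
          n_species_specific = sum(pl$n_species_specific),
          n_taxa_with_specific = length(taxa_with),
          method = me,
          n_monophyletic = rep$n_monophyletic,
          rate_percent = rep$rate_percent
        )
      })
    }, error = function(e) {
      log_lines <<- c(log_lines,
                      paste0("ERROR [", combo_id, "]: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[combo_id]] <- res
  }
  report <- dplyr::bind_rows(rows)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "trees"), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_tsv(report, file.path(out_dir, "combinations.tsv"))
    readr::write_tsv(diagnostics, file.path(out_dir, "diagnostics.tsv"))
    readr::write_tsv(
      dplyr::mutate(per_locus,
                    taxa_with_specific = vapply(.data$taxa_with_specific,
                                                paste, character(1),
                                                collapse = ";")),
      file.path(out_dir, "per_locus.tsv"))
    for (nm in names(trees)) {
      write_newick(trees[[nm]], file.path(out_dir, "trees",
                                          paste0(nm, ".nwk")))
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  list(combination_report = report, diagnostics = diagnostics,
       per_locus = per_locus, trees = trees, log = log_lines)
}

#' Whole-alignment diversity scan with outputs
#'
#' Convenience wrapper: sliding-window pi plus hotspot calling, optionally
#' written as `windows.tsv` and `hotspots.tsv`.
#'
#' @param x A `dna_alignment` (e.g. a whole-plastome alignment).
#' @param window,step,threshold Scan parameters (defaults 600/200/0.05).
#' @param out_dir Optional output directory.
#' @return List with `windows` and `hotspots` tibbles.
#' @export
run_scan <- function(x, window = 600L, step = 200L, threshold = 0.05,
                     out_dir = NULL) {
  w <- sliding_window_pi(x, window, step)
  h <- call_hotspots(w, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::as_tibble(w), file.path(out_dir, "windows.tsv"))
    readr::write_tsv(h, file.path(out_dir, "hotspots.tsv"))
  }
  list(windows = w, hotspots = h)
}
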