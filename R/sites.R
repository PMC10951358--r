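#' Classify alignment columns
#'
#' Tallies ingroup base states per column and flags each column as invariant,
#' variable, parsimony-informative and/or singleton. Outgroup accessions are
#' excluded. Gaps and ambiguity codes are counted as missing, not as states.
#'
#' Definitions (on defined ingroup bases at a column): *variable* = at least 2
#' distinct bases; *parsimony-informative* = at least 2 distinct bases each
#' carried by at least 2 accessions; *singleton* = variable but not
#' informative; *invariant* = at most 1 distinct base.
#'
#' @param x A `dna_alignment`.
#' @param tm Taxon map tibble (see [taxon_map()]).
#' @return A tibble with one row per column: `column`, `n_defined`,
#'   `n_states`, `invariant`, `variable`, `parsimony_informative`,
#'   `singleton`. Per-taxon state counts are attached as the long-format
#'   tibble attribute `"state_counts"` (`column`, `taxon`, `state`, `n`).
#' @export
classify_columns <- function(x, tm) {
  m <- ingroup_matrix(x, tm)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  n_def <- rowSums(counts)
  n_states <- rowSums(counts > 0)
  informative <- rowSums(counts >= 2) >= 2
  out <- tibble::tibble(
    column = seq_len(ncol(m)),
    n_defined = as.integer(n_def),
    n_states = as.integer(n_states),
    invariant = n_states <= 1L,
    variable = n_states >= 2L,
    parsimony_informative = informative,
    singleton = n_states >= 2L & !informative
  )
  tm_in <- tm[!tm$outgroup & tm$accession %in% rownames(m), ]
  long <- purrr::map_dfr(split(tm_in$accession, tm_in$taxon), function(accs) {
    sub <- m[accs, , drop = FALSE]
    cnt <- vapply(bases, function(b) colSums(sub == b), numeric(ncol(m)))
    if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, bases))
    tibble::tibble(column = rep(seq_len(ncol(m)), times = 4L),
                   state = rep(bases, each = ncol(m)),
                   n = as.integer(as.vector(cnt)))
  }, .id = "taxon")
  attr(out, "state_counts") <- long[long$n > 0L, c("column", "taxon", "state", "n")]
  out
}

ingroup_matrix <- function(x, tm) {
  og <- outgroup_accessions(tm)
  keep <- setdiff(accessions(x), og)
  unmapped <- setdiff(keep, tm$accession)
  if (length(unmapped)) {
    stop("mapping error: ingroup accession(s) missing from taxon map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  x[keep, , drop = FALSE]
}

#' Count parsimony-informative columns
#'
#' @param summary Output of [classify_columns()].
#' @return Integer count of columns flagged parsimony-informative.
#' @export
count_informative_sites <- function(summary) {
  sum(summary$parsimony_informative)
}

#' Call species-specific SNP diagnostic sites
#'
#' A column yields a diagnostic site for taxon T with state X when every
#' accession of T carries X there, no accession of any other ingroup taxon
#' carries X, and every non-T ingroup accession has a defined base (A/C/G/T)
#' at that column. Columns where any non-target accession shows a gap or
#' ambiguity are disqualified, and outgroup accessions are ignored throughout.
#'
#' @param x A `dna_alignment`.
#' @param tm Taxon map with at least 2 ingroup taxa.
#' @return A tibble `column`, `taxon`, `state`, `others` (states seen outside
#'   the taxon, comma-separated, sorted), `kind` (always
#'   `"species_specific_snp"`), sorted by `column` then `taxon`.
#' @export
call_species_specific_snps <- function(x, tm) {
  m <- ingroup_matrix(x, tm)
  tm_in <- tm[!tm$outgroup & tm$accession %in% rownames(m), ]
  taxa <- sort(unique(tm_in$taxon))
  if (length(taxa) < 2L) {
    stop("input error: need at least 2 ingroup taxa", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  nc <- ncol(m)
  counts_all <- vapply(bases, function(b) colSums(m == b), numeric(nc))
  if (nc == 1L) counts_all <- matrix(counts_all, nrow = 1L, dimnames = list(NULL, bases))
  n_total <- nrow(m)
  res <- purrr::map_dfr(taxa, function(tx) {
    accs <- tm_in$accession[tm_in$taxon == tx]
    sub <- m[accs, , drop = FALSE]
    cnt <- vapply(bases, function(b) colSums(sub == b), numeric(nc))
    if (nc == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, bases))
    n_t <- length(accs)
    other_def <- rowSums(counts_all - cnt)
    hits <- purrr::map_dfr(bases, function(b) {
      ok <- cnt[, b] == n_t &                       # taxon fixed for b
        (counts_all[, b] - cnt[, b]) == 0 &         # b absent outside taxon
        other_def == (n_total - n_t)                # all others defined
      if (!any(ok)) return(NULL)
      cols <- which(ok)
      others <- vapply(cols, function(cc) {
        oc <- counts_all[cc, ] - cnt[cc, ]
        paste(bases[oc > 0], collapse = ",")
      }, character(1))
      tibble::tibble(column = cols, taxon = tx, state = b, others = others)
    })
    hits
  })
  if (nrow(res) == 0L) {
    return(tibble::tibble(column = integer(), taxon = character(),
                          state = character(), others = character(),
                          kind = character()))
  }
  res$kind <- "species_specific_snp"
  dplyr::arrange(res, .data$column, .data$taxon)
}

#' Call insertion/deletion events
#'
#' Maximal runs of contiguous columns sharing an identical per-accession
#' gap/base presence pattern (with at least one gap) form single events.
#' When a taxon map is supplied, outgroup accessions are excluded and an
#' event is assigned to taxon T when the set of accessions bearing sequence
#' (or, symmetrically, bearing the gap) is exactly T's accession set; polarity
#' is `insertion` when exactly one taxon bears sequence, `deletion` when
#' exactly one taxon bears the gap, otherwise `unpolarized`. Events touching
#' the first or last alignment column are flagged `edge = TRUE`, since
#' terminal gaps often reflect amplicon length rather than biology.
#'
#' @param x A `dna_alignment`.
#' @param tm Optional taxon map; when given, only ingroup accessions enter the
#'   pattern and taxon assignment.
#' @return A tibble `start`, `end`, `length`, `taxon` (`NA` when the pattern
#'   matches no single taxon), `polarity`, `edge`, `sequence` (the bases
#'   carried by sequence-bearing accessions), `n_bearing`, `n_gapped`.
#' @export
call_indel_events <- function(x, tm = NULL) {
  m <- if (is.null(tm)) unclass(x) else ingroup_matrix(x, tm)
  presence <- m != "-"
  gap_cols <- which(colSums(!presence) > 0L)
  empty <- tibble::tibble(start = integer(), end = integer(), length = integer(),
                          taxon = character(), polarity = character(),
                          edge = logical(), sequence = character(),
                          n_bearing = integer(), n_gapped = integer())
  if (length(gap_cols) == 0L) return(empty)
  key <- apply(presence[, gap_cols, drop = FALSE], 2L, paste, collapse = "")
  new_run <- c(TRUE, diff(gap_cols) != 1L | key[-1L] != utils::head(key, -1L))
  run_id <- cumsum(new_run)
  taxon_sets <- NULL
  if (!is.null(tm)) {
    tm_in <- tm[!tm$outgroup & tm$accession %in% rownames(m), ]
    taxon_sets <- split(tm_in$accession, tm_in$taxon)
  }
  L <- ncol(m)
  purrr::map_dfr(split(gap_cols, run_id), function(cols) {
    pres <- presence[, cols[1L]]
    bearing <- rownames(m)[pres]
    gapped <- rownames(m)[!pres]
    taxon <- NA_character_
    polarity <- "unpolarized"
    if (!is.null(taxon_sets)) {
      match_bearing <- names(which(vapply(taxon_sets, setequal, logical(1), bearing)))
      match_gapped <- names(which(vapply(taxon_sets, setequal, logical(1), gapped)))
      if (length(match_bearing) == 1L) {
        taxon <- match_bearing
        polarity <- "insertion"
      } else if (length(match_gapped) == 1L) {
        taxon <- match_gapped
        polarity <- "deletion"
      }
    }
    seq <- if (length(bearing)) paste(m[bearing[1L], cols], collapse = "") else ""
    tibble::tibble(
      start = cols[1L], end = cols[length(cols)],
      length = length(cols), taxon = taxon, polarity = polarity,
      edge = cols[1L] == 1L || cols[length(cols)] == L,
      sequence = seq,
      n_bearing = length(bearing), n_gapped = length(gapped)
    )
  })
}

#' Tabulate diagnostic markers in locus-local coordinates
#'
#' Combines SNP diagnostic sites and indel events into one report table.
#' When a `partition` is given, positions are interpreted on the concatenated
#' alignment and mapped back to per-locus coordinates.
#'
#' @param sites Tibble from [call_species_specific_snps()].
#' @param indels Tibble from [call_indel_events()] (species-specific events,
#'   i.e. rows with a `taxon`, are reported; others are dropped).
#' @param partition Optional tibble `locus`/`start`/`end` from [concatenate()].
#' @param locus Locus label used when `partition` is `NULL` (single locus).
#' @return A tibble `locus`, `position` (single position or `"start-end"`
#'   range), `taxon`, `kind`, `state`, `others`.
#' @export
diagnostic_report <- function(sites, indels = NULL, partition = NULL,
                              locus = "locus") {
  locate <- function(pos) {
    if (is.null(partition)) {
      return(list(locus = locus, local = pos))
    }
    i <- which(partition$start <= pos & pos <= partition$end)
    if (length(i) != 1L) {
      stop("coordinate error: position ", pos, " outside partition",
           call. = FALSE)
    }
    list(locus = partition$locus[i], local = pos - partition$start[i] + 1L)
  }
  rows <- list()
  if (!is.null(sites) && nrow(sites)) {
    rows <- c(rows, purrr::pmap(sites, function(column, taxon, state, others,
                                                kind, ...) {
      at <- locate(column)
      tibble::tibble(locus = at$locus, position = as.character(at$local),
                     taxon = taxon, kind = kind, state = state, others = others)
    }))
  }
  if (!is.null(indels) && nrow(indels)) {
    sp <- indels[!is.na(indels$taxon), , drop = FALSE]
    rows <- c(rows, purrr::pmap(sp, function(start, end, length, taxon,
                                             polarity, edge, sequence, ...) {
      a <- locate(start); b <- locate(end)
      if (a$locus != b$locus) {
        stop("coordinate error: indel ", start, "-", end,
             " spans a locus boundary", call. = FALSE)
      }
      tibble::tibble(locus = a$locus,
                     position = paste0(a$local, "-", b$local),
                     taxon = taxon, kind = polarity, state = sequence,
                     others = "-")
    }))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(locus = character(), position = character(),
                          taxon = character(), kind = character(),
                          state = character(), others = character()))
  }
  dplyr::bind_rows(rows)
}
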