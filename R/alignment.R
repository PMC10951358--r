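#' Multiple sequence alignment container
#'
#' A `dna_alignment` is a character matrix of aligned, equal-length sequences:
#' one row per accession (rownames carry the accession identifiers), one column
#' per alignment position. Columns are addressed 1-based and inclusive
#' throughout the package. Allowed characters are the four bases `A`, `C`, `G`,
#' `T`, the gap `-`, and `N` plus the IUPAC ambiguity codes; anything outside
#' `A/C/G/T` is kept verbatim but treated as missing by downstream analyses.
#' `.` is not a valid gap character.
#'
#' @param seqs A named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with accession rownames.
#' @param name Locus label attached to the alignment.
#' @return A `dna_alignment` object.
#' @examples
#' aln <- alignment(c(s1 = "ACGT", s2 = "ACGA"), name = "demo")
#' aln_length(aln)
#' accessions(aln)
#' @export
alignment <- function(seqs, name = "locus") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      stop("sequences must be named by accession", call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  out <- structure(m, class = c("dna_alignment", class(m)), locus = name)
  validate_alignment(out)
  out
}

ALN_ALLOWED <- c("A", "C", "G", "T", "-", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

validate_alignment <- function(x) {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L) {
    stop("format error: alignment must have at least one sequence and one column",
         call. = FALSE)
  }
  acc <- rownames(x)
  if (is.null(acc) || anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    stop("identifier error: duplicate accession(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(x)), ALN_ALLOWED)
  if (length(bad)) {
    stop("format error: invalid alignment character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @rdname alignment
#' @param x A `dna_alignment`.
#' @export
aln_length <- function(x) ncol(x)

#' @rdname alignment
#' @export
accessions <- function(x) rownames(x)

#' @rdname alignment
#' @export
locus_name <- function(x) attr(x, "locus")

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> locus '", locus_name(x), "': ",
      nrow(x), " accessions x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' Read a gapped FASTA alignment
#'
#' Reads one FASTA file into a [alignment()] object. The accession identifier
#' is the first whitespace-delimited token of each header (GenBank export
#' convention); record order is preserved and characters are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param name Locus label; defaults to the file name without extension.
#' @return A `dna_alignment`.
#' @export
read_fasta_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0L) {
    stop("format error: no FASTA records in ", path, call. = FALSE)
  }
  seqs <- vapply(as.character(recs), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  names(seqs) <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("alignment-shape error: records in ", basename(path),
         " have unequal lengths (", paste(unique(lens), collapse = ", "), ")",
         call. = FALSE)
  }
  alignment(seqs, name = name)
}

#' Write an alignment as FASTA
#'
#' One record per accession, original order, standard sequential FASTA.
#'
#' @param x A `dna_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path) {
  validate_alignment(x)
  if (nrow(x) == 0L) stop("format error: empty accession list", call. = FALSE)
  bin <- ape::as.DNAbin(unclass(x))
  ape::write.FASTA(bin, file = path)
  invisible(path)
}

#' Read and validate a sample-to-taxon map
#'
#' The taxon map links each accession to its taxon label and flags outgroup
#' accessions used for rooting. The file is delimited text (TSV or CSV) with
#' columns `accession`, `taxon` and optionally `outgroup` (0/1).
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `accession` (character), `taxon` (character)
#'   and `outgroup` (logical).
#' @export
read_taxon_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          trim_ws = TRUE, col_types = readr::cols(.default = "c"))
  taxon_map(df)
}

#' Construct a taxon map from a data frame
#'
#' @param df Data frame with columns `accession`, `taxon`, optional `outgroup`.
#' @return A validated tibble (`accession`, `taxon`, `outgroup`).
#' @export
taxon_map <- function(df) {
  if (!all(c("accession", "taxon") %in% names(df))) {
    stop("format error: taxon map needs 'accession' and 'taxon' columns",
         call. = FALSE)
  }
  tm <- tibble::tibble(
    accession = as.character(df$accession),
    taxon = as.character(df$taxon),
    outgroup = if ("outgroup" %in% names(df)) {
      as.logical(as.integer(df$outgroup))
    } else FALSE
  )
  tm$outgroup[is.na(tm$outgroup)] <- FALSE
  if (anyDuplicated(tm$accession)) {
    stop("identifier error: duplicate accession(s) in taxon map: ",
         paste(unique(tm$accession[duplicated(tm$accession)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tm$taxon) | tm$taxon == "")) {
    stop("format error: missing taxon field", call. = FALSE)
  }
  if (sum(!tm$outgroup) < 1L || length(unique(tm$taxon[!tm$outgroup])) < 1L) {
    stop("format error: taxon map needs at least one ingroup taxon",
         call. = FALSE)
  }
  tm
}

#' @rdname taxon_map
#' @param tm A taxon map tibble.
#' @export
outgroup_accessions <- function(tm) tm$accession[tm$outgroup]

#' @rdname taxon_map
#' @export
ingroup_taxa <- function(tm) sort(unique(tm$taxon[!tm$outgroup]))

#' Concatenate per-locus alignments
#'
#' Joins the sequences of each accession across loci, in the given locus order,
#' and records where each locus lands on the combined alignment. Under the
#' default `intersection` policy, accessions absent from some locus are dropped
#' with a warning; under `strict`, all loci must share an identical accession
#' set.
#'
#' @param alignments A list of `dna_alignment` objects (length >= 2, or 1+ for
#'   pipeline use).
#' @param accession_policy `"intersection"` (default) or `"strict"`.
#' @param name Locus label for the combined alignment.
#' @return A list with elements `alignment` (the combined `dna_alignment`) and
#'   `partition`, a tibble `locus`/`start`/`end` (1-based, inclusive) tiling
#'   the combined columns.
#' @export
concatenate <- function(alignments, accession_policy = c("intersection", "strict"),
                        name = "concatenated") {
  accession_policy <- match.arg(accession_policy)
  stopifnot(length(alignments) >= 1L)
  acc_sets <- lapply(alignments, accessions)
  if (accession_policy == "strict") {
    ref <- acc_sets[[1L]]
    same <- vapply(acc_sets, function(a) setequal(a, ref), logical(1))
    if (!all(same)) {
      stop("composition error: strict policy requires identical accession sets",
           call. = FALSE)
    }
    keep <- ref
  } else {
    keep <- Reduce(intersect, acc_sets)
    if (length(keep) == 0L) {
      stop("composition error: no accession shared by all loci", call. = FALSE)
    }
    dropped <- setdiff(unique(unlist(acc_sets)), keep)
    if (length(dropped)) {
      warning("dropping accession(s) absent from some loci: ",
              paste(sort(dropped), collapse = ", "), call. = FALSE)
    }
  }
  mats <- lapply(alignments, function(a) a[keep, , drop = FALSE])
  combined <- do.call(cbind, mats)
  lens <- vapply(alignments, aln_length, integer(1))
  ends <- cumsum(lens)
  part <- tibble::tibble(
    locus = vapply(alignments, locus_name, character(1)),
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = as.integer(ends)
  )
  list(alignment = alignment(combined, name = name), partition = part)
}

#' Write a locus partition table
#'
#' @param partition Tibble `locus`/`start`/`end`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(partition, path)
  invisible(path)
}
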