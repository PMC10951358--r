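#' Configure a synthetic multi-locus authentication dataset
#'
#' Describes a study design of several ingroup taxa with multiple accessions
#' each, one outgroup accession, and per-locus planted diagnostic variants:
#' fixed species-specific SNPs, and insertion/deletion events realised as
#' contiguous gap blocks. Coordinates are final alignment coordinates: an
#' insertion occupies a pre-allocated block of columns where only the target
#' taxon carries bases, so planted coordinates never shift.
#'
#' @param taxa Character vector of ingroup taxon labels.
#' @param accessions_per_taxon Accessions per ingroup taxon (single integer or
#'   one per taxon).
#' @param loci Named integer vector of locus alignment lengths (bp).
#' @param planted_snps Tibble/data frame `locus`, `column`, `taxon`, `state`
#'   (`NA` state = pick a deterministic non-ancestral base), or `NULL`.
#' @param planted_indels Tibble `locus`, `start`, `length`, `taxon`, `type`
#'   (`"insertion"` or `"deletion"`), optional `sequence` for insertions, or
#'   `NULL`.
#' @param background_rate Per-site per-accession substitution probability
#'   within taxa (intra-taxon noise).
#' @param outgroup_divergence Per-site substitution probability separating the
#'   outgroup from the ancestral sequence.
#' @param outgroup_label Taxon label of the outgroup.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   output.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(taxa, accessions_per_taxon, loci,
                              planted_snps = NULL, planted_indels = NULL,
                              background_rate = 0.002,
                              outgroup_divergence = 0.05,
                              outgroup_label = "Valeriana officinalis",
                              seed = 1L) {
  if (length(accessions_per_taxon) == 1L) {
    accessions_per_taxon <- rep(as.integer(accessions_per_taxon), length(taxa))
  }
  stopifnot(length(accessions_per_taxon) == length(taxa),
            all(accessions_per_taxon >= 1L),
            !is.null(names(loci)), all(loci >= 1L))
  if (background_rate < 0 || background_rate > 1 ||
      outgroup_divergence < 0 || outgroup_divergence > 1) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  snps <- if (is.null(planted_snps)) {
    tibble::tibble(locus = character(), column = integer(),
                   taxon = character(), state = character())
  } else tibble::as_tibble(planted_snps)
  indels <- if (is.null(planted_indels)) {
    tibble::tibble(locus = character(), start = integer(), length = integer(),
                   taxon = character(), type = character(),
                   sequence = character())
  } else {
    pi <- tibble::as_tibble(planted_indels)
    if (!"sequence" %in% names(pi)) pi$sequence <- NA_character_
    pi
  }
  cfg <- list(taxa = taxa, accessions_per_taxon = accessions_per_taxon,
              loci = loci, planted_snps = snps, planted_indels = indels,
              background_rate = background_rate,
              outgroup_divergence = outgroup_divergence,
              outgroup_label = outgroup_label, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  for (lc in names(cfg$loci)) {
    L <- cfg$loci[[lc]]
    sn <- cfg$planted_snps[cfg$planted_snps$locus == lc, ]
    ind <- cfg$planted_indels[cfg$planted_indels$locus == lc, ]
    if (nrow(sn) && (min(sn$column) < 1L || max(sn$column) > L)) {
      stop("config error: planted SNP outside locus ", lc, call. = FALSE)
    }
    if (nrow(ind) && (min(ind$start) < 1L || max(ind$start + ind$length - 1L) > L)) {
      stop("config error: planted indel outside locus ", lc, call. = FALSE)
    }
    used <- c(sn$column,
              unlist(purrr::map2(ind$start, ind$length, ~ .x:(.x + .y - 1L))))
    if (anyDuplicated(used)) {
      stop("config error: overlapping planted features in locus ", lc,
           call. = FALSE)
    }
    bad_taxa <- setdiff(c(sn$taxon, ind$taxon), cfg$taxa)
    if (length(bad_taxa)) {
      stop("config error: planted feature for unknown taxon ",
           paste(bad_taxa, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")

#' Simulate a multi-locus, multi-accession dataset with known truth
#'
#' Per locus: a random ancestral sequence is drawn (uniform over A/C/G/T) and
#' copied to every ingroup accession; planted SNPs fix the target taxon's
#' state at their columns (all other accessions keep the ancestral base);
#' planted insertions leave every non-target accession gapped over their
#' block, planted deletions gap only the target taxon; background
#' substitutions are then applied i.i.d. per ingroup accession at
#' `background_rate`, avoiding all planted columns; the outgroup is derived
#' from the ancestor at `outgroup_divergence` (gapped at insertion blocks).
#'
#' @param cfg A [simulation_config()].
#' @return A list: `alignments` (named list of `dna_alignment`), `taxon_map`
#'   (tibble), and `truth` with elements `snps` and `indels` recording the
#'   realised planted features in final alignment coordinates.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  n_tax <- length(cfg$taxa)
  acc_by_taxon <- lapply(seq_len(n_tax), function(i) {
    sprintf("S%02d_%02d", i, seq_len(cfg$accessions_per_taxon[i]))
  })
  names(acc_by_taxon) <- cfg$taxa
  out_acc <- "OUT01"
  tm <- tibble::tibble(
    accession = c(unlist(acc_by_taxon), out_acc),
    taxon = c(rep(cfg$taxa, cfg$accessions_per_taxon), cfg$outgroup_label),
    outgroup = c(rep(FALSE, sum(cfg$accessions_per_taxon)), TRUE)
  )

  truth_snps <- list()
  truth_indels <- list()
  alignments <- list()

  for (lc in names(cfg$loci)) {
    L <- as.integer(cfg$loci[[lc]])
    anc <- sample(BASES, L, replace = TRUE)
    ingroup <- unlist(acc_by_taxon)
    m <- matrix(rep(anc, each = length(ingroup)), nrow = length(ingroup),
                dimnames = list(ingroup, NULL))

    sn <- cfg$planted_snps[cfg$planted_snps$locus == lc, ]
    if (nrow(sn)) {
      sn$ancestral <- anc[sn$column]
      sn$state <- ifelse(is.na(sn$state),
                         BASES[(match(sn$ancestral, BASES)) %% 4L + 1L],
                         sn$state)
      for (k in seq_len(nrow(sn))) {
        m[acc_by_taxon[[sn$taxon[k]]], sn$column[k]] <- sn$state[k]
      }
      truth_snps[[lc]] <- tibble::tibble(
        locus = lc, column = as.integer(sn$column), taxon = sn$taxon,
        state = sn$state, ancestral = sn$ancestral
      )
    }

    ind <- cfg$planted_indels[cfg$planted_indels$locus == lc, ]
    indel_cols <- integer()
    if (nrow(ind)) {
      realized <- list()
      for (k in seq_len(nrow(ind))) {
        cols <- ind$start[k]:(ind$start[k] + ind$length[k] - 1L)
        indel_cols <- c(indel_cols, cols)
        target <- acc_by_taxon[[ind$taxon[k]]]
        if (ind$type[k] == "insertion") {
          seqk <- if (is.na(ind$sequence[k])) {
            paste(sample(BASES, length(cols), replace = TRUE), collapse = "")
          } else toupper(ind$sequence[k])
          m[, cols] <- "-"
          m[target, cols] <- matrix(rep(strsplit(seqk, "")[[1L]],
                                        each = length(target)),
                                    nrow = length(target))
        } else {
          seqk <- paste(anc[cols], collapse = "")
          m[target, cols] <- "-"
        }
        realized[[k]] <- tibble::tibble(
          locus = lc, start = as.integer(ind$start[k]),
          end = as.integer(ind$start[k] + ind$length[k] - 1L),
          length = as.integer(ind$length[k]), taxon = ind$taxon[k],
          type = ind$type[k], sequence = seqk
        )
      }
      truth_indels[[lc]] <- dplyr::bind_rows(realized)
    }

    protected <- c(if (nrow(sn)) sn$column else integer(), indel_cols)
    mutable <- setdiff(seq_len(L), protected)
    if (cfg$background_rate > 0 && length(mutable)) {
      for (a in ingroup) {
        hit <- mutable[stats::runif(length(mutable)) < cfg$background_rate]
        if (length(hit)) {
          m[a, hit] <- vapply(m[a, hit], function(b) {
            sample(setdiff(BASES, b), 1L)
          }, character(1))
        }
      }
    }

    og <- anc
    # columns belonging to insertion blocks are gapped in the outgroup
    ins_cols <- integer()
    if (nrow(ind)) {
      for (k in seq_len(nrow(ind))) {
        if (ind$type[k] == "insertion") {
          ins_cols <- c(ins_cols, ind$start[k]:(ind$start[k] + ind$length[k] - 1L))
        }
      }
    }
    div_cols <- setdiff(seq_len(L), ins_cols)
    if (cfg$outgroup_divergence > 0) {
      hit <- div_cols[stats::runif(length(div_cols)) < cfg$outgroup_divergence]
      if (length(hit)) {
        og[hit] <- vapply(og[hit], function(b) sample(setdiff(BASES, b), 1L),
                          character(1))
      }
    }
    og[ins_cols] <- "-"
    m <- rbind(m, matrix(og, nrow = 1L, dimnames = list(out_acc, NULL)))
    alignments[[lc]] <- alignment(m, name = lc)
  }

  list(
    alignments = alignments,
    taxon_map = tm,
    truth = list(
      snps = if (length(truth_snps)) dplyr::bind_rows(truth_snps) else
        tibble::tibble(locus = character(), column = integer(),
                       taxon = character(), state = character(),
                       ancestral = character()),
      indels = if (length(truth_indels)) dplyr::bind_rows(truth_indels) else
        tibble::tibble(locus = character(), start = integer(), end = integer(),
                       length = integer(), taxon = character(),
                       type = character(), sequence = character())
    )
  )
}

#' Evenly spaced private-SNP plan for a simulated locus
#'
#' Assigns `per_taxon` fixed private SNP columns to each taxon, evenly spread
#' across the locus, for use as `planted_snps` in [simulation_config()].
#' States are left `NA` (chosen relative to the simulated ancestor).
#'
#' @param taxa Character vector of taxon labels.
#' @param locus Locus name.
#' @param locus_length Locus length in columns.
#' @param per_taxon Private SNPs per taxon (default 3).
#' @return A tibble `locus`, `column`, `taxon`, `state`.
#' @export
private_snp_plan <- function(taxa, locus, locus_length, per_taxon = 3L) {
  n <- length(taxa) * per_taxon
  if (n > locus_length) stop("config error: more SNPs than columns", call. = FALSE)
  cols <- round(seq(1L, locus_length, length.out = n + 2L))[2:(n + 1L)]
  tibble::tibble(
    locus = locus,
    column = as.integer(cols),
    taxon = rep(taxa, each = per_taxon),
    state = NA_character_
  )
}
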