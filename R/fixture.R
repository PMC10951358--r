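#' Deterministic worked-example dataset of diagnostic markers
#'
#' Builds a small four-locus alignment set for six ingroup taxa plus a
#' *Valeriana officinalis* outgroup, encoding at exact alignment positions the
#' species-specific markers reported for medicinal *Patrinia*: six
#' substitutions private to *P. scabiosifolia*, five to *P. villosa* subsp.
#' *punctifolia*, three to *P. scabra*, two to *P. heterophylla*, one
#' substitution plus a 24-bp private insertion (psaI-ycf4 columns 185-208,
#' sequence GAAGGGGTATGTTATTATTTTATT) to *P. villosa* subsp. *villosa*, and
#' none to *P. monandra*. The petA alignment additionally carries a
#' "substitution-like" state for *P. monandra* at column 24 where two
#' *P. villosa* accessions have leading gaps, so a correct caller must refuse
#' to report it. All other columns are invariant across the ingroup; the
#' outgroup differs from the backbone at regularly spaced columns so that
#' trees can be rooted. Locus lengths are atpB 430, petA 735, psaI-ycf4 340
#' and rpl2-rpl23 1090 bp.
#'
#' @return A list with `alignments` (named list of `dna_alignment` for atpB,
#'   petA, psaI-ycf4 and rpl2-rpl23) and `taxon_map`.
#' @examples
#' fx <- table2_fixture()
#' snps <- call_species_specific_snps(fx$alignments[["psaI-ycf4"]], fx$taxon_map)
#' @export
table2_fixture <- function() {
  taxa <- c(
    het = "Patrinia heterophylla",
    mon = "Patrinia monandra",
    sca = "Patrinia scabiosifolia",
    vil = "Patrinia villosa subsp. villosa",
    scb = "Patrinia scabra",
    pun = "Patrinia villosa subsp. punctifolia"
  )
  accs <- list(
    het = sprintf("HET%02d", 1:3),
    mon = sprintf("MON%02d", 1:3),
    sca = sprintf("SCA%02d", 1:4),
    vil = sprintf("VIL%02d", 1:5),
    scb = "SCB01",
    pun = "PUN01"
  )
  out_acc <- "VAL01"
  ingroup <- unlist(accs, use.names = FALSE)
  tm <- tibble::tibble(
    accession = c(ingroup, out_acc),
    taxon = c(rep(unname(taxa), lengths(accs)), "Valeriana officinalis"),
    outgroup = c(rep(FALSE, length(ingroup)), TRUE)
  )

  # invariant backbone: fixed repeating pattern, no randomness
  backbone <- function(L) rep(c("A", "T", "G", "C", "T", "A", "C", "G"),
                              length.out = L)

  build <- function(name, L, plant) {
    bb <- backbone(L)
    m <- matrix(rep(bb, each = length(ingroup)), nrow = length(ingroup),
                dimnames = list(ingroup, NULL))
    og <- bb
    shift <- seq(25L, L, by = 50L)  # outgroup divergence, away from markers
    og[shift] <- c(A = "G", T = "C", G = "A", C = "T")[og[shift]]
    m <- rbind(m, matrix(og, nrow = 1L, dimnames = list(out_acc, NULL)))
    plant(m)
  }

  set_site <- function(m, col, taxon_key, state, others) {
    m[setdiff(ingroup, accs[[taxon_key]]), col] <- others
    m[accs[[taxon_key]], col] <- state
    m[out_acc, col] <- others
    m
  }

  atpB <- build("atpB", 430L, function(m) {
    m <- set_site(m, 41L, "pun", "G", "A")
    m <- set_site(m, 83L, "scb", "A", "G")
    m <- set_site(m, 212L, "het", "C", "A")
    m
  })

  petA <- build("petA", 735L, function(m) {
    # near-terminal "substitution-like" column: two villosa accessions have
    # leading gaps, which disqualifies the monandra state as a diagnostic SNP
    m <- set_site(m, 24L, "mon", "A", "G")
    m[c("VIL04", "VIL05"), 1:30] <- "-"
    m <- set_site(m, 194L, "het", "G", "T")
    m <- set_site(m, 221L, "sca", "C", "T")
    m <- set_site(m, 548L, "scb", "T", "C")
    m
  })

  psaI_ycf4 <- build("psaI-ycf4", 340L, function(m) {
    m <- set_site(m, 89L, "sca", "G", "T")
    m <- set_site(m, 162L, "scb", "G", "A")
    ins <- strsplit("GAAGGGGTATGTTATTATTTTATT", "")[[1L]]
    stopifnot(length(ins) == 24L)
    m[, 185:208] <- "-"
    m[accs$vil, 185:208] <- matrix(rep(ins, each = length(accs$vil)),
                                   nrow = length(accs$vil))
    m
  })

  rpl2_rpl23 <- build("rpl2-rpl23", 1090L, function(m) {
    m <- set_site(m, 141L, "sca", "A", "T")
    m <- set_site(m, 165L, "pun", "G", "C")
    m <- set_site(m, 173L, "vil", "C", "G")
    m <- set_site(m, 264L, "pun", "G", "T")
    m <- set_site(m, 265L, "pun", "T", "A")
    m <- set_site(m, 266L, "pun", "T", "A")
    m <- set_site(m, 336L, "sca", "C", "G")
    m <- set_site(m, 337L, "sca", "C", "T")
    m <- set_site(m, 362L, "sca", "C", "T")
    m
  })

  list(
    alignments = list(
      atpB = alignment(atpB, name = "atpB"),
      petA = alignment(petA, name = "petA"),
      `psaI-ycf4` = alignment(psaI_ycf4, name = "psaI-ycf4"),
      `rpl2-rpl23` = alignment(rpl2_rpl23, name = "rpl2-rpl23")
    ),
    taxon_map = tm
  )
}
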