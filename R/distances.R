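#' Pairwise substitution counts between two aligned sequences
#'
#' Compares two equal-length gapped sequences at the positions where both
#' carry an unambiguous base (pairwise deletion). Transitions are A<->G and
#' C<->T; all other differences are transversions. The GC fraction pools the
#' compared sites of both sequences, matching the symmetric pooled-frequency
#' convention of the Tamura 3-parameter model.
#'
#' @param a,b Character vectors of single characters (or strings) of equal
#'   aligned length.
#' @return A list with `L` (compared sites), `P` (transition proportion),
#'   `Q` (transversion proportion) and `theta` (pooled GC fraction). When no
#'   site is comparable, `L = 0` and the proportions are `NA`.
#' @export
pairwise_counts <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) {
    stop("input error: sequences must have equal aligned length", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  L <- sum(ok)
  if (L == 0L) {
    return(list(L = 0L, P = NA_real_, Q = NA_real_, theta = NA_real_))
  }
  aa <- a[ok]; bb <- b[ok]
  diff <- aa != bb
  ts <- diff & ((aa == "A" & bb == "G") | (aa == "G" & bb == "A") |
                  (aa == "C" & bb == "T") | (aa == "T" & bb == "C"))
  list(
    L = L,
    P = sum(ts) / L,
    Q = sum(diff & !ts) / L,
    theta = (sum(aa %in% c("G", "C")) + sum(bb %in% c("G", "C"))) / (2 * L)
  )
}

#' Evolutionary distance from pairwise counts
#'
#' Closed-form distances from transition/transversion proportions `P` and `Q`
#' (and pooled GC content `theta` for T3P):
#' \itemize{
#'   \item `p`: \eqn{d = P + Q};
#'   \item `jc69`: \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)};
#'   \item `k2p`: \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)};
#'   \item `t3p`: \eqn{d = -h\ln(1 - P/h - Q) - \frac{1}{2}(1-h)\ln(1 - 2Q)}
#'     with \eqn{h = 2\theta(1-\theta)}.
#' }
#' With a gamma shape `a`, each \eqn{-\ln(w)} term is replaced by
#' \eqn{a(w^{-1/a} - 1)}, the usual rate-heterogeneity correction (the plain
#' p-distance has no log term and is returned unchanged). A non-positive log
#' argument means the pair is saturated for the model; the function then
#' returns `NA_real_` rather than throwing, so matrix assembly can flag it.
#'
#' @param counts Output of [pairwise_counts()].
#' @param model One of `"p"`, `"jc69"`, `"k2p"`, `"t3p"`.
#' @param gamma_shape Positive gamma shape parameter, or `NULL` for no rate
#'   correction.
#' @return The distance in substitutions per site, or `NA_real_` if saturated
#'   or no site was comparable.
#' @export
seq_distance <- function(counts, model = c("p", "jc69", "k2p", "t3p"),
                         gamma_shape = NULL) {
  model <- match.arg(model)
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop("input error: gamma_shape must be positive", call. = FALSE)
  }
  if (counts$L == 0L || is.na(counts$P)) return(NA_real_)
  P <- counts$P; Q <- counts$Q
  p <- P + Q
  # -ln(w), optionally gamma-corrected
  nl <- function(w) {
    if (w <= 0) return(NA_real_)
    if (is.null(gamma_shape)) -log(w) else gamma_shape * (w^(-1 / gamma_shape) - 1)
  }
  switch(model,
    p = p,
    jc69 = (3 / 4) * nl(1 - (4 / 3) * p),
    k2p = {
      d <- (1 / 2) * nl(1 - 2 * P - Q) + (1 / 4) * nl(1 - 2 * Q)
      d
    },
    t3p = {
      th <- counts$theta
      h <- 2 * th * (1 - th)
      if (h <= 0) return(seq_distance(counts, "jc69", gamma_shape))
      h * nl(1 - P / h - Q) + (1 / 2) * (1 - h) * nl(1 - 2 * Q)
    }
  )
}

#' Pairwise distance matrix for an alignment
#'
#' Applies [pairwise_counts()] and [seq_distance()] to every sequence pair
#' under pairwise deletion. Saturated pairs (non-finite model distance) are
#' assigned twice the largest finite distance and flagged, which keeps tree
#' building runnable while surfacing the problem.
#'
#' @param x A `dna_alignment` with at least 2 sequences.
#' @param model Distance model (see [seq_distance()]).
#' @param gamma_shape Optional positive gamma shape.
#' @return A symmetric numeric matrix with zero diagonal and accession
#'   dimnames, with attributes `model`, `gamma_shape` and `saturated` (a
#'   logical matrix flagging replaced entries).
#' @export
distance_matrix <- function(x, model = c("p", "jc69", "k2p", "t3p"),
                            gamma_shape = NULL) {
  model <- match.arg(model)
  n <- nrow(x)
  if (n < 2L) stop("input error: need at least 2 sequences", call. = FALSE)
  acc <- accessions(x)
  d <- matrix(0, n, n, dimnames = list(acc, acc))
  sat <- matrix(FALSE, n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- pairwise_counts(x[i, ], x[j, ])
      if (cnt$L == 0L) {
        stop("matrix error: no comparable site between ", acc[i], " and ",
             acc[j], call. = FALSE)
      }
      dij <- seq_distance(cnt, model, gamma_shape)
      if (is.na(dij)) {
        sat[i, j] <- sat[j, i] <- TRUE
        dij <- NA_real_
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (any(sat)) {
    repl <- 2 * max(d[is.finite(d)], 0)
    d[is.na(d)] <- repl
    warning(sum(sat) / 2, " saturated pair(s) set to twice the largest ",
            "finite distance", call. = FALSE)
  }
  structure(d, model = model, gamma_shape = gamma_shape, saturated = sat)
}

#' Write a distance matrix as square TSV
#'
#' @param d Matrix from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(d)), rownames = "accession")
  readr::write_tsv(df, path)
  invisible(path)
}
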