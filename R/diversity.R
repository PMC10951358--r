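#' Nucleotide diversity of alignment columns
#'
#' Computes nucleotide diversity (pi), the mean per-site proportion of
#' pairwise differences among sequences. A column is *usable* only when every
#' sequence carries an unambiguous base (`A`, `C`, `G` or `T`) there: any gap
#' or ambiguity code excludes the whole column. Pi is the per-column mean over
#' the `choose(n, 2)` sequence pairs, averaged over usable columns.
#'
#' @param x A `dna_alignment` with at least 2 sequences.
#' @param columns Integer vector of 1-based columns to use; defaults to all.
#' @return A single number, or `NA_real_` when no column is usable.
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "ACGA", c = "ACTA"))
#' nucleotide_diversity(aln)  # 1/3
#' @export
nucleotide_diversity <- function(x, columns = seq_len(aln_length(x))) {
  n <- nrow(x)
  if (n < 2L) stop("input error: need at least 2 sequences", call. = FALSE)
  if (length(columns) == 0L) return(NA_real_)
  if (min(columns) < 1L || max(columns) > ncol(x)) {
    stop("input error: columns out of bounds", call. = FALSE)
  }
  sub <- x[, columns, drop = FALSE]
  per_col <- column_mismatch_fraction(sub)
  usable <- !is.na(per_col)
  if (!any(usable)) return(NA_real_)
  mean(per_col[usable])
}

# Per-column mean pairwise difference over the four bases; NA where any
# sequence has a gap or ambiguity. Uses base counts: for counts k_b over a
# column of n defined bases, #matching pairs = sum choose(k_b, 2).
column_mismatch_fraction <- function(m) {
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  defined <- rowSums(counts)
  same <- rowSums(counts * (counts - 1) / 2)
  out <- (npairs - same) / npairs
  out[defined < n] <- NA_real_
  out
}

#' Sliding-window nucleotide diversity
#'
#' Places fixed-length windows on alignment columns starting at 1, 1 + step,
#' 1 + 2 step, ...; only full-length windows are emitted, so trailing partial
#' windows are dropped. Window coordinates are in alignment space (gap columns
#' count toward the span) while pi within a window uses only its gap-free,
#' ambiguity-free columns.
#'
#' @param x A `dna_alignment`.
#' @param window Window length in alignment columns (default 600).
#' @param step Step between window starts (default 200).
#' @return A tibble with columns `start`, `end`, `usable_sites`, `pi`, one row
#'   per window, carrying class `window_pi`.
#' @export
sliding_window_pi <- function(x, window = 600L, step = 200L) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("input error: window and step must be >= 1",
                                     call. = FALSE)
  L <- aln_length(x)
  if (window > L) stop("input error: window (", window,
                       ") exceeds alignment length (", L, ")", call. = FALSE)
  if (nrow(x) < 2L) stop("input error: need at least 2 sequences", call. = FALSE)
  starts <- seq.int(1L, L - window + 1L, by = step)
  per_col <- column_mismatch_fraction(x)
  res <- lapply(starts, function(s) {
    v <- per_col[s:(s + window - 1L)]
    ok <- !is.na(v)
    c(usable = sum(ok), pi = if (any(ok)) mean(v[ok]) else NA_real_)
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(
    start = starts,
    end = starts + window - 1L,
    usable_sites = as.integer(res[, "usable"]),
    pi = res[, "pi"]
  )
  class(out) <- c("window_pi", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Call divergence hotspot regions from windowed diversity
#'
#' Selects windows whose pi strictly exceeds `threshold` and merges
#' overlapping or book-ended selected windows into regions. Windows with
#' undefined pi (no usable site) are excluded with a warning.
#'
#' @param windows A tibble from [sliding_window_pi()] (sorted by `start`).
#' @param threshold Diversity threshold (default 0.05); membership is
#'   `pi > threshold`.
#' @return A tibble `start`, `end`, `max_pi`, `window_count`, one row per
#'   merged region, sorted by `start`.
#' @export
call_hotspots <- function(windows, threshold = 0.05) {
  if (nrow(windows) == 0L) return(empty_hotspots())
  if (is.unsorted(windows$start)) {
    stop("input error: windows must be sorted by start", call. = FALSE)
  }
  if (anyNA(windows$pi)) {
    warning(sum(is.na(windows$pi)),
            " window(s) with undefined pi excluded from hotspot calling",
            call. = FALSE)
  }
  sel <- windows[!is.na(windows$pi) & windows$pi > threshold, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty_hotspots())
  # merge overlapping/book-ended intervals
  grp <- cumsum(c(1L, as.integer(sel$start[-1L] > utils::head(sel$end, -1L) + 1L)))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sel), .grp = grp),
    start = min(.data$start),
    end = max(.data$end),
    max_pi = max(.data$pi),
    window_count = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(dplyr::select(out, -".grp"), .data$start)
}

empty_hotspots <- function() {
  tibble::tibble(start = integer(), end = integer(),
                 max_pi = double(), window_count = integer())
}

#' Plot a sliding-window diversity scan
#'
#' Line plot of window pi against window midpoint, with the hotspot threshold
#' drawn and above-threshold regions shaded.
#'
#' @param object A `window_pi` tibble from [sliding_window_pi()].
#' @param threshold Threshold line and hotspot shading (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_pi <- function(object, threshold = 0.05, ...) {
  hs <- call_hotspots(object, threshold)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$pi)) +
    ggplot2::geom_line(colour = "grey30", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Alignment position (window midpoint)",
                  y = expression(pi)) +
    ggplot2::theme_minimal()
  if (nrow(hs)) {
    p <- p + ggplot2::geom_rect(
      data = hs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.1
    )
  }
  p
}
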