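## GC-ratio coding-potential statistics.

#' GC ratio of DNA sequences
#'
#' Computes (G + C) / (G + C + A + T) per sequence. Characters outside
#' A/C/G/T (e.g. the ambiguity code N) are excluded from both numerator and
#' denominator; lowercase (softmasked) bases count as their uppercase
#' equivalents.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector of GC ratios in `[0, 1]`.
#' @examples
#' gc_ratio(c("ATGC", "GGCC", "ATNAT"))
#' @export
gc_ratio <- function(sequence) {
  s <- toupper(as.character(sequence))
  gc <- nchar(s) - nchar(gsub("[GC]", "", s))
  at <- nchar(s) - nchar(gsub("[AT]", "", s))
  den <- gc + at
  if (any(den == 0))
    stop("undefined GC ratio: sequence contains no unambiguous A/C/G/T base")
  gc / den
}

.require_catalog <- function(catalog, need = c("orf_class", "gc_ratio")) {
  miss <- setdiff(need, names(catalog))
  if (length(miss))
    stop("catalogue is missing column(s): ", paste(miss, collapse = ", "))
  invisible(catalog)
}

#' Per-class GC and length summary of an ORF catalogue
#'
#' One row per ORF class present in the catalogue, in the canonical class
#' order of [ORF_CLASSES], with count, mean and sd of GC ratio, and mean and
#' median amino-acid length.
#'
#' @param catalog ORF catalogue data.frame with `orf_class`, `gc_ratio`
#'   and `aa_length` columns.
#' @return data.frame with columns `orf_class, n, mean_gc, sd_gc, mean_len,
#'   median_len`; zero rows for an empty catalogue.
#' @export
class_summary <- function(catalog) {
  .require_catalog(catalog, c("orf_class", "gc_ratio", "aa_length"))
  if (!nrow(catalog)) {
    return(data.frame(orf_class = character(), n = integer(),
                      mean_gc = numeric(), sd_gc = numeric(),
                      mean_len = numeric(), median_len = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(catalog, factor(catalog$orf_class,
                              levels = union(ORF_CLASSES,
                                             unique(catalog$orf_class))),
              drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(cl) {
    g <- sp[[cl]]
    data.frame(orf_class = cl, n = nrow(g),
               mean_gc = mean(g$gc_ratio), sd_gc = sd(g$gc_ratio),
               mean_len = mean(g$aa_length),
               median_len = median(g$aa_length),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of a class exceeding a GC threshold
#'
#' @param catalog ORF catalogue data.frame.
#' @param orf_class Class label to restrict to; must be present.
#' @param threshold GC ratio; membership is strict (`gc_ratio > threshold`).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_above <- function(catalog, orf_class, threshold) {
  .require_catalog(catalog)
  g <- catalog[catalog$orf_class %in% orf_class, , drop = FALSE]
  if (!nrow(g))
    stop("class '", orf_class, "' not present in catalogue")
  mean(g$gc_ratio > threshold)
}

#' Length-binned GC profile of an ORF catalogue
#'
#' Bins ORFs by amino-acid length into half-open bins `[lo, hi)` and reports
#' per-bin counts, mean GC, mean length and class composition. Empty bins
#' have `NA` (not zero) means.
#'
#' @param catalog ORF catalogue data.frame.
#' @param bin_edges Strictly increasing numeric vector of at least two edges
#'   covering every `aa_length` in the catalogue.
#' @return data.frame with one row per bin (`bin_lo, bin_hi, n, mean_gc,
#'   mean_len`) and a `composition` attribute: a class-by-bin count matrix.
#' @export
length_gc_profile <- function(catalog, bin_edges) {
  .require_catalog(catalog, c("orf_class", "gc_ratio", "aa_length"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L)
    stop("need at least two bin edges")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  if (nrow(catalog) &&
      (any(catalog$aa_length < lo[1L]) || any(catalog$aa_length >= hi[length(hi)])))
    stop("bin edges do not cover the catalogue's length range")
  idx <- findInterval(catalog$aa_length, bin_edges,
                      rightmost.closed = FALSE)
  out <- data.frame(bin_lo = lo, bin_hi = hi, n = 0L,
                    mean_gc = NA_real_, mean_len = NA_real_)
  comp <- matrix(0L, nrow = length(ORF_CLASSES), ncol = length(lo),
                 dimnames = list(ORF_CLASSES, sprintf("[%g,%g)", lo, hi)))
  for (b in seq_along(lo)) {
    g <- catalog[idx == b, , drop = FALSE]
    out$n[b] <- nrow(g)
    if (nrow(g)) {
      out$mean_gc[b] <- mean(g$gc_ratio)
      out$mean_len[b] <- mean(g$aa_length)
      tb <- table(factor(g$orf_class, levels = ORF_CLASSES))
      comp[, b] <- as.integer(tb)
    }
  }
  attr(out, "composition") <- comp
  out
}
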