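## Six-frame ORF discovery.
##
## Coordinates are 0-based half-open on the forward strand throughout; an ORF
## record spans start codon through stop codon inclusive, so
## end - start == 3 * (aa_length + 1).

STOP_CODONS <- c("TAA", "TAG", "TGA")

.empty_catalog <- function() {
  data.frame(orf_id = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             aa_length = integer(), nt_sequence = character(),
             orf_class = character(), parent_transcript = character(),
             gene_id = character(), gc_ratio = numeric(),
             stringsAsFactors = FALSE)
}

.check_dna <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s))
    stop("input error: sequence contains characters outside {A,C,G,T,N}")
  s
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Scan the three frames of an oriented sequence. Returns 0-based half-open
## coordinates in that orientation. One ORF per (frame, stop): the 5'-most
## ATG since the previous in-frame stop.
.scan_frames <- function(s) {
  L <- nchar(s)
  out <- vector("list", 3L)
  n_skipped_n <- 0L
  for (off in 0:2) {
    if (L - off < 6L) next   # need at least start + stop codon
    pos <- seq.int(off + 1L, L - 2L, by = 3L)
    cod <- substring(s, pos, pos + 2L)
    stop_i <- which(cod %in% STOP_CODONS)
    start_i <- which(cod == "ATG")
    if (!length(stop_i) || !length(start_i)) next
    nxt <- findInterval(start_i, stop_i) + 1L
    ok <- nxt <= length(stop_i)
    start_i <- start_i[ok]
    stop_k <- stop_i[nxt[ok]]
    if (!length(start_i)) next
    # 5'-most start per stop
    first <- !duplicated(stop_k)   # start_i ascending => first hit is 5'-most
    cs <- start_i[first]
    ct <- stop_k[first]
    aa <- ct - cs
    s0 <- pos[cs] - 1L
    e0 <- pos[ct] + 2L
    nt <- substring(s, s0 + 1L, e0)
    has_n <- grepl("N", nt, fixed = TRUE)
    n_skipped_n <- n_skipped_n + sum(has_n)
    keep <- !has_n
    out[[off + 1L]] <- data.frame(start0 = s0[keep], end0 = e0[keep],
                                  aa = aa[keep], nt = nt[keep],
                                  stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(start0 = integer(), end0 = integer(), aa = integer(),
                      nt = character(), stringsAsFactors = FALSE)
  attr(res, "n_skipped_n") <- n_skipped_n
  res
}

#' Find open reading frames in all six frames of a DNA sequence
#'
#' Enumerates every ATG-initiated ORF (standard genetic code) on both strands
#' whose length in codons, excluding the stop codon, lies within
#' `[min_codons, max_codons]`. Nested in-frame starts sharing a stop codon
#' are collapsed to the 5'-most ATG, as in standard annotation practice.
#' ORFs whose span contains the ambiguity code `N` are skipped and counted
#' in the `n_skipped_n` attribute of the result.
#'
#' @param sequence A single DNA string (character or [Biostrings::DNAString])
#'   over the alphabet A/C/G/T/N; lowercase is accepted and upper-cased.
#' @param min_codons,max_codons Inclusive bounds on codon count excluding the
#'   stop codon. The default `max_codons = 99` corresponds to the usual
#'   smORF definition of fewer than 100 codons.
#' @param seq_id Sequence name recorded in the output.
#' @return A data.frame of ORF records with 0-based half-open forward-strand
#'   coordinates, strand, `aa_length`, the sense nucleotide sequence
#'   (start through stop codon) and placeholder classification columns.
#' @examples
#' find_orfs("ATGAAATAA")
#' @export
find_orfs <- function(sequence, min_codons = 1L, max_codons = 99L,
                      seq_id = "seq") {
  stopifnot(min_codons >= 1L, max_codons >= min_codons)
  s <- .check_dna(sequence)
  L <- nchar(s)
  if (L == 0L) {
    out <- .empty_catalog()
    attr(out, "n_skipped_n") <- 0L
    return(out)
  }
  skipped <- 0L
  pieces <- list()
  fwd <- .scan_frames(s)
  if (!is.null(fwd) && nrow(fwd)) {
    pieces$fwd <- data.frame(start = fwd$start0, end = fwd$end0,
                             strand = "+", aa_length = fwd$aa,
                             nt_sequence = fwd$nt, stringsAsFactors = FALSE)
  }
  skipped <- skipped + (attr(fwd, "n_skipped_n") %||% 0L)
  rev <- .scan_frames(.revcomp(s))
  if (!is.null(rev) && nrow(rev)) {
    pieces$rev <- data.frame(start = L - rev$end0, end = L - rev$start0,
                             strand = "-", aa_length = rev$aa,
                             nt_sequence = rev$nt, stringsAsFactors = FALSE)
  }
  skipped <- skipped + (attr(rev, "n_skipped_n") %||% 0L)
  if (!length(pieces)) {
    out <- .empty_catalog()
    attr(out, "n_skipped_n") <- skipped
    return(out)
  }
  orfs <- do.call(rbind, pieces)
  orfs <- orfs[orfs$aa_length >= min_codons & orfs$aa_length <= max_codons, ,
               drop = FALSE]
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  out <- data.frame(
    orf_id = sprintf("%s:%d-%d(%s)", seq_id, orfs$start, orfs$end,
                     orfs$strand),
    seq_id = seq_id, start = orfs$start, end = orfs$end,
    strand = orfs$strand, aa_length = orfs$aa_length,
    nt_sequence = orfs$nt_sequence, orf_class = NA_character_,
    parent_transcript = NA_character_, gene_id = NA_character_,
    gc_ratio = gc_ratio(orfs$nt_sequence),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped_n") <- skipped
  out
}

#' Find ORFs across a multi-record FASTA or DNAStringSet
#'
#' @param x Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @inheritParams find_orfs
#' @return Concatenated ORF records over all sequences; the `n_skipped_n`
#'   attribute totals ORFs skipped for containing `N`.
#' @export
scan_genome <- function(x, min_codons = 1L, max_codons = 99L) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  nm <- names(x) %||% as.character(seq_along(x))
  nm <- sub("\\s.*$", "", nm)
  res <- lapply(seq_along(x), function(i)
    find_orfs(as.character(x[[i]]), min_codons, max_codons, seq_id = nm[i]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_skipped_n") <-
    sum(vapply(res, function(r) attr(r, "n_skipped_n") %||% 0L, integer(1)))
  out
}
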