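## Transcript-model annotation, read from GFF3.
##
## GFF3 coordinates are 1-based inclusive on disk; they are kept that way
## inside the GRanges holders and converted when compared with the 0-based
## half-open ORF catalogue coordinates.

.NONCODING_TYPES <- c("ncRNA", "lnc_RNA", "lncRNA", "lincRNA",
                      "noncoding_transcript")
.TX_TYPES <- c("mRNA", "transcript", "pseudogene", .NONCODING_TYPES)

.first_parent <- function(p) {
  vapply(p, function(x) if (length(x)) x[[1L]] else NA_character_,
         character(1))
}

#' Read a transcript annotation from a GFF3 file
#'
#' Builds the transcript model set used by [classify_catalog()] and
#' [curate_catalog()]: transcript spans with biotype, per-transcript CDS
#' spans with amino-acid lengths, 5'/3' UTR intervals and pseudogene exons.
#' Transcript biotype is taken from the feature type (`mRNA` is coding;
#' `ncRNA`/`lnc_RNA` are noncoding; `pseudogene` features act as their own
#' transcripts).
#'
#' @param gff Path to a GFF3 file.
#' @return An object of class `transcript_annotation`: a list of GRanges
#'   (`transcripts`, `cds`, `utr5`, `utr3`, `pseudogene_exons`).
#' @export
read_annotation <- function(gff) {
  gr <- rtracklayer::import(gff, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID %||% rep(NA_character_, length(gr)))
  parent <- if (!is.null(md$Parent)) .first_parent(md$Parent)
            else rep(NA_character_, length(gr))

  is_tx <- type %in% .TX_TYPES
  tx <- gr[is_tx]
  tx_id <- id[is_tx]
  tx_gene <- parent[is_tx]
  tx_gene[is.na(tx_gene)] <- tx_id[is.na(tx_gene)]
  biotype <- ifelse(type[is_tx] == "mRNA", "protein_coding",
             ifelse(type[is_tx] == "pseudogene", "pseudogene", "noncoding"))
  # a generic "transcript" feature is coding iff it owns CDS children
  cds_parents <- unique(parent[type == "CDS"])
  generic <- type[is_tx] == "transcript"
  biotype[generic] <- ifelse(tx_id[generic] %in% cds_parents,
                             "protein_coding", "noncoding")
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(tx_id = tx_id,
                                               gene_id = tx_gene,
                                               biotype = biotype)

  gene_of <- setNames(tx_gene, tx_id)

  cds_raw <- gr[type == "CDS"]
  cds_tx <- parent[type == "CDS"]
  if (length(cds_raw)) {
    sp <- split(seq_along(cds_raw), cds_tx)
    cds <- do.call(c, lapply(names(sp), function(t) {
      g <- cds_raw[sp[[t]]]
      span <- range(g)
      S4Vectors::mcols(span) <- S4Vectors::DataFrame(
        tx_id = t, gene_id = unname(gene_of[t]),
        aa_length = sum(GenomicRanges::width(g)) / 3 - 1)
      span
    }))
  } else {
    cds <- GenomicRanges::GRanges()
  }

  pick <- function(tp) {
    g <- gr[type == tp]
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      tx_id = parent[type == tp],
      gene_id = unname(gene_of[parent[type == tp]]))
    g
  }
  utr5 <- pick("five_prime_UTR")
  utr3 <- pick("three_prime_UTR")

  pg_ids <- tx_id[biotype == "pseudogene"]
  pg_exons <- gr[type == "exon" & parent %in% pg_ids]
  if (length(pg_exons)) {
    S4Vectors::mcols(pg_exons) <- S4Vectors::DataFrame(
      tx_id = parent[type == "exon" & parent %in% pg_ids],
      gene_id = unname(gene_of[parent[type == "exon" & parent %in% pg_ids]]))
  }

  structure(list(transcripts = tx, cds = cds, utr5 = utr5, utr3 = utr3,
                 pseudogene_exons = pg_exons),
            class = "transcript_annotation")
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat("transcript_annotation:",
      length(x$transcripts), "transcripts,",
      length(x$cds), "CDS,",
      length(x$utr5), "5'UTRs,", length(x$utr3), "3'UTRs,",
      length(x$pseudogene_exons), "pseudogene exons\n")
  invisible(x)
}

## ORF catalogue rows (0-based half-open) as a GRanges (1-based inclusive).
.catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$seq_id,
    ranges = IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    strand = catalog$strand)
}
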