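## Annotation-based ORF class assignment and catalogue curation.
##
## Precedence when an ORF could satisfy several rules:
##   CDS evidence (sCDS/canonical) > uORF > dORF > pseudogene > lncORF,
## with intergenic reserved for ORFs overlapping no transcript at all.
## ORFs that overlap a transcript but match no containment rule are resolved
## by any-overlap in the same precedence order, so that classification is
## always a partition.

.hits <- function(query, subject, type = "any", ignore.strand = FALSE) {
  if (!length(subject)) return(rep(NA_integer_, length(query)))
  # contigs without annotation are expected; silence the seqlevel notice
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, type = type,
                                ignore.strand = ignore.strand))
  out <- rep(NA_integer_, length(query))
  qh <- S4Vectors::queryHits(h)
  out[qh[!duplicated(qh)]] <- S4Vectors::subjectHits(h)[!duplicated(qh)]
  out
}

#' Assign an ORF class to every record in a catalogue
#'
#' Classifies each ORF against a transcript annotation: `sCDS` when it
#' coincides with an annotated CDS of at most `max_codons` codons on an
#' mRNA, `canonical` for longer CDS, `uORF`/`dORF` when contained in an
#' annotated 5'/3' UTR, `pseudogene` within pseudogene exons, `lncORF`
#' within a noncoding transcript, and `intergenic` when overlapping no
#' transcript. ORFs nested inside (but not equal to) a CDS inherit that
#' CDS's class. Containment is strand-aware; the final any-overlap fallback
#' is not.
#'
#' @param catalog ORF catalogue data.frame from [find_orfs()] or
#'   [scan_genome()].
#' @param annotation A `transcript_annotation` from [read_annotation()].
#' @param max_codons smORF size limit in codons excluding the stop; a CDS of
#'   at most this many codons is `sCDS`, anything longer `canonical`.
#' @return The catalogue with `orf_class`, `parent_transcript` and `gene_id`
#'   filled in.
#' @export
classify_catalog <- function(catalog, annotation, max_codons = 99L) {
  if (!inherits(annotation, "transcript_annotation"))
    stop("no annotation loaded: 'annotation' must be a transcript_annotation")
  if (!nrow(catalog)) return(catalog)
  q <- .catalog_granges(catalog)
  n <- nrow(catalog)
  cls <- rep(NA_character_, n)
  tx_of <- rep(NA_character_, n)
  gene_of <- rep(NA_character_, n)

  take <- function(idx, subject, label_fun) {
    new <- is.na(cls) & !is.na(idx)
    if (!any(new)) return(invisible(NULL))
    md <- S4Vectors::mcols(subject)
    cls[new] <<- label_fun(md[idx[new], , drop = FALSE])
    tx_of[new] <<- md$tx_id[idx[new]]
    gene_of[new] <<- md$gene_id[idx[new]]
    invisible(NULL)
  }
  cds_label <- function(md)
    ifelse(md$aa_length <= max_codons, "sCDS", "canonical")

  ann <- annotation
  take(.hits(q, ann$cds, type = "equal"), ann$cds, cds_label)
  take(.hits(q, ann$utr5, type = "within"), ann$utr5,
       function(md) rep("uORF", nrow(md)))
  take(.hits(q, ann$utr3, type = "within"), ann$utr3,
       function(md) rep("dORF", nrow(md)))
  take(.hits(q, ann$cds, type = "within"), ann$cds, cds_label)
  take(.hits(q, ann$pseudogene_exons, type = "within"), ann$pseudogene_exons,
       function(md) rep("pseudogene", nrow(md)))
  nc <- ann$transcripts[S4Vectors::mcols(ann$transcripts)$biotype ==
                          "noncoding"]
  take(.hits(q, nc, type = "within"), nc,
       function(md) rep("lncORF", nrow(md)))

  # fallback: partial overlaps, same precedence, strand-blind last resort
  take(.hits(q, ann$cds, ignore.strand = TRUE), ann$cds, cds_label)
  take(.hits(q, ann$utr5, ignore.strand = TRUE), ann$utr5,
       function(md) rep("uORF", nrow(md)))
  take(.hits(q, ann$utr3, ignore.strand = TRUE), ann$utr3,
       function(md) rep("dORF", nrow(md)))
  take(.hits(q, ann$pseudogene_exons, ignore.strand = TRUE),
       ann$pseudogene_exons, function(md) rep("pseudogene", nrow(md)))
  take(.hits(q, ann$transcripts, ignore.strand = TRUE), ann$transcripts,
       function(md) rep("lncORF", nrow(md)))

  cls[is.na(cls)] <- "intergenic"
  catalog$orf_class <- cls
  catalog$parent_transcript <- tx_of
  catalog$gene_id <- gene_of
  catalog
}

#' Classify a single ORF record
#'
#' @param orf A one-row ORF catalogue data.frame.
#' @inheritParams classify_catalog
#' @return The class label as a character scalar.
#' @export
classify_orf <- function(orf, annotation, max_codons = 99L) {
  stopifnot(nrow(orf) == 1L)
  classify_catalog(orf, annotation, max_codons)$orf_class
}

.orf_overlap_frac <- function(a, b) {
  # fraction of the shorter record's span covered by the intersection
  ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  ov / min(a$end - a$start, b$end - b$start)
}

## priority order used when one of several redundant isoforms is retained:
## longest first, ties broken by the 5'-most start on the record's strand.
.iso_order <- function(df) {
  five_prime <- ifelse(df$strand == "-", -df$end, df$start)
  order(-df$aa_length, five_prime)
}

#' Curate a classified ORF catalogue
#'
#' Applies three filters, in order, and reports what each removed:
#' 1. drops any `sCDS` whose gene carries another annotated protein isoform
#'    longer than 100 aa;
#' 2. among a gene's peptide isoforms that are identical or whose spans
#'    overlap at least 80% of the shorter one, retains a single record
#'    (the longest, ties broken by the 5'-most start);
#' 3. caps `lncORF` records at five per noncoding transcript (the longest
#'    five, same tie-break).
#'
#' Curation is idempotent: applying it to its own output removes nothing.
#'
#' @inheritParams classify_catalog
#' @param records A classified ORF catalogue.
#' @return A list with `catalog` (the retained records) and `report`, a
#'   `curation_report` with removal counts and the removed `orf_id`s.
#' @export
curate_catalog <- function(records, annotation, max_codons = 99L) {
  n_input <- nrow(records)
  removed_long <- character()
  removed_red <- character()
  removed_cap <- character()

  # 1. sCDS with a >100 aa protein isoform on the same gene
  if (n_input && length(annotation$cds)) {
    cds_md <- S4Vectors::mcols(annotation$cds)
    long_genes <- unique(cds_md$gene_id[cds_md$aa_length > 100])
    drop <- records$orf_class == "sCDS" & records$gene_id %in% long_genes
    drop[is.na(drop)] <- FALSE
    removed_long <- records$orf_id[drop]
    records <- records[!drop, , drop = FALSE]
  }

  # 2. redundant peptide isoforms within a gene (sCDS records only)
  if (nrow(records)) {
    scds_idx <- which(records$orf_class == "sCDS" & !is.na(records$gene_id))
    for (g in unique(records$gene_id[scds_idx])) {
      idx <- scds_idx[records$gene_id[scds_idx] == g]
      if (length(idx) < 2L) next
      df <- records[idx, , drop = FALSE]
      ord <- .iso_order(df)
      kept <- integer()
      for (i in ord) {
        same_seq <- df$seq_id[kept] == df$seq_id[i] &
                    df$strand[kept] == df$strand[i]
        red <- any(vapply(kept[same_seq], function(k) {
          identical(df$nt_sequence[[k]], df$nt_sequence[[i]]) ||
            .orf_overlap_frac(df[k, ], df[i, ]) >= 0.80
        }, logical(1)))
        if (red) removed_red <- c(removed_red, df$orf_id[i])
        else kept <- c(kept, i)
      }
    }
    records <- records[!records$orf_id %in% removed_red, , drop = FALSE]
  }

  # 3. at most five lncORFs per noncoding transcript
  if (nrow(records)) {
    ln_idx <- which(records$orf_class == "lncORF" &
                      !is.na(records$parent_transcript))
    for (tx in unique(records$parent_transcript[ln_idx])) {
      idx <- ln_idx[records$parent_transcript[ln_idx] == tx]
      if (length(idx) <= 5L) next
      df <- records[idx, , drop = FALSE]
      ord <- .iso_order(df)
      removed_cap <- c(removed_cap, df$orf_id[ord[-(1:5)]])
    }
    records <- records[!records$orf_id %in% removed_cap, , drop = FALSE]
  }

  report <- structure(list(
    n_input = n_input,
    n_removed_long_isoform = length(removed_long),
    n_removed_redundant = length(removed_red),
    n_removed_lncorf_cap = length(removed_cap),
    n_output = nrow(records),
    removed_ids = c(removed_long, removed_red, removed_cap)),
    class = "curation_report")
  stopifnot(report$n_output ==
              report$n_input - report$n_removed_long_isoform -
              report$n_removed_redundant - report$n_removed_lncorf_cap)
  list(catalog = records, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation:", x$n_input, "in;",
      x$n_removed_long_isoform, "long-isoform,",
      x$n_removed_redundant, "redundant,",
      x$n_removed_lncorf_cap, "lncORF-cap removed;",
      x$n_output, "out\n")
  invisible(x)
}
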