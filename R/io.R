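## TSV readers/writers for the catalogue and count tables.

#' Write an ORF catalogue as BED-like TSV
#'
#' Column order follows BED conventions: `seq_id, start, end, orf_id,
#' aa_length, strand, orf_class, gc_ratio` (0-based half-open
#' coordinates), followed by any remaining catalogue columns.
#'
#' @param catalog ORF catalogue data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  lead <- c("seq_id", "start", "end", "orf_id", "aa_length", "strand",
            "orf_class", "gc_ratio")
  cols <- c(lead, setdiff(names(catalog), lead))
  write.table(catalog[intersect(cols, names(catalog))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ORF catalogue written by [write_catalog()]
#' @param path TSV file.
#' @return data.frame catalogue.
#' @export
read_catalog <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a curation report as TSV
#' @param report A `curation_report` from [curate_catalog()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  df <- data.frame(metric = c("n_input", "n_removed_long_isoform",
                              "n_removed_redundant", "n_removed_lncorf_cap",
                              "n_output"),
                   value = c(report$n_input, report$n_removed_long_isoform,
                             report$n_removed_redundant,
                             report$n_removed_lncorf_cap, report$n_output))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#' @param path Text file.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
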