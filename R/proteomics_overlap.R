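## Proteomic detection-overlap, detection-rate, false-positive and
## per-experiment-yield accounting. All pure set/count arithmetic at gene
## level; percentages are returned at full precision (round only for
## display, see pct1()).

#' Format a percentage to one decimal, as printed in reports
#' @param x Numeric percentage(s).
#' @return Character vector rounded to one decimal place.
#' @export
pct1 <- function(x) sprintf("%.1f", round(x, 1))

#' Build a table of proteomic detection records
#'
#' One row per (gene, experiment, peptide) evidence item; exact duplicates
#' are dropped to enforce the uniqueness invariant.
#'
#' @param gene_id,experiment_id Character vectors (recycled).
#' @param method Detection method per record, e.g. `"punchp"` or `"gel"`.
#' @param sample Sample of origin, e.g. `"embryo"` or `"s2"`.
#' @param peptide_seq Supporting peptide sequence, or `""` when unknown.
#' @param is_scds Whether the gene is a short coding sequence (vs canonical).
#' @return data.frame of detection records.
#' @export
detection_records <- function(gene_id, experiment_id, method = "punchp",
                              sample = "embryo", peptide_seq = "",
                              is_scds = TRUE) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id,
                   experiment_id = rep_len(experiment_id, n),
                   method = rep_len(method, n),
                   sample = rep_len(sample, n),
                   peptide_seq = rep_len(peptide_seq, n),
                   is_scds = rep_len(is_scds, n),
                   stringsAsFactors = FALSE)
  df[!duplicated(df[c("gene_id", "experiment_id", "peptide_seq")]), ,
     drop = FALSE]
}

#' Two-set detection overlap report
#'
#' Counts genes detected in both sets and in exactly one, and the overlap
#' percentage `100 * both / (both + only_a + only_b)`.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return A list with `n_both`, `n_only_a`, `n_only_b` and `overlap_pct`
#'   (full precision; format with [pct1()]).
#' @export
overlap_report <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (!length(a) && !length(b))
    stop("undefined overlap percentage: both sets are empty")
  n_both <- length(intersect(a, b))
  n_only_a <- length(setdiff(a, b))
  n_only_b <- length(setdiff(b, a))
  list(n_both = n_both, n_only_a = n_only_a, n_only_b = n_only_b,
       overlap_pct = 100 * n_both / (n_both + n_only_a + n_only_b))
}

#' Detection rate against a reference set
#'
#' @param detected Character vector of detected gene identifiers.
#' @param reference Non-empty character vector of reference gene
#'   identifiers (e.g. the Ribo-seq-translated set).
#' @return Percentage `100 * |detected n reference| / |reference|`.
#' @export
detection_rate <- function(detected, reference) {
  reference <- unique(reference)
  if (!length(reference)) stop("reference set is empty")
  100 * length(intersect(unique(detected), reference)) / length(reference)
}

#' False-positive accounting for proteomic detections
#'
#' Detections absent from the Ribo-seq translated set are "extra"; extras
#' carrying any corroborating evidence (prior proteomics, ambiguous
#' Ribo-seq signal, RNA-seq support) are "explained"; the remainder are
#' possible false positives. The rate denominator is the total number of
#' detected genes in this study.
#'
#' @param detected Character vector of detected gene identifiers.
#' @param riboseq_set Non-empty reference set of Ribo-seq translated genes.
#' @param prior_proteomics,ambiguous_riboseq,rnaseq_support Character
#'   vectors of genes with each kind of corroborating evidence.
#' @return A list with `n_detected_total`, `n_extra`, `n_explained`,
#'   `n_possible_fp` and `fp_rate_pct`.
#' @export
false_positive_analysis <- function(detected, riboseq_set,
                                    prior_proteomics = character(),
                                    ambiguous_riboseq = character(),
                                    rnaseq_support = character()) {
  if (!length(riboseq_set)) stop("Ribo-seq reference set is empty")
  detected <- unique(detected)
  extras <- setdiff(detected, riboseq_set)
  support <- unique(c(prior_proteomics, ambiguous_riboseq, rnaseq_support))
  explained <- intersect(extras, support)
  fp <- setdiff(extras, explained)
  list(n_detected_total = length(detected),
       n_extra = length(extras),
       n_explained = length(explained),
       n_possible_fp = length(fp),
       fp_rate_pct = 100 * length(fp) / length(detected))
}

#' Per-method experiment yield report
#'
#' Mean number of distinct sCDS genes detected per experiment and the
#' sCDS:canonical detection ratio, per method.
#'
#' @param records Detection records (see [detection_records()]); only rows
#'   with `is_scds = TRUE` count as sCDS detections.
#' @param canonical_counts data.frame with `experiment_id` and
#'   `n_canonical`, covering every experiment in `records`. When it also
#'   carries a `method` column it defines the full experiment roster per
#'   method, so experiments with zero sCDS detections still enter the
#'   per-experiment mean.
#' @return data.frame with one row per method: `method, n_experiments,
#'   mean_scds_per_experiment, scds_per_canonical`.
#' @export
experiment_yield <- function(records, canonical_counts) {
  stopifnot(all(c("experiment_id", "n_canonical") %in%
                  names(canonical_counts)))
  missing_exp <- setdiff(unique(records$experiment_id),
                         canonical_counts$experiment_id)
  if (length(missing_exp))
    stop("missing canonical count for experiment(s): ",
         paste(missing_exp, collapse = ", "))
  has_roster <- "method" %in% names(canonical_counts)
  methods <- if (has_roster)
    unique(c(records$method, canonical_counts$method))
  else unique(records$method)
  out <- list()
  for (m in methods) {
    rm_ <- records[records$method == m, , drop = FALSE]
    exps <- if (has_roster)
      unique(canonical_counts$experiment_id[canonical_counts$method == m])
    else unique(rm_$experiment_id)
    if (!length(exps)) next
    scds <- rm_[rm_$is_scds, , drop = FALSE]
    per_exp <- vapply(exps, function(e)
      length(unique(scds$gene_id[scds$experiment_id == e])), numeric(1))
    total_scds <- sum(per_exp)
    total_canon <- sum(canonical_counts$n_canonical[
      canonical_counts$experiment_id %in% exps])
    out[[m]] <- data.frame(
      method = m, n_experiments = length(exps),
      mean_scds_per_experiment = mean(per_exp),
      scds_per_canonical = if (total_canon > 0) total_scds / total_canon
                           else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene evidence hit counts
#'
#' Number of distinct (experiment, peptide) evidence items per gene;
#' duplicated records count once.
#'
#' @param records Detection records.
#' @return data.frame with `gene_id` and `n_hits`, sorted by gene.
#' @export
hit_count_distribution <- function(records) {
  if (!nrow(records))
    return(data.frame(gene_id = character(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  u <- records[!duplicated(records[c("gene_id", "experiment_id",
                                     "peptide_seq")]), , drop = FALSE]
  tb <- table(u$gene_id)
  data.frame(gene_id = names(tb), n_hits = as.integer(tb),
             stringsAsFactors = FALSE)
}
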