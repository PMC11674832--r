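## Per-gene functional-indicator integration: merged indicator table,
## phenotype-group summaries, functional and conservation fractions, and
## (optional, beyond the descriptive comparison) association tests.

.check_unique_genes <- function(df, what) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id within ", what, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
}

#' Merge per-gene functional indicators into one table
#'
#' Outer join on `gene_id` of catalogue-derived sequence features, a
#' proteomic detection flag, conservation/RNAi annotation flags and
#' phenotype calls. Genes present in the phenotype calls but absent from
#' the catalogue are retained with missing sequence fields (and reported in
#' the `n_unmatched_phenotype` attribute). Genes without a phenotype call
#' are `untested`.
#'
#' @param catalog Optional ORF catalogue; rolled up to one row per gene
#'   (longest isoform) contributing `gc_ratio` and `aa_length`.
#' @param detections Optional character vector of detected gene ids, or a
#'   detection-record data.frame (see [detection_records()]).
#' @param conservation Optional data.frame with `gene_id` and any of
#'   `drosophilid_conserved`, `human_conserved`, `rnai_hit` (logical).
#' @param phenotypes Optional data.frame with `gene_id`, `phenotype`
#'   (`mutant`/`wild_type`/`untested`) and optionally `source`
#'   (`this_work`/`comparison_study`/`both`).
#' @return data.frame with one row per gene and columns `gene_id,
#'   proteomic_detected, gc_ratio, aa_length, drosophilid_conserved,
#'   human_conserved, rnai_hit, phenotype, source`.
#' @export
build_indicator_table <- function(catalog = NULL, detections = NULL,
                                  conservation = NULL, phenotypes = NULL) {
  pieces <- list()
  if (!is.null(catalog) && nrow(catalog)) {
    cc <- catalog[!is.na(catalog$gene_id), , drop = FALSE]
    cc <- cc[order(-cc$aa_length), , drop = FALSE]
    cc <- cc[!duplicated(cc$gene_id), c("gene_id", "gc_ratio", "aa_length")]
    pieces$catalog <- cc
  }
  det_genes <- NULL
  if (!is.null(detections)) {
    det_genes <- if (is.data.frame(detections)) unique(detections$gene_id)
                 else unique(as.character(detections))
  }
  if (!is.null(conservation) && nrow(conservation)) {
    .check_unique_genes(conservation, "conservation flags")
    pieces$conservation <- conservation
  }
  if (!is.null(phenotypes) && nrow(phenotypes)) {
    .check_unique_genes(phenotypes, "phenotype calls")
    ph <- phenotypes
    bad <- setdiff(unique(ph$phenotype), c("mutant", "wild_type", "untested"))
    if (length(bad))
      stop("unknown phenotype value(s): ", paste(bad, collapse = ", "))
    if (is.null(ph$source)) ph$source <- "this_work"
    pieces$phenotypes <- ph
  }
  if (!length(pieces) && is.null(det_genes)) {
    return(data.frame(gene_id = character(), proteomic_detected = logical(),
                      gc_ratio = numeric(), aa_length = numeric(),
                      drosophilid_conserved = logical(),
                      human_conserved = logical(), rnai_hit = logical(),
                      phenotype = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- Reduce(function(a, b) merge(a, b, by = "gene_id", all = TRUE),
                pieces)
  if (is.null(tab))
    tab <- data.frame(gene_id = det_genes, stringsAsFactors = FALSE)
  for (col in c("gc_ratio", "aa_length"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
  for (col in c("drosophilid_conserved", "human_conserved", "rnai_hit"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  tab$proteomic_detected <- if (is.null(det_genes)) NA
                            else tab$gene_id %in% det_genes
  if (is.null(tab$phenotype)) tab$phenotype <- "untested"
  tab$phenotype[is.na(tab$phenotype)] <- "untested"
  if (is.null(tab$source)) tab$source <- NA_character_
  n_unmatched <- if (!is.null(pieces$phenotypes) && !is.null(pieces$catalog))
    sum(!pieces$phenotypes$gene_id %in% pieces$catalog$gene_id) else 0L
  cols <- c("gene_id", "proteomic_detected", "gc_ratio", "aa_length",
            "drosophilid_conserved", "human_conserved", "rnai_hit",
            "phenotype", "source")
  tab <- tab[order(tab$gene_id), cols]
  rownames(tab) <- NULL
  attr(tab, "n_unmatched_phenotype") <- n_unmatched
  tab
}

.pct_of <- function(flag) {
  known <- !is.na(flag)
  den <- sum(known)
  num <- sum(flag[known])
  list(pct = if (den > 0) 100 * num / den else NA_real_,
       num = num, den = den)
}

#' Phenotype-group summaries of an indicator table
#'
#' One row per group with indicator percentages and means. Missing values
#' are excluded from each denominator, and every percentage's numerator and
#' denominator are emitted so that the number is reproducible.
#'
#' @param table Indicator table from [build_indicator_table()].
#' @param group_by Grouping column, default `"phenotype"`.
#' @return data.frame with per-group `n`, percentage/mean columns and the
#'   matching `_num`/`_den` (or `_n`) columns.
#' @export
group_summary <- function(table, group_by = "phenotype") {
  if (!group_by %in% names(table))
    stop("grouping column '", group_by, "' not present")
  sp <- split(table, table[[group_by]])
  out <- do.call(rbind, lapply(names(sp), function(g) {
    d <- sp[[g]]
    det <- .pct_of(d$proteomic_detected)
    dro <- .pct_of(d$drosophilid_conserved)
    hum <- .pct_of(d$human_conserved)
    rna <- .pct_of(d$rnai_hit)
    data.frame(group = g, n = nrow(d),
               pct_detected = det$pct, det_num = det$num, det_den = det$den,
               mean_gc = if (any(!is.na(d$gc_ratio)))
                 mean(d$gc_ratio, na.rm = TRUE) else NA_real_,
               gc_n = sum(!is.na(d$gc_ratio)),
               mean_len = if (any(!is.na(d$aa_length)))
                 mean(d$aa_length, na.rm = TRUE) else NA_real_,
               len_n = sum(!is.na(d$aa_length)),
               pct_drosophilid = dro$pct, dros_num = dro$num,
               dros_den = dro$den,
               pct_human = hum$pct, hum_num = hum$num, hum_den = hum$den,
               pct_rnai = rna$pct, rnai_num = rna$num, rnai_den = rna$den,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of tested genes with a mutant phenotype
#'
#' Among genes whose phenotype call is not `untested`, the fraction called
#' `mutant`, reported with its numerator and denominator. The percentage is
#' returned at full precision; format with [pct1()] for display.
#'
#' @param table Indicator table with a `phenotype` column.
#' @param scope `"all"` or a `source` value to restrict to (requires a
#'   `source` column).
#' @return list with `numerator`, `denominator`, `percentage`.
#' @export
functional_fraction <- function(table, scope = "all") {
  d <- table
  if (!identical(scope, "all")) {
    if (is.null(d$source)) stop("no source column to scope by")
    d <- d[!is.na(d$source) & d$source %in% scope, , drop = FALSE]
  }
  tested <- d$phenotype %in% c("mutant", "wild_type")
  den <- sum(tested)
  if (den == 0) stop("no tested genes in scope; fraction undefined")
  num <- sum(d$phenotype[tested] == "mutant")
  list(numerator = num, denominator = den, percentage = 100 * num / den)
}

#' Fraction of genes carrying a conservation (or other boolean) flag
#'
#' @param table Indicator table.
#' @param flag Name of a logical column, e.g. `"human_conserved"`.
#' @return list with `numerator`, `denominator`, `percentage` (percentage
#'   of non-missing flags that are TRUE).
#' @export
conservation_fraction <- function(table, flag = "human_conserved") {
  if (!nrow(table)) stop("empty indicator table")
  if (!flag %in% names(table)) stop("no column '", flag, "'")
  v <- table[[flag]][!is.na(table[[flag]])]
  if (!length(v)) stop("flag '", flag, "' has no non-missing values")
  list(numerator = sum(v), denominator = length(v),
       percentage = 100 * sum(v) / length(v))
}

#' Indicator-phenotype association tests
#'
#' For each boolean indicator, the 2x2 table against mutant/wild-type
#' phenotype gives a sample odds ratio, an exact (hypergeometric) p-value
#' and a Benjamini-Hochberg adjusted q-value across indicators. This is an
#' added analysis: the underlying comparison is descriptive, and a
#' degenerate margin flags the odds ratio as undefined/infinite.
#'
#' @param table Indicator table.
#' @param indicators Logical columns to test.
#' @return data.frame with `indicator, odds_ratio, p_value, q_value,
#'   degenerate`.
#' @export
association_tests <- function(table,
                              indicators = c("proteomic_detected",
                                             "drosophilid_conserved",
                                             "human_conserved",
                                             "rnai_hit")) {
  d <- table[table$phenotype %in% c("mutant", "wild_type"), , drop = FALSE]
  res <- lapply(indicators, function(ind) {
    ok <- !is.na(d[[ind]])
    tb <- table(factor(d[[ind]][ok], levels = c(TRUE, FALSE)),
                factor(d$phenotype[ok], levels = c("mutant", "wild_type")))
    a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; dd <- tb[2, 2]
    degen <- any(rowSums(tb) == 0) || any(colSums(tb) == 0)
    or <- if (b * c_ == 0) {
      if (a * dd == 0) NA_real_ else Inf
    } else (a * dd) / (b * c_)
    p <- if (degen) NA_real_ else fisher.test(tb)$p.value
    data.frame(indicator = ind, odds_ratio = or, p_value = p,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[c("indicator", "odds_ratio", "p_value", "q_value", "degenerate")]
}
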