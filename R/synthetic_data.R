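## Synthetic-data generators: a planted genome with annotation, Mendelian
## cross counts, balancer-competition counts, and proteomic detection
## tables, each with a machine-joinable truth table. All generators are
## deterministic under their seed.

.BASES <- c("A", "C", "G", "T")
.ALL_CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES,
                               paste0))
.CODON_GC <- vapply(strsplit(.ALL_CODONS, ""),
                    function(b) sum(b %in% c("G", "C")), numeric(1))
.SENSE <- !.ALL_CODONS %in% STOP_CODONS

## codon probabilities for iid bases with per-base G+C probability g,
## conditioned on not being a stop codon; codon prob depends only on its
## G+C count: (g/2)^gc * ((1-g)/2)^(3-gc)
.codon_probs <- function(g) {
  p <- (g / 2)^.CODON_GC * ((1 - g) / 2)^(3 - .CODON_GC)
  p[!.SENSE] <- 0
  p / sum(p)
}

.sense_gc_frac <- function(g) sum(.codon_probs(g) * .CODON_GC) / 3

.calib_cache <- new.env(parent = emptyenv())

## per-base probability whose stop-conditioned codon GC fraction equals the
## requested target (memoised: one root-find per distinct target)
.calibrate_base_prob <- function(target_frac) {
  key <- sprintf("%.9f", target_frac)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (target_frac <= .sense_gc_frac(1e-3) ||
      target_frac >= .sense_gc_frac(1 - 1e-3))
    stop("infeasible internal-codon GC target: ", signif(target_frac, 3))
  root <- uniroot(function(g) .sense_gc_frac(g) - target_frac,
                  c(1e-3, 1 - 1e-3), tol = 1e-10)$root
  .calib_cache[[key]] <- root
  root
}

## One ORF: fixed ATG, aa - 1 internal sense codons calibrated so the
## expected GC of the whole span (start through stop) equals target_gc,
## stop codon uniform over the three stops (expected GC 2/3).
.orf_seq <- function(aa, target_gc) {
  stopifnot(aa >= 2)
  internal_frac <- (target_gc * 3 * (aa + 1) - 1 - 2 / 3) / (3 * (aa - 1))
  g <- .calibrate_base_prob(internal_frac)
  body <- sample(.ALL_CODONS, aa - 1L, replace = TRUE,
                 prob = .codon_probs(g))
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1L))
}

.STOP_UNIT <- "TTAATTAATTAA"   # stop codons in all three frames; own revcomp

## Spacer/flank sequence: roughly the intergenic GC, scrubbed of ATG (and
## CAT, its reverse complement) so it can never seed or extend an ORF, with
## all-frame stops planted at least every 48 nt.
.spacer <- function(n, gc = 0.40) {
  if (n <= 0) return("")
  pieces <- character()
  left <- n
  while (left > 0) {
    k <- min(left, 36L)
    pieces <- c(pieces, paste(sample(.BASES, k, replace = TRUE,
                                     prob = c((1 - gc) / 2, gc / 2,
                                              gc / 2, (1 - gc) / 2)),
                              collapse = ""), .STOP_UNIT)
    left <- left - k - nchar(.STOP_UNIT)
  }
  s <- substr(paste(pieces, collapse = ""), 1L, n)
  s <- gsub("ATG", "ATC", s, fixed = TRUE)
  gsub("CAT", "CAC", s, fixed = TRUE)
}

.LEN_PARAMS <- list(
  sCDS       = c(mean = 73, sd = 15, lo = 20, hi = 99),
  canonical  = c(mean = 200, sd = 50, lo = 120, hi = 400),
  uORF       = c(mean = 25, sd = 8, lo = 10, hi = 40),
  dORF       = c(mean = 25, sd = 8, lo = 10, hi = 40),
  lncORF     = c(mean = 30, sd = 10, lo = 11, hi = 60),
  pseudogene = c(mean = 60, sd = 20, lo = 20, hi = 99),
  intergenic = c(mean = 30, sd = 10, lo = 10, hi = 60))

.sample_len <- function(class, n) {
  p <- .LEN_PARAMS[[class]]
  pmin(pmax(round(rnorm(n, p["mean"], p["sd"])), p["lo"]), p["hi"])
}

#' Synthetic-genome configuration
#'
#' Defaults plant ORF classes at the published class-mean GC ratios
#' (intergenic 0.40, lncORF 0.47, pseudogene 0.48, sCDS 0.51, canonical
#' 0.54; UTR ORFs, for which no reference mean exists, at 0.45-0.46) with
#' field-realistic length distributions per class.
#'
#' @param seed Mandatory integer seed.
#' @param class_counts Named counts of planted ORFs per class.
#' @param gc_means Named target GC ratio per class.
#' @param lncorfs_per_rna How many ORFs each noncoding RNA carries.
#' @return A list of class `synth_genome_config`.
#' @export
synth_genome_config <- function(seed,
                                class_counts = c(sCDS = 30, canonical = 5,
                                                 uORF = 10, dORF = 10,
                                                 lncORF = 10,
                                                 pseudogene = 10,
                                                 intergenic = 20),
                                gc_means = c(intergenic = 0.40,
                                             lncORF = 0.47,
                                             pseudogene = 0.48,
                                             sCDS = 0.51, canonical = 0.54,
                                             uORF = 0.46, dORF = 0.45),
                                lncorfs_per_rna = 1L) {
  stopifnot(!missing(seed), is.numeric(seed))
  if (any(gc_means < 0) || any(gc_means > 1))
    stop("GC targets must be probabilities")
  structure(list(seed = as.integer(seed), class_counts = class_counts,
                 gc_means = gc_means,
                 lncorfs_per_rna = as.integer(lncorfs_per_rna)),
            class = "synth_genome_config")
}

## cassette: sense-strand sequence + features + planted ORFs, local 0-based
## half-open coordinates. Feature rows: type, start, end, id, parent.
.new_cassette <- function() {
  list(seq = "", feats = NULL, orfs = NULL)
}

.orf_with_gc <- function(class, aa, gc) {
  tryCatch(.orf_seq(aa, gc),
           error = function(e)
             stop("infeasible GC target for class ", class, ": ",
                  conditionMessage(e)))
}

.cassette_mrna <- function(class, aa, gc, gene, host_gc = 0.54) {
  # class is "sCDS" or "canonical": mRNA whose CDS is the planted ORF
  u5 <- .spacer(60); orf <- .orf_with_gc(class, aa, gc); u3 <- .spacer(60)
  ol <- nchar(orf); Lc <- 60 + ol + 60
  tx <- paste0(gene, "-RA")
  feats <- data.frame(
    type = c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
             "three_prime_UTR"),
    start = c(0, 0, 0, 0, 60, 60 + ol),
    end = c(Lc, Lc, Lc, 60, 60 + ol, Lc),
    id = c(gene, tx, paste0(tx, ":exon"), paste0(tx, ":u5"),
           paste0(tx, ":cds"), paste0(tx, ":u3")),
    parent = c(NA, gene, tx, tx, tx, tx), stringsAsFactors = FALSE)
  orfs <- data.frame(start = 60, end = 60 + ol, aa = aa, class = class,
                     target_gc = gc, gene_id = gene, tx_id = tx,
                     stringsAsFactors = FALSE)
  list(seq = paste0(u5, orf, u3), feats = feats, orfs = orfs)
}

.cassette_utr_orf <- function(class, aa, gc, gene, host_gc = 0.54) {
  # class "uORF" or "dORF": smORF planted inside the 5' or 3' UTR of an
  # mRNA whose own CDS is canonical length (120 aa)
  orf <- .orf_with_gc(class, aa, gc); ol <- nchar(orf)
  cds <- .orf_with_gc("canonical", 120L, host_gc); cl <- nchar(cds)
  tx <- paste0(gene, "-RA")
  if (class == "uORF") {
    u5 <- paste0(.spacer(30), orf, .STOP_UNIT, .spacer(18))
    u3 <- .spacer(60)
    orf_start <- 30
  } else {
    u5 <- .spacer(60)
    u3 <- paste0(.STOP_UNIT, .spacer(18), orf, .spacer(30))
    orf_start <- nchar(u5) + cl + nchar(.STOP_UNIT) + 18
  }
  u5l <- nchar(u5); u3l <- nchar(u3); Lc <- u5l + cl + u3l
  feats <- data.frame(
    type = c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
             "three_prime_UTR"),
    start = c(0, 0, 0, 0, u5l, u5l + cl),
    end = c(Lc, Lc, Lc, u5l, u5l + cl, Lc),
    id = c(gene, tx, paste0(tx, ":exon"), paste0(tx, ":u5"),
           paste0(tx, ":cds"), paste0(tx, ":u3")),
    parent = c(NA, gene, tx, tx, tx, tx), stringsAsFactors = FALSE)
  orfs <- data.frame(start = orf_start, end = orf_start + ol, aa = aa,
                     class = class, target_gc = gc, gene_id = gene,
                     tx_id = tx, stringsAsFactors = FALSE)
  list(seq = paste0(u5, cds, u3), feats = feats, orfs = orfs)
}

.cassette_contained <- function(class, aas, gc, gene) {
  # "lncORF" (possibly several ORFs per RNA), "pseudogene", "intergenic"
  seqs <- character(); orfs <- list(); pos <- 0
  add <- function(s) { seqs <<- c(seqs, s); pos <<- pos + nchar(s) }
  add(.spacer(30))
  for (i in seq_along(aas)) {
    orf <- .orf_with_gc(class, aas[i], gc)
    orfs[[i]] <- data.frame(start = pos, end = pos + nchar(orf),
                            aa = aas[i], class = class, target_gc = gc,
                            stringsAsFactors = FALSE)
    add(orf)
    add(paste0(.STOP_UNIT, .spacer(18)))
  }
  add(.spacer(12))
  s <- paste(seqs, collapse = "")
  Lc <- nchar(s)
  orfs <- do.call(rbind, orfs)
  tx <- NA_character_
  feats <- NULL
  if (class == "lncORF") {
    tx <- paste0(gene, "-RA")
    feats <- data.frame(
      type = c("gene", "ncRNA", "exon"), start = c(0, 0, 0),
      end = c(Lc, Lc, Lc),
      id = c(gene, tx, paste0(tx, ":exon")),
      parent = c(NA, gene, tx), stringsAsFactors = FALSE)
  } else if (class == "pseudogene") {
    tx <- gene
    feats <- data.frame(
      type = c("pseudogene", "exon"), start = c(0, 0), end = c(Lc, Lc),
      id = c(gene, paste0(gene, ":exon")),
      parent = c(NA, gene), stringsAsFactors = FALSE)
  }
  orfs$gene_id <- if (class == "intergenic") NA_character_ else gene
  orfs$tx_id <- tx
  list(seq = s, feats = feats, orfs = orfs)
}

.gff_escape <- function(x) gsub("[;=,\t]", "_", x)

.write_gff3 <- function(rows, contig_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (nm in names(contig_len))
    writeLines(sprintf("##sequence-region %s 1 %d", nm, contig_len[[nm]]),
               con)
  if (!is.null(rows) && nrow(rows)) {
    attrs <- ifelse(is.na(rows$parent),
                    sprintf("ID=%s", .gff_escape(rows$id)),
                    sprintf("ID=%s;Parent=%s", .gff_escape(rows$id),
                            .gff_escape(rows$parent)))
    phase <- ifelse(rows$type == "CDS", "0", ".")
    writeLines(sprintf("%s\tsmorfkit_synth\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       rows$seq_id, rows$type, as.integer(rows$start) + 1L,
                       as.integer(rows$end), rows$strand, phase, attrs),
               con)
  }
  invisible(path)
}

#' Generate a synthetic genome with planted, annotated ORFs
#'
#' Builds one contig per ORF class, planting ORFs of that class at the
#' configured GC and length distributions, embedded in stop-rich spacer
#' sequence (GC 0.40, scrubbed of start codons, with stop codons in every
#' frame at least every 48 nt) so that planted ORF boundaries are exactly
#' recoverable. Annotation (gene/mRNA/UTR/CDS/ncRNA/pseudogene features)
#' is written as GFF3 consistent with the planted classes. Each planted
#' ORF is placed on a random strand.
#'
#' @param config A [synth_genome_config()].
#' @param dir Output directory; created if needed.
#' @return list with `fasta` and `gff` paths and `truth`, a data.frame of
#'   planted ORFs (`orf_id, seq_id, start, end, strand, class, aa_length,
#'   target_gc, gene_id, tx_id`; coordinates 0-based half-open, forward
#'   strand). The truth table is also written to `truth.tsv` in `dir`.
#' @export
gen_genome <- function(config, dir = tempfile("synthgenome")) {
  stopifnot(inherits(config, "synth_genome_config"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "annotation.gff3")
  truth_path <- file.path(dir, "truth.tsv")

  contigs <- character()
  gff_rows <- list()
  truth <- list()
  counts <- config$class_counts
  counts <- counts[counts > 0]
  gidx <- 0L
  for (class in names(counts)) {
    n <- counts[[class]]
    seq_id <- paste0("chr_", class)
    n_units <- if (class == "lncORF")
      ceiling(n / config$lncorfs_per_rna) else n
    left <- n
    pieces <- character()
    offset <- 0L
    for (u in seq_len(n_units)) {
      gidx <- gidx + 1L
      gene <- sprintf("SYNG%04d", gidx)
      gc <- config$gc_means[[class]]
      cass <- switch(class,
        sCDS = , canonical =
          .cassette_mrna(class, .sample_len(class, 1L), gc, gene),
        uORF = , dORF =
          .cassette_utr_orf(class, .sample_len(class, 1L), gc, gene),
        lncORF = {
          k <- min(config$lncorfs_per_rna, left)
          .cassette_contained(class, .sample_len(class, k), gc, gene)
        },
        pseudogene = , intergenic =
          .cassette_contained(class, .sample_len(class, 1L), gc, gene))
      left <- left - nrow(cass$orfs)
      strand <- sample(c("+", "-"), 1L)
      Lc <- nchar(cass$seq)
      flip <- function(s, e) if (strand == "+") cbind(s, e)
                             else cbind(Lc - e, Lc - s)
      spacer <- .spacer(80L)
      offset <- offset + nchar(spacer)
      cseq <- if (strand == "+") cass$seq else .revcomp(cass$seq)
      if (!is.null(cass$feats)) {
        fc <- flip(cass$feats$start, cass$feats$end)
        gff_rows[[length(gff_rows) + 1L]] <- data.frame(
          seq_id = seq_id, type = cass$feats$type,
          start = fc[, 1L] + offset, end = fc[, 2L] + offset,
          strand = strand, id = cass$feats$id, parent = cass$feats$parent,
          stringsAsFactors = FALSE)
      }
      oc <- flip(cass$orfs$start, cass$orfs$end)
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = seq_id, start = as.integer(oc[, 1L]) + offset,
        end = as.integer(oc[, 2L]) + offset,
        strand = strand, class = cass$orfs$class,
        aa_length = cass$orfs$aa, target_gc = cass$orfs$target_gc,
        gene_id = cass$orfs$gene_id, tx_id = cass$orfs$tx_id,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, spacer, cseq)
      offset <- offset + Lc
    }
    pieces <- c(pieces, .spacer(80L))
    contigs[[seq_id]] <- paste(pieces, collapse = "")
  }

  dna <- Biostrings::DNAStringSet(unlist(contigs) %||% character())
  Biostrings::writeXStringSet(dna, fasta)
  gff_df <- if (length(gff_rows)) do.call(rbind, gff_rows) else NULL
  .write_gff3(gff_df, vapply(contigs, nchar, integer(1)), gff)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               strand = character(), class = character(),
               aa_length = integer(), target_gc = numeric(),
               gene_id = character(), tx_id = character(),
               stringsAsFactors = FALSE)
  if (nrow(truth_df))
    truth_df <- cbind(orf_id = sprintf("%s:%d-%d(%s)", truth_df$seq_id,
                                       truth_df$start, truth_df$end,
                                       truth_df$strand),
                      truth_df, stringsAsFactors = FALSE)
  else truth_df <- cbind(orf_id = character(), truth_df)
  write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(fasta = fasta, gff = gff, truth = truth_df)
}

#' Generate hemizygous cross counts with known viabilities
#'
#' Offspring of each cross fall into the two scored classes with the
#' Insertion/Df class binomial at success probability `v / (1 + v)`, where
#' `v` is the gene's true relative viability.
#'
#' @param true_viability Numeric vector in `[0, 1]` of true relative
#'   viabilities, optionally named by gene.
#' @param n_offspring Scored offspring per cross (positive; recycled).
#' @param seed Integer seed.
#' @return data.frame `gene_id, n_ins_df, n_ins_bal` with a `truth`
#'   attribute carrying the planted viabilities.
#' @export
gen_cross_counts <- function(true_viability, n_offspring, seed) {
  if (any(n_offspring <= 0)) stop("n_offspring must be positive")
  if (any(true_viability < 0 | true_viability > 1))
    stop("true viabilities must lie in [0, 1]")
  set.seed(seed)
  n <- length(true_viability)
  gene_id <- names(true_viability) %||% sprintf("SYNG%04d", seq_len(n))
  n_offspring <- rep_len(n_offspring, n)
  n_df <- rbinom(n, n_offspring, true_viability / (1 + true_viability))
  out <- data.frame(gene_id = gene_id, n_ins_df = n_df,
                    n_ins_bal = n_offspring - n_df,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(gene_id = gene_id,
                                   true_v = unname(true_viability),
                                   stringsAsFactors = FALSE)
  out
}

#' Generate balancer-competition count tables with known selection
#'
#' Delegates to [simulate_kr_population()] per gene and emits per-replicate
#' per-generation genotype counts.
#'
#' @param s True selection coefficient(s), optionally named by gene.
#' @param h,q0,N,generations,replicates As in [simulate_kr_population()].
#' @param seed Integer seed.
#' @return data.frame `gene_id, replicate, generation, n_II, n_IB, q, R,
#'   extinct` with a `truth` attribute of planted `s` per gene.
#' @export
gen_kr_counts <- function(s, h = 0, q0 = 0.5, N, generations = 3L,
                          replicates = 1L, seed) {
  gene_id <- names(s) %||% sprintf("SYNG%04d", seq_along(s))
  set.seed(seed)
  out <- lapply(seq_along(s), function(i) {
    tr <- simulate_kr_population(s[[i]], h = h, q0 = q0, N = N,
                                 generations = generations,
                                 replicates = replicates)
    cbind(gene_id = gene_id[i], tr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- data.frame(gene_id = gene_id, s = unname(s),
                                   stringsAsFactors = FALSE)
  res
}

#' Generate proteomic detection tables with a translation covariate
#'
#' Each gene carries a lognormal translation-level covariate; detection in
#' each experiment is Bernoulli with probability logistic in the log
#' covariate. Per-method intercepts are calibrated so the expected number
#' of distinct true detections per experiment matches
#' `per_experiment_mean`. Canonical co-detections are Poisson at
#' `per_experiment_mean / scds_per_canonical`. False detections (genes
#' outside the Ribo-seq set) are planted so their expected share of all
#' detected genes is `fp_rate`.
#'
#' @param gene_ids Genes in the Ribo-seq translated reference set.
#' @param seed Integer seed.
#' @param n_experiments,per_experiment_mean,scds_per_canonical Named
#'   (per-method) experiment counts, planted mean distinct sCDS detections
#'   per experiment, and sCDS:canonical detection ratio.
#' @param slope Logistic slope on the log covariate (0 gives the
#'   no-effect null).
#' @param covariate_meanlog,covariate_sdlog Lognormal covariate parameters.
#' @param fp_rate Planted false-detection share of detected genes.
#' @return list with `records` (detection records), `canonical_counts`
#'   (per experiment), and `truth` (per gene: covariate, detected,
#'   is_fake).
#' @export
gen_detection_tables <- function(gene_ids, seed,
                                 n_experiments = c(punchp = 29L, gel = 5L),
                                 per_experiment_mean = c(punchp = 2.55,
                                                         gel = 23.7),
                                 scds_per_canonical = c(punchp = 0.02,
                                                        gel = 0.09),
                                 slope = 1,
                                 covariate_meanlog = 1,
                                 covariate_sdlog = 1.2,
                                 fp_rate = 0.071) {
  set.seed(seed)
  ng <- length(gene_ids)
  stopifnot(ng > 0)
  x <- rlnorm(ng, covariate_meanlog, covariate_sdlog)
  eta <- slope * log(x)
  records <- list()
  canonical <- list()
  for (m in names(n_experiments)) {
    target <- per_experiment_mean[[m]] / ng
    if (target >= 1)
      stop("per-experiment mean exceeds gene count for method ", m)
    a <- uniroot(function(a0) mean(plogis(a0 + eta)) - target,
                 c(-40, 40), tol = 1e-10)$root
    p <- plogis(a + eta)
    for (e in seq_len(n_experiments[[m]])) {
      exp_id <- sprintf("%s_%02d", m, e)
      hit <- runif(ng) < p
      if (any(hit))
        records[[length(records) + 1L]] <- data.frame(
          gene_id = gene_ids[hit], experiment_id = exp_id, method = m,
          sample = "embryo", peptide_seq = "", is_scds = TRUE,
          stringsAsFactors = FALSE)
      canonical[[length(canonical) + 1L]] <- data.frame(
        experiment_id = exp_id, method = m,
        n_canonical = rpois(1L, per_experiment_mean[[m]] /
                              scds_per_canonical[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  rec <- if (length(records)) do.call(rbind, records) else
    detection_records(character(), character())
  canon <- do.call(rbind, canonical)
  true_detected <- unique(rec$gene_id)
  n_fp <- if (fp_rate > 0 && length(true_detected))
    rbinom(1L, length(true_detected), fp_rate / (1 - fp_rate)) else 0L
  fake <- character()
  if (n_fp > 0) {
    fake <- sprintf("FAKE%04d", seq_len(n_fp))
    records_fp <- data.frame(
      gene_id = fake,
      experiment_id = sample(canon$experiment_id, n_fp, replace = TRUE),
      method = NA_character_, sample = "embryo", peptide_seq = "",
      is_scds = TRUE, stringsAsFactors = FALSE)
    records_fp$method <- sub("_[0-9]+$", "", records_fp$experiment_id)
    rec <- rbind(rec, records_fp)
  }
  truth <- data.frame(
    gene_id = c(gene_ids, fake),
    covariate = c(x, rep(NA_real_, length(fake))),
    detected = c(gene_ids %in% true_detected, rep(TRUE, length(fake))),
    is_fake = c(rep(FALSE, ng), rep(TRUE, length(fake))),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  list(records = rec, canonical_counts = canon, truth = truth)
}
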