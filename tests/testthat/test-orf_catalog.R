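test_that("find_orfs handles trivial and degenerate inputs", {
  expect_equal(nrow(find_orfs("")), 0L)

  one <- find_orfs("ATGAAATAA", min_codons = 1, max_codons = 99)
  expect_equal(nrow(one), 1L)
  expect_equal(one$aa_length, 2L)
  expect_equal(one$strand, "+")
  expect_equal(one$start, 0L)
  expect_equal(one$end, 9L)
  expect_equal(one$nt_sequence, "ATGAAATAA")

  expect_error(find_orfs("ATGXXTAA"), "input error")

  # ORF spanning an N is skipped and logged
  skipped <- find_orfs("ATGANATAA")
  expect_equal(nrow(skipped), 0L)
  expect_equal(attr(skipped, "n_skipped_n"), 1L)
})

test_that("find_orfs respects ORF record invariants", {
  set.seed(42)
  for (i in 1:20) {
    cat <- find_orfs(random_dna(800), min_codons = 1, max_codons = 99)
    if (!nrow(cat)) next
    expect_true(all(cat$end - cat$start == 3 * (cat$aa_length + 1)))
    expect_true(all(substring(cat$nt_sequence, 1, 3) == "ATG"))
    stops <- substring(cat$nt_sequence, nchar(cat$nt_sequence) - 2)
    expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
    expect_true(all(cat$aa_length >= 1))
  }
})

test_that("find_orfs equals the brute-force six-frame oracle", {
  set.seed(7)
  key <- c("start", "end", "strand", "aa_length")
  for (i in 1:10) {
    s <- random_dna(600, gc = runif(1, 0.3, 0.6))
    got <- find_orfs(s, min_codons = 1, max_codons = 99)[key]
    want <- oracle_find_orfs(s, 1, 99)[key]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # and with N present, both skip the same ORFs
  s <- paste0(random_dna(200), "NN", random_dna(200))
  got <- find_orfs(s, 1, 99)[key]
  want <- oracle_find_orfs(s, 1, 99)[key]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("classification matches planted truth and is a partition", {
  g <- small_genome()
  catalog <- scan_genome(g$fasta, max_codons = 1000)
  ann <- read_annotation(g$gff)
  catalog <- classify_catalog(catalog, ann, max_codons = 99)

  expect_false(anyNA(catalog$orf_class))
  expect_true(all(catalog$orf_class %in% ORF_CLASSES))
  expect_equal(sum(table(catalog$orf_class)), nrow(catalog))

  m <- merge(g$truth, catalog, by = c("seq_id", "start", "end", "strand"))
  expect_equal(nrow(m), nrow(g$truth))   # every planted ORF recovered
  agree <- mean(m$class == m$orf_class)
  expect_gte(agree, 0.99)
  # planted gene assignment carried through
  expect_equal(m$gene_id.x[!is.na(m$gene_id.x)],
               m$gene_id.y[!is.na(m$gene_id.x)])
})

test_that("classify_orf single-record contract and errors", {
  g <- small_genome()
  ann <- read_annotation(g$gff)
  tr <- g$truth[g$truth$class == "sCDS", ][1, ]
  orf <- data.frame(orf_id = "x", seq_id = tr$seq_id, start = tr$start,
                    end = tr$end, strand = tr$strand,
                    aa_length = tr$aa_length, nt_sequence = "",
                    orf_class = NA, parent_transcript = NA, gene_id = NA,
                    gc_ratio = NA)
  expect_equal(classify_orf(orf, ann), "sCDS")
  expect_error(classify_orf(orf, NULL), "annotation")
  # a contig with no annotated transcript -> intergenic
  orf$seq_id <- "chr_unannotated"
  expect_equal(classify_orf(orf, ann), "intergenic")
})

test_that("curation drops long-isoform sCDS, redundant isoforms, caps lncORFs", {
  g <- small_genome()
  catalog <- classify_catalog(scan_genome(g$fasta, max_codons = 1000),
                              read_annotation(g$gff), max_codons = 99)
  ann <- read_annotation(g$gff)

  # 1. a planted sCDS whose gene we give a fake >100aa isoform
  victim <- catalog[catalog$orf_class == "sCDS", ][1, ]
  cds <- ann$cds
  extra <- cds[1]
  S4Vectors::mcols(extra) <- S4Vectors::DataFrame(
    tx_id = "fakeiso-RB", gene_id = victim$gene_id, aa_length = 120)
  ann_long <- ann
  ann_long$cds <- c(cds, extra)
  cur <- curate_catalog(catalog, ann_long)
  expect_true(victim$orf_id %in% cur$report$removed_ids)
  expect_gte(cur$report$n_removed_long_isoform, 1L)

  # 2. redundant isoforms: duplicate an already-curated sCDS with a 90%
  # overlapping span; exactly that one extra record must go
  base <- curate_catalog(catalog, ann)$catalog
  victim <- base[base$orf_class == "sCDS", ][1, ]
  dup <- victim
  shift <- round((victim$end - victim$start) * 0.10)
  dup$orf_id <- "dup1"
  dup$start <- victim$start + shift
  dup$end <- victim$end + shift
  cur2 <- curate_catalog(rbind(base, dup), ann)
  expect_equal(cur2$report$n_removed_redundant, 1L)
  kept <- setdiff(c(victim$orf_id, "dup1"), cur2$report$removed_ids)
  expect_length(kept, 1L)

  # 3. seven lncORFs on one RNA -> five retained
  g7 <- gen_genome(synth_genome_config(
    seed = 5, class_counts = c(lncORF = 7), lncorfs_per_rna = 7L))
  cat7 <- classify_catalog(scan_genome(g7$fasta, max_codons = 1000),
                           read_annotation(g7$gff))
  cur7 <- curate_catalog(cat7, read_annotation(g7$gff))
  # accidental ORFs inside the RNA also classify as lncORF; the cap keeps
  # exactly the five longest of however many the transcript carries
  n_ln <- sum(cat7$orf_class == "lncORF")
  expect_gte(n_ln, 7L)
  expect_equal(cur7$report$n_removed_lncorf_cap, n_ln - 5L)
  expect_equal(sum(cur7$catalog$orf_class == "lncORF"), 5L)

  # report conservation and idempotence
  rep2 <- curate_catalog(cur2$catalog, ann)
  expect_equal(rep2$report$n_input, rep2$report$n_output)
  expect_equal(rep2$catalog, cur2$catalog)
  expect_equal(cur2$report$n_output,
               cur2$report$n_input - cur2$report$n_removed_long_isoform -
                 cur2$report$n_removed_redundant -
                 cur2$report$n_removed_lncorf_cap)
})

test_that("catalogue TSV round trip preserves records", {
  g <- small_genome()
  catalog <- classify_catalog(scan_genome(g$fasta), read_annotation(g$gff))
  path <- tempfile(fileext = ".tsv")
  write_catalog(catalog, path)
  back <- read_catalog(path)
  expect_equal(nrow(back), nrow(catalog))
  expect_equal(back$start, catalog$start)
  expect_equal(back$orf_class, catalog$orf_class)
  expect_equal(back$gc_ratio, catalog$gc_ratio, tolerance = 1e-12)
})
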