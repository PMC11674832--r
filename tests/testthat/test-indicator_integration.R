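test_that("build_indicator_table joins, flags and errors", {
  expect_equal(nrow(build_indicator_table()), 0L)

  cons <- data.frame(gene_id = "g1", drosophilid_conserved = TRUE,
                     human_conserved = FALSE, rnai_hit = TRUE)
  phen <- data.frame(gene_id = "g1", phenotype = "mutant")
  cat <- data.frame(gene_id = "g1", gc_ratio = 0.5, aa_length = 60,
                    orf_id = "o", seq_id = "c", start = 0, end = 183,
                    strand = "+", nt_sequence = "", orf_class = "sCDS",
                    parent_transcript = NA)
  tab <- build_indicator_table(cat, detections = "g1",
                               conservation = cons, phenotypes = phen)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$proteomic_detected)
  expect_equal(tab$phenotype, "mutant")
  expect_equal(tab$gc_ratio, 0.5)

  # phenotype genes absent from the catalogue are retained
  phen2 <- rbind(phen, data.frame(gene_id = "g2", phenotype = "wild_type"))
  tab2 <- build_indicator_table(cat, phenotypes = phen2)
  expect_equal(nrow(tab2), 2L)
  expect_true(is.na(tab2$gc_ratio[tab2$gene_id == "g2"]))
  expect_equal(attr(tab2, "n_unmatched_phenotype"), 1L)

  expect_error(build_indicator_table(
    phenotypes = rbind(phen, phen)), "duplicate")
  expect_error(build_indicator_table(
    phenotypes = data.frame(gene_id = "g", phenotype = "odd")), "unknown")

  # packaged fixtures join to the 46 assessed genes
  t1 <- table1_fixture()
  tab3 <- build_indicator_table(detections = t1$gene_id[1:10],
                                phenotypes = t1[c("gene_id", "phenotype",
                                                  "source")])
  expect_equal(nrow(tab3), 46L)
})

test_that("group_summary margins, missing handling, trivial partition", {
  tab <- build_indicator_table(
    phenotypes = data.frame(gene_id = paste0("g", 1:76),
                            phenotype = rep(c("mutant", "wild_type"),
                                            c(47, 29))),
    detections = paste0("g", c(1:29, 48:63)))
  gs <- group_summary(tab)
  mu <- gs[gs$group == "mutant", ]
  wt <- gs[gs$group == "wild_type", ]
  expect_equal(mu$n, 47L)
  expect_equal(mu$pct_detected, 100 * 29 / 47)
  expect_equal(wt$pct_detected, 100 * 16 / 29)
  # every percentage reproducible from its emitted margins
  expect_equal(mu$pct_detected, 100 * mu$det_num / mu$det_den)

  single <- group_summary(tab[1, ])
  expect_true(single$pct_detected %in% c(0, 100))

  # all-missing indicator -> NA, not 0
  expect_true(is.na(mu$pct_rnai))
  expect_equal(mu$rnai_den, 0L)

  # single-group partition equals whole-table summary
  tab$grp <- "all"
  whole <- group_summary(tab, "grp")
  expect_equal(whole$pct_detected, 100 * 45 / 76)
  expect_error(group_summary(tab, "nope"), "not present")
})

test_that("functional_fraction on packaged fixtures and invariances", {
  t1 <- build_indicator_table(
    phenotypes = table1_fixture()[c("gene_id", "phenotype", "source")])
  ff <- functional_fraction(t1)
  expect_equal(ff$numerator, 21L)
  expect_equal(ff$denominator, 46L)
  expect_equal(ff$percentage, 100 * 21 / 46)

  pooled <- build_indicator_table(
    phenotypes = pooled_phenotype_fixture())
  fp <- functional_fraction(pooled)
  expect_equal(c(fp$numerator, fp$denominator), c(47L, 76L))
  expect_equal(pct1(fp$percentage), "61.8")
  # scoped to this work only
  fw <- functional_fraction(pooled, scope = "this_work")
  expect_equal(c(fw$numerator, fw$denominator), c(21L, 46L))

  hemi <- build_indicator_table(phenotypes = hemizygous_stage_fixture())
  fh <- functional_fraction(hemi)
  expect_equal(c(fh$numerator, fh$denominator), c(20L, 43L))

  # row order and duplicated untested rows do not matter
  shuf <- t1[sample(nrow(t1)), ]
  extra <- rbind(shuf, data.frame(gene_id = c("u1", "u2"),
                                  proteomic_detected = NA, gc_ratio = NA,
                                  aa_length = NA,
                                  drosophilid_conserved = NA,
                                  human_conserved = NA, rnai_hit = NA,
                                  phenotype = "untested", source = NA))
  ff2 <- functional_fraction(extra)
  expect_equal(ff2$percentage, ff$percentage)

  expect_error(functional_fraction(extra[extra$phenotype == "untested", ]),
               "undefined")
})

test_that("conservation_fraction arithmetic and planted-rate recovery", {
  fx <- conservation_fixture()
  cf <- conservation_fraction(fx, "human_conserved")
  expect_equal(c(cf$numerator, cf$denominator), c(298L, 887L))
  expect_equal(pct1(cf$percentage), "33.6")

  all_tab <- data.frame(gene_id = "g", human_conserved = TRUE)
  expect_equal(conservation_fraction(all_tab)$percentage, 100)
  expect_error(conservation_fraction(all_tab[0, ]), "empty")

  set.seed(13)
  n <- 887
  planted <- data.frame(gene_id = seq_len(n),
                        drosophilid_conserved = runif(n) < 0.475)
  pr <- conservation_fraction(planted, "drosophilid_conserved")
  se <- sqrt(0.475 * 0.525 / n) * 100
  expect_lt(abs(pr$percentage - 47.5), 3 * se)
})

test_that("association_tests odds ratios, degeneracy and null calibration", {
  mk <- function(a, b, c_, d) {
    data.frame(gene_id = seq_len(a + b + c_ + d),
               proteomic_detected = rep(c(TRUE, TRUE, FALSE, FALSE),
                                        c(a, b, c_, d)),
               phenotype = rep(c("mutant", "wild_type", "mutant",
                                 "wild_type"), c(a, b, c_, d)))
  }
  even <- association_tests(mk(5, 5, 5, 5), "proteomic_detected")
  expect_equal(even$odds_ratio, 1.0)

  degen <- association_tests(mk(10, 0, 0, 10), "proteomic_detected")
  expect_true(is.infinite(degen$odds_ratio))

  # type-I error of the exact test at alpha = 0.05 under the null
  set.seed(29)
  reps <- 400
  pvals <- replicate(reps, {
    flag <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    phen <- sample(c("mutant", "wild_type"), 40, replace = TRUE)
    tb <- data.frame(gene_id = 1:40, proteomic_detected = flag,
                     phenotype = phen)
    association_tests(tb, "proteomic_detected")$p_value
  })
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
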