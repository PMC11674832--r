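## Packaged fixtures.
##
## The per-gene genetic-assessment table and the group-margin table are
## transcriptions of published summary tables shipped under inst/extdata/.
## The hemizygous-stage and pooled fixtures reproduce only the published
## margins (the underlying per-gene assignments were not printed), so they
## are built programmatically and labelled synthetic.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "smorfkit")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Per-gene genetic assessment fixture (46 genes)
#'
#' Transcribed per-gene hemizygous viability, relative-fitness and overall
#' phenotype calls for the 46 sCDS genes assessed by insertional
#' mutagenesis: 21 mutant and 25 wild-type.
#'
#' @return data.frame with `gene_id, hemizygous_phenotype,
#'   relative_fitness, overall_phenotype, phenotype, source`.
#' @export
table1_fixture <- function() {
  df <- read.delim(.extdata("table1_genetic_calls.tsv"),
                   stringsAsFactors = FALSE, na.strings = "")
  df$phenotype <- df$overall_phenotype
  df$source <- "this_work"
  df
}

#' Group-margin indicator fixture
#'
#' Transcribed per-group indicator margins (percent detected, mean GC,
#' mean length, conservation and RNAi percentages) for the mutant, fully
#' viable and all-sCDS groups.
#'
#' @return data.frame, one row per group.
#' @export
table2_margins_fixture <- function() {
  read.delim(.extdata("table2_indicator_margins.tsv"),
             stringsAsFactors = FALSE)
}

#' Synthetic hemizygous-stage phenotype fixture (20 of 43)
#'
#' Margin-only synthetic stand-in for the hemizygous+fitness screening
#' stage: 43 tested genes of which 20 show a requirement. Gene identifiers
#' are synthetic.
#'
#' @return data.frame with `gene_id, phenotype, source`.
#' @export
hemizygous_stage_fixture <- function() {
  data.frame(
    gene_id = sprintf("SYNHEMI%03d", 1:43),
    phenotype = rep(c("mutant", "wild_type"), c(20L, 23L)),
    source = "this_work", stringsAsFactors = FALSE)
}

#' Synthetic pooled phenotype fixture (47 of 76)
#'
#' Margin-only synthetic stand-in for the pooled comparison of this work's
#' 46 insertional mutants with a comparison study's knockout/somatic
#' results: 76 assessed genes, 47 mutant. The first 46 rows are the real
#' per-gene calls from [table1_fixture()]; the 30 comparison-study rows
#' (26 mutant, 4 wild-type) are synthetic identifiers chosen to realise
#' the published margins.
#'
#' @return data.frame with `gene_id, phenotype, source`.
#' @export
pooled_phenotype_fixture <- function() {
  t1 <- table1_fixture()[c("gene_id", "phenotype", "source")]
  comp <- data.frame(
    gene_id = sprintf("SYNKO%03d", 1:30),
    phenotype = rep(c("mutant", "wild_type"), c(26L, 4L)),
    source = "comparison_study", stringsAsFactors = FALSE)
  rbind(t1, comp)
}

#' Synthetic conservation-flag fixture (298 of 887)
#'
#' Margin-only synthetic stand-in for the genome-wide human-conservation
#' annotation: 887 sCDS genes of which 298 carry the human-conserved flag.
#'
#' @return data.frame with `gene_id, human_conserved`.
#' @export
conservation_fixture <- function() {
  data.frame(
    gene_id = sprintf("SYNCONS%03d", 1:887),
    human_conserved = rep(c(TRUE, FALSE), c(298L, 589L)),
    stringsAsFactors = FALSE)
}
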