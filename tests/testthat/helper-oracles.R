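# Independent oracles, deliberately naive: these re-derive expected values
# by direct enumeration and never share code with the implementation.

# Brute-force six-frame ORF scan: enumerate every ATG in both orientations,
# walk codon by codon to the first in-frame stop, then keep the 5'-most ATG
# per (orientation, stop). Coordinates 0-based half-open, forward strand.
oracle_find_orfs <- function(sequence, min_codons = 1, max_codons = 99) {
  sequence <- toupper(sequence)
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(s)
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(s, "")[[1]])), collapse = "")
  scan_one <- function(s) {
    L <- nchar(s)
    hits <- list()
    if (L >= 3) for (i in 1:(L - 2)) {
      if (substring(s, i, i + 2) != "ATG") next
      j <- i + 3
      found <- FALSE
      while (j + 2 <= L) {
        if (substring(s, j, j + 2) %in% stops) { found <- TRUE; break }
        j <- j + 3
      }
      if (!found) next
      hits[[length(hits) + 1]] <-
        data.frame(start0 = i - 1, end0 = j + 2, aa = (j - i) / 3)
    }
    if (!length(hits))
      return(data.frame(start0 = integer(), end0 = integer(),
                        aa = integer()))
    df <- do.call(rbind, hits)
    # 5'-most ATG per stop (end0 identifies orientation-frame-stop)
    df <- df[order(df$start0), ]
    df[!duplicated(df$end0), ]
  }
  L <- nchar(sequence)
  fwd <- scan_one(sequence)
  out <- if (nrow(fwd))
    data.frame(start = fwd$start0, end = fwd$end0, strand = "+",
               aa_length = fwd$aa) else NULL
  rev <- scan_one(revcomp(sequence))
  if (nrow(rev))
    out <- rbind(out, data.frame(start = L - rev$end0, end = L - rev$start0,
                                 strand = "-", aa_length = rev$aa))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_length = integer()))
  out <- out[out$aa_length >= min_codons & out$aa_length <= max_codons, ]
  span <- mapply(function(st, en, str) {
    sp <- substring(sequence, st + 1, en)
    if (str == "-") sp <- revcomp(sp)
    sp
  }, out$start, out$end, out$strand)
  out <- out[!grepl("N", span), ]
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# Punnett-square oracle for the balancer competition: track genotype
# fractions by explicit gamete enumeration, remove BB zygotes, apply
# viability weights, renormalise.
oracle_kr <- function(s, h, generations, q0 = 0.5) {
  f <- c(II = 0, IB = 1, BB = 0)       # 1:1 setup: all heterozygotes
  if (q0 != 0.5) {
    f <- c(II = (1 - 2 * q0), IB = 2 * q0, BB = 0)  # q among I/B parents
  }
  out <- NULL
  for (t in seq_len(generations)) {
    gB <- unname((f["IB"] / 2) / (f["II"] + f["IB"]))  # balancer gametes
    gI <- 1 - gB
    zyg <- c(II = gI^2, IB = 2 * gI * gB, BB = gB^2)
    w <- c(II = 1 - s, IB = 1 - h * s, BB = 0)
    surv <- zyg * w
    surv <- surv / sum(surv)
    out <- rbind(out, data.frame(
      generation = t, f_II = unname(surv["II"]),
      f_IB = unname(surv["IB"]),
      R = unname(surv["II"] / surv["IB"]),
      q = unname(surv["IB"] / 2)))
    f <- surv
  }
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small annotated genome shared by catalogue tests
small_genome <- function(seed = 101) {
  gen_genome(synth_genome_config(
    seed = seed,
    class_counts = c(sCDS = 6, canonical = 2, uORF = 4, dORF = 4,
                     lncORF = 4, pseudogene = 3, intergenic = 6)))
}
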