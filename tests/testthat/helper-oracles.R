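# Independent reference computations used across the suite. These stay
# deliberately naive: exhaustive enumeration and direct simulation, never
# sharing code with the implementation they check.

# Longest common subsequence by exhaustive enumeration: every subsequence of
# the shorter string is tested for being a subsequence of the longer.
lcs_exhaustive <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) > length(bv)) { tmp <- av; av <- bv; bv <- tmp }
  n <- length(av)
  if (n == 0L) return(0L)
  is_subseq <- function(x, y) {
    j <- 1L
    for (c in x) {
      while (j <= length(y) && y[j] != c) j <- j + 1L
      if (j > length(y)) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    sub <- av[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    if (length(sub) > best && is_subseq(sub, bv)) best <- length(sub)
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Match count via Biostrings global alignment under the match=1, mismatch=0,
# gap=0 scoring (the independent library route).
biostrings_match_count <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 0)
  as.integer(Biostrings::score(pa))
}

# Random multi-chromosome annotation with dispersed, tandem/overlapping and
# edge-hugging repeats, for oracle-equivalence property tests.
random_annotation <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1)
  sizes <- setNames(sample(3000:30000, n_chrom),
                    paste0("chr", seq_len(n_chrom)))
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0)
  for (cn in names(sizes)) {
    C <- sizes[[cn]]
    k <- sample(0:6, 1)
    if (k == 0) next
    for (i in seq_len(k)) {
      len <- sample(50:2500, 1)
      len <- min(len, C)
      kind <- sample(c("anywhere", "left_edge", "right_edge"), 1,
                     prob = c(0.7, 0.15, 0.15))
      st <- switch(kind,
        anywhere = sample.int(C - len + 1L, 1L) - 1L,
        left_edge = sample(0:min(100, C - len), 1),
        right_edge = C - len - sample(0:min(100, C - len), 1))
      chrom <- c(chrom, cn); s0 <- c(s0, st); e0 <- c(e0, st + len)
    }
  }
  if (length(chrom) == 0L) {   # ensure at least one repeat somewhere
    cn <- names(sizes)[1]
    chrom <- cn; s0 <- 100; e0 <- min(sizes[[cn]], 100 + 800)
  }
  make_annotation(chrom, s0, e0, sprintf("g%03d", seq_along(chrom)),
                  "*", sizes)
}

# Union size by explicit position-set enumeration (0-based half-open).
position_set_union_bp <- function(ann) {
  total <- 0L
  for (cn in unique(as.character(GenomicRanges::seqnames(ann)))) {
    sel <- as.character(GenomicRanges::seqnames(ann)) == cn
    pos <- unlist(Map(seq.int,
                      GenomicRanges::start(ann)[sel],
                      GenomicRanges::end(ann)[sel]))
    total <- total + length(unique(pos))
  }
  total
}
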