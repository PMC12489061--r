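#' Match-count global alignment score
#'
#' Scores a global alignment of two nucleotide sequences with match = 1,
#' mismatch = 0, gap = 0 and returns the optimal score: the maximum number of
#' identical aligned base pairs. Under this scoring the optimum equals the
#' longest-common-subsequence (LCS) length, and it is computed by dynamic
#' programming in O(|a|*|b|) time.
#'
#' Comparison is case-insensitive. Only A, C, G and T can match; `N` (or any
#' other ambiguity code) matches nothing, not even itself. An empty sequence
#' yields a score of 0 (not an error).
#'
#' @param a,b Nucleotide sequences: single character strings, or
#'   [Biostrings::DNAString] objects.
#' @return Integer match count in `[0, min(nchar(a), nchar(b))]`.
#' @examples
#' match_count_alignment("ACGT", "ACGT")  # 4
#' match_count_alignment("ACGT", "TGCA")  # 1
#' @export
match_count_alignment <- function(a, b) {
  a <- as_sequence_string(a, "a")
  b <- as_sequence_string(b, "b")
  .lcs_match_count_cpp(a, b)
}

#' Normalized pairwise similarity
#'
#' Divides the match-count alignment score of two sequences by a length
#' normalizer so that the value lies in `[0, 1]`, with 1 attained if and only
#' if the sequences are identical (under the `"max"` normalizer).
#'
#' The normalization convention is configurable:
#' \describe{
#'   \item{`"max"` (default)}{score / max(|a|, |b|). Penalizes length
#'     mismatch; 1 iff identical.}
#'   \item{`"min"`}{score / min(|a|, |b|). 1 iff the shorter sequence is a
#'     subsequence of the longer.}
#'   \item{`"alignment"`}{score / alignment length. With this scoring the
#'     optimal global alignment has |a| + |b| - score columns.}
#' }
#'
#' @inheritParams match_count_alignment
#' @param normalizer One of `"max"`, `"min"`, `"alignment"`.
#' @return Similarity fraction in `[0, 1]`.
#' @examples
#' normalized_similarity("ACGT", "TGCA")  # 0.25
#' normalized_similarity("AAAA", "AA")    # 0.5
#' @export
normalized_similarity <- function(a, b, normalizer = c("max", "min", "alignment")) {
  normalizer <- match.arg(normalizer)
  a <- as_sequence_string(a, "a")
  b <- as_sequence_string(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("normalized similarity is undefined for empty sequences")
  }
  m <- .lcs_match_count_cpp(a, b)
  denom <- switch(normalizer,
    max = max(nchar(a), nchar(b)),
    min = min(nchar(a), nchar(b)),
    alignment = nchar(a) + nchar(b) - m
  )
  m / denom
}

#' Pairwise similarity matrix over paralog families
#'
#' Computes [normalized_similarity()] for every within-family gene pair and
#' returns a square symmetric matrix over all family members, in family
#' order. Cells pairing genes from different families are `NA` (absent)
#' unless `all_pairs = TRUE`; the diagonal is 1.
#'
#' @param sequences Gene sequences: a named character vector or a named
#'   [Biostrings::DNAStringSet], names = gene IDs.
#' @param families Family membership: a data.frame with columns `family_id`
#'   and `gene_id`, or a path to a TSV with those columns.
#' @param normalizer Passed to [normalized_similarity()].
#' @param all_pairs If `TRUE`, also score cross-family pairs (exhaustive
#'   mode); by default the matrix is computed within the family structure.
#' @return Numeric matrix with gene IDs as dimnames and attributes
#'   `families` (the membership table) and `normalizer`.
#' @export
family_matrix <- function(sequences, families,
                          normalizer = c("max", "min", "alignment"),
                          all_pairs = FALSE) {
  normalizer <- match.arg(normalizer)
  families <- as_family_table(families)
  sequences <- as_sequence_set(sequences)
  missing <- setdiff(families$gene_id, names(sequences))
  if (length(missing) > 0L) {
    stop("no sequence provided for family member(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- families$gene_id
  fam <- families$family_id
  n <- length(ids)
  mat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(mat) <- 1
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!all_pairs && fam[i] != fam[j]) next
        s <- normalized_similarity(sequences[[ids[i]]], sequences[[ids[j]]],
                                   normalizer = normalizer)
        mat[i, j] <- s
        mat[j, i] <- s
      }
    }
  }
  structure(mat, families = families, normalizer = normalizer)
}

#' Threshold a similarity matrix into retained pairs and genes
#'
#' Applies the retention filter: gene pairs whose similarity is below the
#' threshold are removed, and a gene is retained if it belongs to at least
#' one retained pair. The retained gene set is the "highly similar paralog"
#' set fed to the rearrangement-risk model.
#'
#' @param m Similarity matrix from [family_matrix()] (or any symmetric
#'   numeric matrix with gene IDs as dimnames; `NA` = pair not scored).
#' @param theta Retention threshold in `(0, 1]`; pairs with similarity
#'   `>= theta` are kept. Default 0.7.
#' @return data.frame with columns `gene_a`, `gene_b`, `similarity` (one row
#'   per retained unordered pair) and attribute `retained_genes` (character
#'   vector of genes in at least one retained pair).
#' @export
filter_pairs <- function(m, theta = 0.7) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta > 1) {
    stop("`theta` must be a single value in (0, 1]")
  }
  ids <- rownames(m)
  idx <- which(upper.tri(m) & !is.na(m) & m >= theta, arr.ind = TRUE)
  pairs <- data.frame(
    gene_a = ids[idx[, 1L]],
    gene_b = ids[idx[, 2L]],
    similarity = m[idx],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "retained_genes") <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  attr(pairs, "theta") <- theta
  pairs
}

#' Write a similarity matrix as TSV
#'
#' @param m Matrix from [family_matrix()].
#' @param path Output path; a `#`-prefixed provenance header is written first.
#' @param ... Extra `key = value` pairs for the provenance header.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path, ...) {
  write_provenance_header(path,
                          normalizer = attr(m, "normalizer") %||% "max", ...)
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a family membership table
#'
#' @param path TSV with columns `family_id` and `gene_id` (header required).
#' @return data.frame with those two character columns.
#' @export
read_family_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  as_family_table(tab)
}

as_family_table <- function(families) {
  if (is.character(families) && length(families) == 1L) {
    return(read_family_table(families))
  }
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  if (!all(c("family_id", "gene_id") %in% names(families))) {
    stop("family table needs columns `family_id` and `gene_id`")
  }
  if (anyDuplicated(families$gene_id)) {
    stop("duplicated gene IDs in family table: ",
         paste(unique(families$gene_id[duplicated(families$gene_id)]),
               collapse = ", "))
  }
  families$family_id <- as.character(families$family_id)
  families$gene_id <- as.character(families$gene_id)
  families[c("family_id", "gene_id")]
}

as_sequence_set <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet") ||
      methods::is(sequences, "BStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences) || is.null(names(sequences))) {
    stop("`sequences` must be a named character vector or DNAStringSet")
  }
  sequences
}

as_sequence_string <- function(x, what) {
  if (methods::is(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`", what, "` must be a single sequence string")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
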