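#' Read a chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp. No header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"),
                    comment.char = "#")
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  bad <- which(!is.finite(tab$length) | tab$length <= 0 |
                 tab$length != round(tab$length))
  if (length(bad) > 0L) {
    stop("invalid chromosome length at line ", bad[1L], " of ", path)
  }
  if (anyDuplicated(tab$chrom)) {
    stop("duplicated chromosome name in ", path)
  }
  setNames(as.integer(tab$length), tab$chrom)
}

#' Parse a repeat/paralog annotation against chromosome sizes
#'
#' Reads gene intervals from BED (0-based half-open) or GFF3 (1-based
#' closed) into a [GenomicRanges::GRanges] carrying the genome's
#' [GenomeInfoDb::Seqinfo]. Internally the model works in 0-based half-open
#' coordinates; `GRanges` stores the equivalent 1-based closed form. Strand
#' is preserved but unused by the risk model.
#'
#' @param path BED or GFF3 file (format inferred from the extension, or set
#'   `format`).
#' @param chrom_sizes Path to a chrom.sizes TSV, or a named numeric vector of
#'   chromosome lengths.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return `GRanges` with a `gene_id` metadata column and seqlengths set.
#' @export
parse_annotation <- function(path, chrom_sizes, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  if (is.null(names(chrom_sizes)) || !is.numeric(chrom_sizes)) {
    stop("`chrom_sizes` must be a named numeric vector or a chrom.sizes path")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      stop("cannot infer annotation format from extension ", sQuote(ext),
           "; pass `format`")
    )
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) {
      stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  ids <- if (!is.null(gr$name)) {
    gr$name
  } else if (!is.null(gr$ID)) {
    gr$ID
  } else if (!is.null(gr$Name)) {
    gr$Name
  } else {
    paste0("feature_", seq_along(gr))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(ids))
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("annotation references chromosome(s) absent from chrom.sizes: ",
         paste(unknown, collapse = ", "))
  }
  validate_annotation(gr, chrom_sizes)
}

#' Assemble an annotation from parts
#'
#' Convenience constructor used by the synthetic-genome generator and by
#' tests: builds the same `GRanges` that [parse_annotation()] would return.
#'
#' @param chrom Chromosome name per interval.
#' @param start0,end0 0-based half-open coordinates per interval.
#' @param gene_id Unique gene identifier per interval.
#' @param strand Strand per interval (`"+"`, `"-"` or `"*"`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return `GRanges` with seqlengths set and a `gene_id` metadata column.
#' @export
make_annotation <- function(chrom, start0, end0, gene_id,
                            strand = "*", chrom_sizes) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    gene_id = as.character(gene_id)
  )
  validate_annotation(gr, chrom_sizes)
}

validate_annotation <- function(gr, chrom_sizes) {
  w <- GenomicRanges::width(gr)
  if (any(w < 1L)) {
    i <- which(w < 1L)[1L]
    stop("interval ", i, " (", gr$gene_id[i], "): end <= start")
  }
  if (anyDuplicated(gr$gene_id)) {
    stop("duplicated gene IDs in annotation: ",
         paste(unique(gr$gene_id[duplicated(gr$gene_id)]), collapse = ", "))
  }
  sl <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  over <- which(GenomicRanges::end(gr) >
                  sl[as.character(GenomicRanges::seqnames(gr))] |
                GenomicRanges::start(gr) < 1L)
  if (length(over) > 0L) {
    i <- over[1L]
    stop("interval ", i, " (", gr$gene_id[i],
         ") extends beyond chromosome ",
         as.character(GenomicRanges::seqnames(gr))[i])
  }
  gr
}

#' Total genome length of an annotation
#'
#' @param ann `GRanges` with seqlengths (from [parse_annotation()]).
#' @return Sum of chromosome lengths in bp.
#' @export
genome_length <- function(ann) {
  sl <- GenomeInfoDb::seqlengths(ann)
  if (any(is.na(sl))) stop("annotation has chromosomes without lengths")
  sum(as.numeric(sl))
}

#' Merge intervals into a disjoint sorted cover
#'
#' Position-set union semantics on half-open intervals: overlapping and
#' book-ended intervals (e.g. `[0,10)` and `[10,20)`) merge; intervals on
#' different chromosomes never merge. Thin wrapper over
#' [GenomicRanges::reduce()], which implements exactly this.
#'
#' @param intervals `GRanges`.
#' @return Sorted, pairwise-disjoint `GRanges` covering the union.
#' @export
merge_intervals <- function(intervals) {
  GenomicRanges::reduce(GenomicRanges::sort(intervals), ignore.strand = TRUE)
}

#' Write an annotation as BED6
#'
#' @param ann `GRanges` with a `gene_id` column.
#' @param path Output BED path (0-based half-open, name = gene ID, score 0).
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ann)),
    start = GenomicRanges::start(ann) - 1L,
    end = GenomicRanges::end(ann),
    name = if (!is.null(ann$gene_id)) ann$gene_id else
      rep(".", length(ann)),
    score = rep(0L, length(ann)),
    strand = as.character(GenomicRanges::strand(ann)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write chromosome sizes as a chrom.sizes TSV
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
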