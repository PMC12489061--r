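BASES <- c("A", "C", "G", "T")

#' Specify a synthetic paralog family
#'
#' @param n_copies Number of gene copies (>= 1).
#' @param gene_length Planted gene length in bp (> 0).
#' @param sub_rate Per-base substitution probability in `[0, 1]` applied
#'   independently to each copy relative to the family's ancestral sequence.
#' @param indel_rate Per-base indel probability in `[0, 1]` (half deletions,
#'   half single-base insertions).
#' @param placement `"dispersed"` (random non-overlapping positions across
#'   chromosomes) or `"tandem"` (copies in one cluster separated by
#'   `spacer` bp, emulating tandem paralog arrays).
#' @param spacer Spacer between tandem copies, bp (>= 0).
#' @return List of class `family_spec`.
#' @export
family_spec <- function(n_copies, gene_length, sub_rate = 0.05,
                        indel_rate = 0, placement = c("dispersed", "tandem"),
                        spacer = 100) {
  placement <- match.arg(placement)
  stopifnot(n_copies >= 1, gene_length > 0,
            sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, spacer >= 0)
  structure(list(n_copies = as.integer(n_copies),
                 gene_length = as.integer(gene_length),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 placement = placement, spacer = as.integer(spacer)),
            class = "family_spec")
}

#' Specify a synthetic genome
#'
#' @param chrom_lengths Chromosome lengths in bp (named or unnamed; unnamed
#'   chromosomes are called `chrI`, `chrII`, ...).
#' @param families List of [family_spec()] objects.
#' @param seed Integer seed; one global generator stream governs every draw,
#'   so identical spec + seed gives byte-identical outputs.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, families, seed = 1L) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1L,
            all(chrom_lengths > 0), length(families) >= 1L)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", as.roman(seq_along(chrom_lengths)))
  }
  families <- lapply(families, function(f) {
    if (!inherits(f, "family_spec")) f <- do.call(family_spec, f)
    f
  })
  total_gene_bp <- sum(vapply(families, function(f)
    as.numeric(f$n_copies) * f$gene_length, numeric(1)))
  if (total_gene_bp > sum(as.numeric(chrom_lengths))) {
    stop("total planted gene length (", total_gene_bp,
         " bp) exceeds genome size")
  }
  structure(list(chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths)),
                 families = families, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Read a genome spec from a YAML config
#'
#' Expected keys: `seed`, `chromosomes` (list of lengths or name: length
#' map), `families` (list of maps with the [family_spec()] fields).
#'
#' @param path YAML file.
#' @return `genome_spec`.
#' @export
read_genome_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  chrom <- unlist(cfg$chromosomes)
  genome_spec(chrom_lengths = chrom, families = cfg$families,
              seed = cfg$seed %||% 1L)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Expected per-site identity between two copies independently mutated from
# one ancestor at per-base substitution rate p (uniform over the 3
# alternatives): both untouched, or both hit and coinciding.
expected_pair_identity <- function(p) (1 - p)^2 + p^2 / 3

mutate_copy <- function(ancestor, sub_rate, indel_rate) {
  n <- length(ancestor)
  seq <- ancestor
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit) > 0L) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      idx <- match(seq[hit], BASES)
      seq[hit] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
    }
  }
  if (indel_rate > 0) {
    u <- runif(n)
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    tok <- character(2L * n)
    tok[2L * seq_len(n)] <- ifelse(del, "", seq)
    if (any(ins)) {
      tok[2L * which(ins) - 1L] <- sample(BASES, sum(ins), replace = TRUE)
    }
    seq <- tok[nzchar(tok)]
  }
  seq
}

place_gene <- function(occupied, chrom_lengths, len, rng_attempts = 500L) {
  fits <- names(chrom_lengths)[chrom_lengths >= len]
  if (length(fits) == 0L) {
    stop("gene of length ", len, " does not fit on any chromosome (longest: ",
         names(chrom_lengths)[which.max(chrom_lengths)], ")")
  }
  w <- as.numeric(chrom_lengths[fits])
  for (attempt in seq_len(rng_attempts)) {
    chrom <- if (length(fits) == 1L) fits else sample(fits, 1L, prob = w)
    C <- chrom_lengths[[chrom]]
    start0 <- sample.int(C - len + 1L, 1L) - 1L
    occ <- occupied[[chrom]]
    if (is.null(occ) ||
        !any(start0 < occ$end & occ$start < start0 + len)) {
      return(list(chrom = chrom, start0 = start0))
    }
  }
  stop("could not place a ", len, "-bp gene without overlap after ",
       rng_attempts, " attempts (chromosome(s) too crowded: ",
       paste(fits, collapse = ", "), ")")
}

#' Generate a synthetic genome with planted paralog families
#'
#' Plants paralogous gene families of controlled copy number, length,
#' divergence and clustering on toy chromosomes. Each family derives its
#' copies from one random ancestral sequence by independent per-base
#' substitution (uniform over the three alternative bases) and single-base
#' indel events. Placement rejects overlaps; tandem families are placed as
#' one cluster with a fixed spacer.
#'
#' @param spec A [genome_spec()].
#' @return List of class `synthetic_genome` with elements:
#'   \describe{
#'     \item{annotation}{`GRanges` of planted gene intervals
#'       (seqlengths set, `gene_id` column).}
#'     \item{sequences}{named [Biostrings::DNAStringSet] of gene sequences
#'       (indels can make these differ from the planted interval length).}
#'     \item{families}{data.frame `family_id`, `gene_id`.}
#'     \item{truth}{data.frame per within-family gene pair with
#'       `expected_identity`, the per-site identity expectation under the
#'       substitution process (indel effects not included).}
#'     \item{chrom_sizes}{named integer vector.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chrom_lengths <- spec$chrom_lengths
    occupied <- setNames(vector("list", length(chrom_lengths)),
                         names(chrom_lengths))
    rows <- list()
    seqs <- list()
    truth <- list()
    fam_tab <- list()
    for (fi in seq_along(spec$families)) {
      f <- spec$families[[fi]]
      fam_id <- sprintf("fam%03d", fi)
      ancestor <- sample(BASES, f$gene_length, replace = TRUE)
      ids <- sprintf("%s_g%02d", fam_id, seq_len(f$n_copies))
      if (f$placement == "tandem") {
        block <- f$n_copies * f$gene_length +
          (f$n_copies - 1L) * f$spacer
        at <- place_gene(occupied, chrom_lengths, block)
        starts <- at$start0 + (seq_len(f$n_copies) - 1L) *
          (f$gene_length + f$spacer)
        chroms <- rep(at$chrom, f$n_copies)
        occupied[[at$chrom]] <- rbind(
          occupied[[at$chrom]],
          data.frame(start = at$start0, end = at$start0 + block))
      } else {
        chroms <- character(f$n_copies)
        starts <- integer(f$n_copies)
        for (ci in seq_len(f$n_copies)) {
          at <- place_gene(occupied, chrom_lengths, f$gene_length)
          chroms[ci] <- at$chrom
          starts[ci] <- at$start0
          occupied[[at$chrom]] <- rbind(
            occupied[[at$chrom]],
            data.frame(start = at$start0, end = at$start0 + f$gene_length))
        }
      }
      for (ci in seq_len(f$n_copies)) {
        seqs[[ids[ci]]] <- paste(
          mutate_copy(ancestor, f$sub_rate, f$indel_rate), collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chroms[ci], start0 = starts[ci],
          end0 = starts[ci] + f$gene_length, gene_id = ids[ci],
          strand = sample(c("+", "-"), 1L))
      }
      if (f$n_copies >= 2L) {
        pr <- utils::combn(ids, 2L)
        truth[[length(truth) + 1L]] <- data.frame(
          family_id = fam_id, gene_a = pr[1L, ], gene_b = pr[2L, ],
          expected_identity = expected_pair_identity(f$sub_rate))
      }
      fam_tab[[length(fam_tab) + 1L]] <- data.frame(
        family_id = fam_id, gene_id = ids)
    }
    rows <- do.call(rbind, rows)
    ann <- make_annotation(rows$chrom, rows$start0, rows$end0, rows$gene_id,
                           rows$strand, chrom_lengths)
    structure(list(
      annotation = ann,
      sequences = Biostrings::DNAStringSet(unlist(seqs)),
      families = do.call(rbind, fam_tab),
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(family_id = character(), gene_a = character(),
                   gene_b = character(), expected_identity = numeric()),
      chrom_sizes = chrom_lengths,
      spec = spec
    ), class = "synthetic_genome")
  })
}

#' Write a synthetic genome to disk
#'
#' Writes `genes.fasta` (one record per gene ID), `genes.bed` (BED6, 0-based
#' half-open), `genome.chrom.sizes`, `families.tsv` and `truth.tsv` into a
#' directory.
#'
#' @param genome Result of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$sequences, file.path(dir, "genes.fasta"))
  write_annotation_bed(genome$annotation, file.path(dir, "genes.bed"))
  write_chrom_sizes(genome$chrom_sizes, file.path(dir, "genome.chrom.sizes"))
  write_tsv_provenance(genome$families, file.path(dir, "families.tsv"),
                       seed = genome$spec$seed)
  write_tsv_provenance(genome$truth, file.path(dir, "truth.tsv"),
                       seed = genome$spec$seed)
  invisible(dir)
}

#' Generate replicate assay signals around a known true ratio
#'
#' Draws `n` paired sample/control signal values with multiplicative
#' lognormal noise of coefficient of variation `cv`. Noise multipliers have
#' expectation 1 (meanlog `-sigma^2/2`, `sigma^2 = log(1 + cv^2)`), so the
#' ratio of group means equals `true_ratio` in expectation; the mean of
#' per-replicate ratios carries the usual lognormal ratio bias
#' `exp(sigma^2)` (~`1 + cv^2`), which vanishes as `cv -> 0`.
#'
#' @param true_ratio True sample/control ratio (> 0).
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n Number of replicates (>= 2).
#' @param seed Integer seed.
#' @param strain Strain label for the output rows.
#' @param kind Measurement kind label (e.g. `"dlc_signal"`).
#' @param base_level Control group mean signal (> 0), default 1.
#' @return data.frame in assay-table form (columns `strain`, `condition`,
#'   `replicate`, `kind`, `value`, `pair_id`) with attributes `true_ratio`
#'   and `cv`.
#' @export
generate_assay_replicates <- function(true_ratio, cv, n, seed = 1L,
                                      strain = "synthetic",
                                      kind = "dlc_signal", base_level = 1) {
  if (!is.numeric(true_ratio) || true_ratio <= 0) {
    stop("`true_ratio` must be > 0")
  }
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0")
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2")
  n <- as.integer(n)
  with_seed(seed, {
    sigma2 <- log(1 + cv^2)
    noise <- function(k) {
      if (cv == 0) rep(1, k) else
        stats::rlnorm(k, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
    }
    sample_vals <- base_level * true_ratio * noise(n)
    control_vals <- base_level * noise(n)
    out <- data.frame(
      strain = strain,
      condition = rep(c("sample", "control"), each = n),
      replicate = rep(seq_len(n), 2L),
      kind = kind,
      value = c(sample_vals, control_vals),
      pair_id = rep(seq_len(n), 2L)
    )
    attr(out, "true_ratio") <- true_ratio
    attr(out, "cv") <- cv
    out
  })
}
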