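#' Resection model parameters
#'
#' Bundles the parameters of the resection-exposure model. Defaults follow
#' the biology of budding yeast double-strand-break repair: resection
#' proceeds at ~4 kb per hour, a repeat must present at least 300 bp of
#' contiguous single-stranded homology to engage in recombination, and a
#' crossover-competent break must fall more than 300 bp inside the repeat
#' edges.
#'
#' @param speed Resection speed `v` in bp per hour (> 0). Default 4000.
#' @param min_exposure Minimal contiguous exposed length `E_min` in bp (> 0).
#'   Default 300.
#' @param margin Crossover edge margin in bp (>= 0). Default 300.
#' @param times Time grid in hours (non-negative). Default `seq(0, 4, 0.1)`.
#' @return List of class `resection_params`.
#' @export
resection_params <- function(speed = 4000, min_exposure = 300,
                             margin = 300, times = seq(0, 4, by = 0.1)) {
  stopifnot(is.numeric(speed), length(speed) == 1L, speed > 0,
            is.numeric(min_exposure), length(min_exposure) == 1L,
            min_exposure > 0,
            is.numeric(margin), length(margin) == 1L, margin >= 0,
            is.numeric(times), length(times) >= 1L, all(times >= 0))
  structure(list(speed = speed, min_exposure = min_exposure,
                 margin = margin, times = sort(times)),
            class = "resection_params")
}

#' @export
print.resection_params <- function(x, ...) {
  cat(sprintf(
    "resection model: v = %g bp/h, E_min = %g bp, CO margin = %g bp, %d time points in [%g, %g] h\n",
    x$speed, x$min_exposure, x$margin, length(x$times),
    min(x$times), max(x$times)))
  invisible(x)
}

# 0-based half-open arm coordinates for the exposure rule, unclipped.
# A break at position x exposes the repeat [s, e) on its right tract iff the
# tract [x, x+L) contiguously covers >= E of it: x in [s-(L-E), e-E).
# Symmetrically for the left tract: x in [s+E, e+(L-E)). Repeats shorter
# than E, or tracts shorter than E, expose nothing.
exposure_arm_coords <- function(s0, e0, L, E) {
  len <- e0 - s0
  ok <- L >= E & len >= E
  data.frame(
    chrom_idx = rep(which(ok), 2L),
    start = c(s0[ok] - (L - E), s0[ok] + E),
    end = c(e0[ok] - E, e0[ok] + (L - E)),
    side = rep(c("right", "left"), each = sum(ok))
  )
}

clip_to_granges <- function(chrom, start0, end0, chrom_sizes) {
  cl <- as.numeric(chrom_sizes[chrom])
  start0 <- pmax(start0, 0)
  end0 <- pmin(end0, cl)
  keep <- end0 > start0
  GenomicRanges::GRanges(
    seqnames = factor(chrom[keep], levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(start = start0[keep] + 1, end = end0[keep]),
    seqlengths = setNames(as.integer(chrom_sizes), names(chrom_sizes))
  )
}

#' Break positions from which resection exposes a repeat
#'
#' Computes, for each annotated repeat, the set of break positions from
#' which bidirectional resection of tract length `L` leaves at least
#' `min_exposure` bp of that repeat single-stranded on at least one side of
#' the break. In 0-based half-open coordinates the set for a repeat
#' `[s, e)` is `[s-(L-E), e-E) U [s+E, e+(L-E))`, clipped to the
#' chromosome; it is empty when `L` or the repeat is shorter than `E`, and
#' the two arms coalesce into one interval once the repeat is at least
#' `2*E` long. For repeats shorter than `2*E` a central band remains where
#' neither side can expose `E` contiguous bp.
#'
#' @param interval `GRanges` of repeat intervals (one or more).
#' @param L Resection tract length per end, in bp (>= 0).
#' @param min_exposure Minimal contiguous exposure `E_min` in bp.
#' @return Merged `GRanges` of at-risk break positions (union over the
#'   supplied repeats), clipped to chromosome bounds.
#' @export
exposure_intervals <- function(interval, L, min_exposure = 300) {
  stopifnot(L >= 0, min_exposure > 0)
  sl <- GenomeInfoDb::seqlengths(interval)
  if (any(is.na(sl))) stop("intervals need seqlengths (see parse_annotation)")
  arms <- exposure_arm_coords(GenomicRanges::start(interval) - 1,
                              GenomicRanges::end(interval),
                              L, min_exposure)
  chrom <- as.character(GenomicRanges::seqnames(interval))[arms$chrom_idx]
  merge_intervals(clip_to_granges(chrom, arms$start, arms$end, sl))
}

at_risk_intervals_ <- function(ann, L, E, mode, both_ends) {
  sl <- GenomeInfoDb::seqlengths(ann)
  s0 <- GenomicRanges::start(ann) - 1
  e0 <- as.numeric(GenomicRanges::end(ann))
  chrom_all <- as.character(GenomicRanges::seqnames(ann))
  if (mode == "naive") {
    return(merge_intervals(clip_to_granges(chrom_all, s0 - L, e0 + L, sl)))
  }
  arms <- exposure_arm_coords(s0, e0, L, E)
  chrom <- chrom_all[arms$chrom_idx]
  if (!both_ends) {
    return(merge_intervals(clip_to_granges(chrom, arms$start, arms$end, sl)))
  }
  right <- arms$side == "right"
  gr_right <- merge_intervals(clip_to_granges(chrom[right], arms$start[right],
                                              arms$end[right], sl))
  gr_left <- merge_intervals(clip_to_granges(chrom[!right], arms$start[!right],
                                             arms$end[!right], sl))
  GenomicRanges::intersect(gr_right, gr_left)
}

#' Genome fraction at risk under the one-ended resection-exposure geometry
#'
#' The core risk quantity: with resection proceeding at `v` bp/h, a break at
#' time `t` has resected `L = v*t` bp per end; a randomly placed break is at
#' risk of paralog-mediated rearrangement (half-crossover, break-induced
#' replication, or multi-invasion) if resection exposes at least `E_min`
#' contiguous bp of some annotated repeat on at least one side. The function
#' unions the per-repeat exposure sets, merges them, and divides the covered
#' bp by the total genome length.
#'
#' @param ann Repeat annotation (`GRanges` with seqlengths).
#' @param t Time after break formation, hours (single value, >= 0).
#' @param params [resection_params()].
#' @param mode `"exposure"` (default) uses the minimal-exposure rule above;
#'   `"naive"` is a compatibility mode that simply extends each repeat by
#'   `L` on both sides.
#' @param both_ends If `TRUE`, require >= `E_min` exposure of a repeat on
#'   *both* sides of the break (strict two-ended geometry). Default `FALSE`:
#'   the one-ended pathways need a single usable end.
#' @return Fraction of the genome in `[0, 1]`.
#' @export
resection_risk_fraction <- function(ann, t, params = resection_params(),
                                    mode = c("exposure", "naive"),
                                    both_ends = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  L <- params$speed * t
  gr <- at_risk_intervals_(ann, L, params$min_exposure, mode, both_ends)
  sum(as.numeric(GenomicRanges::width(gr))) / genome_length(ann)
}

#' Genome fraction eligible for crossover-mediated rearrangement
#'
#' Under the canonical two-ended crossover geometry, a break can translocate
#' two paralogs only if it falls squarely within a repeat, more than
#' `margin` bp away from both edges. Eligible positions per repeat of length
#' `len` total `max(0, len - 2*margin)`; overlapping eligible zones are
#' merged before summing.
#'
#' @param ann Repeat annotation (`GRanges` with seqlengths).
#' @param margin Edge margin in bp (default 300).
#' @return Fraction of the genome in `[0, 1]`; 0 for an empty annotation.
#' @export
co_risk_fraction <- function(ann, margin = 300) {
  stopifnot(margin >= 0)
  if (length(ann) == 0L) return(0)
  sl <- GenomeInfoDb::seqlengths(ann)
  s0 <- GenomicRanges::start(ann) - 1
  e0 <- as.numeric(GenomicRanges::end(ann))
  gr <- merge_intervals(clip_to_granges(
    as.character(GenomicRanges::seqnames(ann)),
    s0 + margin, e0 - margin, sl))
  sum(as.numeric(GenomicRanges::width(gr))) / genome_length(ann)
}

#' At-risk genome fraction as a function of time after break formation
#'
#' Evaluates [resection_risk_fraction()] over the parameter time grid and
#' returns one row per time point. Static repeat coverage (merged repeat bp
#' over genome bp, the `t -> 0` envelope of the repeats themselves) is
#' attached as attributes `static_coverage` (merged) and
#' `static_coverage_unmerged`.
#'
#' @inheritParams resection_risk_fraction
#' @return data.frame of class `risk_profile` with columns `t_hours`,
#'   `L_bp`, `at_risk_bp`, `genome_fraction`.
#' @export
risk_profile <- function(ann, params = resection_params(),
                         mode = c("exposure", "naive"), both_ends = FALSE) {
  mode <- match.arg(mode)
  G <- genome_length(ann)
  rows <- lapply(params$times, function(t) {
    L <- params$speed * t
    gr <- at_risk_intervals_(ann, L, params$min_exposure, mode, both_ends)
    bp <- sum(as.numeric(GenomicRanges::width(gr)))
    data.frame(t_hours = t, L_bp = L, at_risk_bp = bp,
               genome_fraction = bp / G)
  })
  out <- do.call(rbind, rows)
  attr(out, "static_coverage") <-
    sum(as.numeric(GenomicRanges::width(merge_intervals(ann)))) / G
  attr(out, "static_coverage_unmerged") <-
    sum(as.numeric(GenomicRanges::width(ann))) / G
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' At-risk intervals at a single time point
#'
#' @inheritParams resection_risk_fraction
#' @return Merged `GRanges` of break positions at risk at time `t`.
#' @export
at_risk_intervals <- function(ann, t, params = resection_params(),
                              mode = c("exposure", "naive"),
                              both_ends = FALSE) {
  mode <- match.arg(mode)
  stopifnot(t >= 0)
  at_risk_intervals_(ann, params$speed * t, params$min_exposure,
                     mode, both_ends)
}

#' Exhaustive per-base verification oracle for the resection model
#'
#' Independent reference computation: every base of the genome is visited
#' and the break is simulated in the middle of that base (continuous
#' position `i + 0.5`). The two resection tracts `(x-L, x)` and `(x, x+L)`
#' are intersected with every repeat; the base is at risk if the maximal
#' contiguous overlap of either tract with some single repeat is at least
#' `min_exposure`. Returns the marked fraction. Intended for small genomes;
#' refuses genomes above 10 Mb (use the closed form there).
#'
#' @param ann Repeat annotation (`GRanges` with seqlengths).
#' @param L Resection tract length in bp.
#' @param min_exposure Minimal contiguous exposure in bp.
#' @param both_ends Require both tracts to expose a repeat.
#' @return Fraction of genome positions at risk.
#' @export
per_base_oracle <- function(ann, L, min_exposure = 300, both_ends = FALSE) {
  G <- genome_length(ann)
  if (G > 1e7) {
    stop("genome too large for per-base enumeration (>10 Mb); ",
         "use resection_risk_fraction()")
  }
  sl <- GenomeInfoDb::seqlengths(ann)
  E <- min_exposure
  at_risk_bp <- 0
  for (chrom in names(sl)) {
    C <- as.numeric(sl[[chrom]])
    on_chr <- ann[as.character(GenomicRanges::seqnames(ann)) == chrom]
    if (length(on_chr) == 0L) next
    left_ok <- logical(C)
    right_ok <- logical(C)
    for (k in seq_along(on_chr)) {
      s <- GenomicRanges::start(on_chr)[k] - 1
      e <- GenomicRanges::end(on_chr)[k]
      lo <- max(0, floor(s - L)); hi <- min(C - 1, ceiling(e + L))
      if (hi < lo) next
      i <- lo:hi
      x <- i + 0.5
      right_ov <- pmin(e, x + L) - pmax(s, x)
      left_ov <- pmin(e, x) - pmax(s, x - L)
      right_ok[i + 1] <- right_ok[i + 1] | (right_ov >= E)
      left_ok[i + 1] <- left_ok[i + 1] | (left_ov >= E)
    }
    hit <- if (both_ends) left_ok & right_ok else left_ok | right_ok
    at_risk_bp <- at_risk_bp + sum(hit)
  }
  at_risk_bp / G
}

#' Exhaustive per-base oracle for crossover eligibility
#'
#' Visits every base, places the break in the middle of that base, and marks
#' it eligible if it lies strictly more than `margin` bp from both edges of
#' some repeat.
#'
#' @inheritParams co_risk_fraction
#' @return Fraction of genome positions eligible.
#' @export
per_base_co_oracle <- function(ann, margin = 300) {
  G <- genome_length(ann)
  if (G > 1e7) stop("genome too large for per-base enumeration (>10 Mb)")
  sl <- GenomeInfoDb::seqlengths(ann)
  eligible_bp <- 0
  for (chrom in names(sl)) {
    C <- as.numeric(sl[[chrom]])
    on_chr <- ann[as.character(GenomicRanges::seqnames(ann)) == chrom]
    if (length(on_chr) == 0L) next
    ok <- logical(C)
    for (k in seq_along(on_chr)) {
      s <- GenomicRanges::start(on_chr)[k] - 1
      e <- GenomicRanges::end(on_chr)[k]
      i <- seq.int(max(0, floor(s)), min(C - 1, ceiling(e)))
      x <- i + 0.5
      ok[i + 1] <- ok[i + 1] | ((x - s > margin) & (e - x > margin))
    }
    eligible_bp <- eligible_bp + sum(ok)
  }
  eligible_bp / G
}

#' Write a risk profile as TSV
#'
#' @param profile Result of [risk_profile()].
#' @param path Output path.
#' @param ... Extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_risk_profile <- function(profile, path, ...) {
  p <- attr(profile, "params")
  write_provenance_header(
    path,
    mode = attr(profile, "mode"),
    speed_bp_per_h = p$speed, min_exposure_bp = p$min_exposure,
    static_coverage = attr(profile, "static_coverage"),
    static_coverage_unmerged = attr(profile, "static_coverage_unmerged"),
    ...)
  append_tsv(as.data.frame(profile), path)
}
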