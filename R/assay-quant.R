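sem <- function(x) sd(x) / sqrt(length(x))

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", what, "` must be finite and non-negative")
  }
}

#' Relative signal level against matched in-parallel controls
#'
#' Per-replicate sample/control ratios for paired measurements (each sample
#' scored in parallel with its matched control), with their mean and SEM.
#' The ratio of group means is also reported.
#'
#' @param samples,matched_controls Equal-length paired signal vectors;
#'   controls must be strictly positive.
#' @return List with `ratios` (per replicate), `mean_ratio`, `sem`,
#'   `ratio_of_means`, `n`.
#' @export
relative_level <- function(samples, matched_controls) {
  if (length(samples) != length(matched_controls)) {
    stop("`samples` and `matched_controls` must be paired (equal length)")
  }
  check_positive(samples, "samples")
  check_positive(matched_controls, "matched_controls")
  if (any(matched_controls == 0)) {
    stop("zero control signal: relative level undefined")
  }
  r <- samples / matched_controls
  list(ratios = r, mean_ratio = mean(r), sem = sem(r),
       ratio_of_means = mean(samples) / mean(matched_controls),
       n = length(r))
}

#' Fold inhibition between two signal groups
#'
#' `mean(inactive) / mean(active)`: values above 1 mean the "active"
#' condition (e.g. donor transcription) suppresses the signal. A
#' mean-of-per-replicate-ratios variant is available for paired groups.
#'
#' @param inactive,active Signal vectors for the two conditions; both group
#'   means must be positive (a zero active mean is reported as `Inf` with a
#'   warning rather than an error).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"` (paired
#'   groups of equal length only).
#' @return Fold value (> 0, possibly `Inf`).
#' @export
fold_inhibition <- function(inactive, active,
                            method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  check_positive(inactive, "inactive")
  check_positive(active, "active")
  if (mean(inactive) <= 0) stop("inactive group mean must be > 0")
  if (mean(active) == 0) {
    warning("active group mean is zero; fold inhibition is infinite")
    return(Inf)
  }
  if (method == "mean_of_ratios") {
    if (length(inactive) != length(active)) {
      stop("mean_of_ratios requires paired groups of equal length")
    }
    return(mean(inactive / active))
  }
  mean(inactive) / mean(active)
}

#' Donor preference fold
#'
#' Fold preference for engaging the intra-chromosomal over the
#' inter-chromosomal donor: `mean(intra) / mean(inter)`. When the two
#' vectors are paired (same strain measures both donors), per-replicate
#' ratios are reported too.
#'
#' @param intra,inter Signal vectors; `inter` mean must be positive.
#' @param paired Whether replicates are paired across the two vectors.
#' @return List with `fold`, and for paired input `ratios`, `mean_ratio`,
#'   `sem`.
#' @export
donor_preference <- function(intra, inter, paired = length(intra) == length(inter)) {
  check_positive(intra, "intra")
  check_positive(inter, "inter")
  if (mean(inter) == 0) stop("zero inter-donor mean: preference undefined")
  out <- list(fold = mean(intra) / mean(inter), n = length(intra))
  if (paired) {
    if (length(intra) != length(inter)) {
      stop("paired preference requires equal-length vectors")
    }
    if (any(inter == 0)) stop("zero inter-donor replicate: ratio undefined")
    r <- intra / inter
    out$ratios <- r
    out$mean_ratio <- mean(r)
    out$sem <- sem(r)
  }
  out
}

#' Recombinant product frequency normalized to circularization efficiency
#'
#' Converts junction signals (non-crossover or crossover circles) into the
#' percentage of broken molecules repaired into that product:
#' `(junction / loading) / (circ_control / loading) * 100` per replicate.
#' The loading control cancels algebraically but is kept in the contract so
#' inputs mirror the assay's measured quantities.
#'
#' @param junction Junction signal per replicate.
#' @param circ_control Circularization-control signal per replicate (> 0).
#' @param loading Loading-control signal per replicate (> 0).
#' @return List with `percent` (per replicate), `mean`, `sem`, `n`.
#' @export
recombinant_frequency <- function(junction, circ_control, loading) {
  stopifnot(length(junction) == length(circ_control),
            length(junction) == length(loading))
  check_positive(junction, "junction")
  if (any(circ_control <= 0)) stop("zero circularization control")
  if (any(loading <= 0)) stop("zero loading control")
  pct <- 100 * (junction / loading) / (circ_control / loading)
  list(percent = pct, mean = mean(pct), sem = sem(pct), n = length(pct))
}

#' Plating viability percentage
#'
#' Colony survival after break induction relative to the uninduced plating:
#' `100 * (colonies_dsb / colonies_no_dsb) * dilution_factor`, where
#' `dilution_factor` corrects for unequal plating dilutions.
#'
#' @param colonies_dsb Colony count on inducing plates.
#' @param colonies_no_dsb Colony count on non-inducing plates (> 0).
#' @param dilution_factor Ratio correcting plating dilutions (default 1).
#' @return Viability percentage (vectorized over replicates).
#' @export
plating_viability <- function(colonies_dsb, colonies_no_dsb,
                              dilution_factor = 1) {
  check_positive(colonies_dsb, "colonies_dsb")
  if (any(colonies_no_dsb <= 0)) {
    stop("zero uninduced colony count: viability undefined")
  }
  100 * (colonies_dsb / colonies_no_dsb) * dilution_factor
}

#' Break-dependent translocation (MIR) frequency
#'
#' Frequency of selectable recombinants among viable cells with break
#' induction (galactose) minus the background frequency without induction
#' (glucose), floored at zero. Both raw frequencies are always reported.
#'
#' @param lys_plus_gal,viable_gal Recombinant and viable counts with
#'   induction.
#' @param lys_plus_glu,viable_glu Recombinant and viable counts without
#'   induction.
#' @return List with `frequency` (break-dependent), `freq_gal`, `freq_glu`.
#' @export
mir_frequency <- function(lys_plus_gal, viable_gal,
                          lys_plus_glu, viable_glu) {
  check_positive(lys_plus_gal, "lys_plus_gal")
  check_positive(lys_plus_glu, "lys_plus_glu")
  if (any(viable_gal <= 0) || any(viable_glu <= 0)) {
    stop("zero viable count: frequency undefined")
  }
  f_gal <- lys_plus_gal / viable_gal
  f_glu <- lys_plus_glu / viable_glu
  list(frequency = pmax(0, f_gal - f_glu),
       freq_gal = f_gal, freq_glu = f_glu)
}

#' Two-group comparison with the small-n test-switch rule
#'
#' Two-tailed non-parametric Mann-Whitney-Wilcoxon comparison (exact null
#' for small samples without ties), switching to a two-tailed Student
#' t-test when either group has fewer than 4 replicates. Identical constant
#' groups return p = 1 by convention.
#'
#' @param group_a,group_b Value vectors (each n >= 2).
#' @param paired Paired comparison (requires equal lengths).
#' @return List with `p.value`, `method` (`"wilcoxon"` or `"t"`), `n_a`,
#'   `n_b`, `paired`.
#' @export
rank_sum_compare <- function(group_a, group_b, paired = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2")
  }
  if (paired && length(group_a) != length(group_b)) {
    stop("paired comparison requires equal group sizes")
  }
  use_t <- min(length(group_a), length(group_b)) < 4L
  degenerate <- if (paired) {
    all(group_a == group_b)
  } else {
    length(unique(c(group_a, group_b))) == 1L
  }
  if (degenerate) {
    return(list(p.value = 1, method = if (use_t) "t" else "wilcoxon",
                n_a = length(group_a), n_b = length(group_b),
                paired = paired))
  }
  if (use_t) {
    ok <- tryCatch(
      stats::t.test(group_a, group_b, paired = paired,
                    alternative = "two.sided"),
      error = function(e) NULL)
    p <- if (is.null(ok)) 1 else ok$p.value
    method <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, paired = paired,
                         alternative = "two.sided", exact = TRUE))
    p <- ht$p.value
    method <- "wilcoxon"
  }
  list(p.value = p, method = method,
       n_a = length(group_a), n_b = length(group_b), paired = paired)
}

#' Read a replicate-level assay table
#'
#' @param path TSV with header columns `strain`, `condition`, `replicate`,
#'   `kind`, `value` and optionally `pair_id`.
#' @return data.frame with those columns; values checked non-negative.
#' @export
read_assay_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("strain", "condition", "replicate", "kind", "value")
  if (!all(need %in% names(tab))) {
    stop("assay table needs columns: ", paste(need, collapse = ", "))
  }
  check_positive(tab$value, "value")
  tab
}
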