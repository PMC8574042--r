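#' Calling enhancer regions from per-bin probabilities
#'
#' Bins at or above the probability threshold (0.8 by default) form
#' candidate regions; neighbouring candidates within 100 bp are merged when
#' the average probability over their member bins stays strictly above the
#' threshold; regions are then classed by size (fragment < 50 bp,
#' enhancer 50 bp - 1 kb, super-enhancer > 1 kb) and, against a reference
#' enhancer set, by origin (common / putative / reference-only).
#'
#' @name enhancer-calling
NULL

#' Calling configuration
#'
#' @param threshold Probability threshold; a bin is a candidate when its
#'   probability is `>= threshold` ("0.8 or higher"), while merging
#'   requires the combined mean to be strictly `> threshold`.
#' @param merge_gap Maximum gap (bp) between neighbouring regions
#'   considered for merging.
#' @param min_size Regions shorter than this are fragments (bp).
#' @param super_size Regions longer than this are super-enhancers (bp).
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(threshold = 0.8, merge_gap = 100, min_size = 50,
                           super_size = 1000) {
  if (!.is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    .stopf("threshold must lie strictly inside (0, 1)")
  if (merge_gap < 0) .stopf("merge_gap must be >= 0")
  if (min_size >= super_size)
    .stopf("fragment bound must be below the super-enhancer bound")
  structure(list(threshold = threshold, merge_gap = merge_gap,
                 min_size = min_size, super_size = super_size),
            class = "calling_config")
}

#' Maximal runs of high-probability bins
#'
#' @param probabilities Per-bin enhancer probabilities.
#' @param bins The [tile_genome()] grid the probabilities live on.
#' @param config A [calling_config()].
#' @return `GRanges` of candidate regions with metadata `mean_prob`,
#'   `sum_prob`, `n_bins` (the member-bin bookkeeping that merging needs).
#' @export
call_candidate_regions <- function(probabilities, bins, config = calling_config()) {
  stopifnot(inherits(bins, "genome_bins"))
  if (length(probabilities) != length(bins$gr))
    .stopf("probabilities length (%d) does not match bin count (%d)",
           length(probabilities), length(bins$gr))
  hot <- probabilities >= config$threshold
  if (!any(hot)) return(.empty_regions())
  gr <- bins$gr
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    p = probabilities, hot = hot)
  dt[, run := data.table::rleid(chrom, hot)]
  regions <- dt[hot == TRUE,
                list(chrom = chrom[1L], start = start[1L], end = end[.N],
                     sum_prob = sum(p), n_bins = .N), by = "run"]
  out <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end),
    sum_prob = regions$sum_prob, n_bins = regions$n_bins,
    mean_prob = regions$sum_prob / regions$n_bins)
  GenomeInfoDb::seqlevels(out) <- names(bins$chrom_sizes)
  GenomeInfoDb::seqlengths(out) <- bins$chrom_sizes
  out
}

.empty_regions <- function() {
  GenomicRanges::GRanges(sum_prob = numeric(), n_bins = integer(),
                         mean_prob = numeric())
}

#' Merge neighbouring candidate regions
#'
#' Greedy left-to-right scan iterated to a fixpoint: an adjacent pair less
#' than or equal to `merge_gap` bp apart is merged iff the mean probability
#' over the two regions' member bins (gap bins excluded from the mean,
#' included in the span) is strictly above the threshold.
#'
#' @param candidates Output of [call_candidate_regions()] (sorted; unsorted
#'   input is sorted with a warning).
#' @param config A [calling_config()].
#' @return `GRanges` of merged regions with `mean_prob` and `size_class`.
#' @export
merge_regions <- function(candidates, config = calling_config()) {
  if (!length(candidates)) return(.classify(candidates, config))
  if (is.unsorted(GenomicRanges::order(candidates))) {
    .warnf("candidates were not sorted; sorting")
    candidates <- sort(candidates)
  }
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(candidates)),
    start = GenomicRanges::start(candidates),
    end = GenomicRanges::end(candidates),
    sum_prob = candidates$sum_prob, n_bins = candidates$n_bins,
    stringsAsFactors = FALSE)
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(df)) {
      same <- df$chrom[i] == df$chrom[i + 1L]
      gap <- df$start[i + 1L] - df$end[i] - 1L
      if (same && gap <= config$merge_gap) {
        mean_p <- (df$sum_prob[i] + df$sum_prob[i + 1L]) /
          (df$n_bins[i] + df$n_bins[i + 1L])
        # strictly "above" the threshold; the epsilon keeps the boundary
        # decision (combined mean exactly at threshold -> no merge) robust
        # to summation order
        if (mean_p > config$threshold + 1e-9) {
          df$end[i] <- df$end[i + 1L]
          df$sum_prob[i] <- df$sum_prob[i] + df$sum_prob[i + 1L]
          df$n_bins[i] <- df$n_bins[i] + df$n_bins[i + 1L]
          df <- df[-(i + 1L), , drop = FALSE]
          merged_any <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  out <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    sum_prob = df$sum_prob, n_bins = df$n_bins,
    mean_prob = df$sum_prob / df$n_bins)
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(candidates)
  GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(candidates)
  .classify(out, config)
}

.classify <- function(regions, config) {
  w <- IRanges::width(regions)
  regions$size_class <- ifelse(w < config$min_size, "fragment",
                        ifelse(w > config$super_size, "super_enhancer",
                               "enhancer"))
  regions
}

#' Size class of a region
#'
#' @param width Region width(s) in bp.
#' @param config A [calling_config()].
#' @return `"fragment"` (< 50 bp), `"enhancer"` (50 bp - 1 kb) or
#'   `"super_enhancer"` (> 1 kb).
#' @export
classify_size <- function(width, config = calling_config()) {
  ifelse(width < config$min_size, "fragment",
         ifelse(width > config$super_size, "super_enhancer", "enhancer"))
}

#' Classify predictions against a reference enhancer set
#'
#' A predicted region overlapping a reference region by at least 1 bp is
#' `common`; otherwise `putative`. A reference region with no predicted
#' overlap is `reference_only`.
#'
#' @param predicted `GRanges` of predicted regions.
#' @param reference `GRanges` of reference (e.g. reporter-assay) enhancers.
#' @return List with `predicted` (input plus `origin_class`),
#'   `reference_only` (`GRanges`) and `summary` (named counts).
#' @export
compare_to_reference <- function(predicted, reference) {
  ov <- IRanges::overlapsAny(predicted, reference, minoverlap = 1L)
  predicted$origin_class <- ifelse(ov, "common", "putative")
  ref_only <- reference[!IRanges::overlapsAny(reference, predicted,
                                              minoverlap = 1L)]
  list(predicted = predicted, reference_only = ref_only,
       summary = c(common = sum(ov), putative = sum(!ov),
                   reference_only = length(ref_only)))
}

#' Call enhancer regions from a trained model
#'
#' Convenience wrapper: inference, candidate detection, merging, size and
#' (optionally) origin classification.
#'
#' @param rulebase A trained [rule_base()].
#' @param dataset A [bin_dataset()].
#' @param config A [calling_config()].
#' @param reference Optional reference enhancer `GRanges`.
#' @param drop_fragments Drop sub-50 bp fragments from the result (the
#'   default downstream behaviour).
#' @return `GRanges` of called regions.
#' @export
call_enhancers <- function(rulebase, dataset, config = calling_config(),
                           reference = NULL, drop_fragments = TRUE) {
  p <- predict_probability(rulebase, dataset$features)
  regions <- merge_regions(call_candidate_regions(p, dataset$bins, config),
                           config)
  if (drop_fragments) regions <- regions[regions$size_class != "fragment"]
  if (!is.null(reference))
    regions <- compare_to_reference(regions, reference)$predicted
  regions
}

#' Write called regions as BED6
#'
#' Name encodes the origin class (or size class when no reference was
#' given); score is 1000 x mean probability.
#'
#' @param regions Called regions.
#' @param path Output path.
#' @export
write_calls <- function(regions, path) {
  out <- regions
  out$name <- if (!is.null(regions$origin_class)) regions$origin_class
              else regions$size_class
  out$score <- round(1000 * regions$mean_prob)
  out$sum_prob <- NULL
  out$n_bins <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
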