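#' Genome tiling, signal mapping and labeled bin datasets
#'
#' The genome is tiled into fixed-width bins (10 bp by default, matching the
#' resolution at which smoothed ChIP enrichment scores are analysed), signal
#' tracks are aggregated per bin and min-max normalized, reporter-assay peaks
#' are expanded and converted into binary bin labels, and a stratified sample
#' of labeled bins forms the training material for rule induction.
#'
#' Coordinates are held as `GRanges` (1-based closed, the Bioconductor
#' convention); BED/bedGraph files are converted on read/write by
#' `rtracklayer`.
#'
#' @name genome-tracks
NULL

#' Tile a genome into fixed-width bins
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp), or a
#'   two-column data frame (chrom, size).
#' @param width Bin width in bp (default 10).
#' @param exclude Chromosomes to drop (e.g. sex chromosomes, excluded to
#'   avoid dosage-compensation biases).
#' @return An object of class `genome_bins`: a list with `gr` (the tiling as
#'   `GRanges`, last bin per chromosome possibly shorter), `width`,
#'   `chrom_sizes`.
#' @export
tile_genome <- function(chrom_sizes, width = 10, exclude = character()) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  if (!length(chrom_sizes)) .stopf("empty genome: no chromosomes given")
  if (any(chrom_sizes <= 0)) .stopf("chromosome sizes must be positive")
  if (width < 1) .stopf("bin width must be >= 1")
  unknown <- setdiff(exclude, names(chrom_sizes))
  if (length(unknown))
    .warnf("excluded chromosome(s) not in genome: %s",
           paste(unknown, collapse = ", "))
  keep <- setdiff(names(chrom_sizes), exclude)
  chrom_sizes <- chrom_sizes[keep]
  if (!length(chrom_sizes))
    return(structure(list(gr = GenomicRanges::GRanges(), width = width,
                          chrom_sizes = chrom_sizes), class = "genome_bins"))
  grl <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(1L, len, by = width)
    GenomicRanges::GRanges(
      factor(rep(ch, length(starts)), levels = names(chrom_sizes)),
      IRanges::IRanges(start = starts, end = pmin(starts + width - 1L, len)))
  })
  gr <- do.call(c, grl)
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  n_per_chrom <- vapply(grl, length, integer(1))
  offsets <- setNames(cumsum(c(0L, head(n_per_chrom, -1L))),
                      names(chrom_sizes))
  structure(list(gr = gr, width = width, chrom_sizes = chrom_sizes,
                 offsets = offsets),
            class = "genome_bins")
}

# Bin indices covering [start, end] (1-based closed) on one chromosome, or
# NULL when the window leaves the chromosome.
.bin_index_range <- function(bins, chrom, start, end) {
  len <- bins$chrom_sizes[[chrom]]
  if (is.null(len) || is.na(len) || start < 1 || end > len || end < start)
    return(NULL)
  off <- bins$offsets[[chrom]]
  (off + (start - 1L) %/% bins$width + 1L):(off + (end - 1L) %/% bins$width + 1L)
}

#' @export
length.genome_bins <- function(x) length(x$gr)

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome bins: %d bins of %d bp over %d chromosome(s)\n",
              length(x$gr), x$width, length(x$chrom_sizes)))
  invisible(x)
}

#' Aggregate interval records onto the bin grid
#'
#' Each bin receives the coverage-weighted mean of the record values
#' overlapping it (weights are overlap lengths); bins touched by no record
#' get 0. Records extending past chromosome ends are clipped.
#'
#' @param records A `GRanges` with a `score` column, or a data frame with
#'   columns chrom, start, end (0-based half-open), value.
#' @param bins A [tile_genome()] result.
#' @param aggregator `"wmean"` (default), `"mean"` (unweighted over
#'   overlapping records) or `"max"`.
#' @param mark Mark name recorded on the returned track.
#' @return An object of class `signal_track`: list with `mark`, `values`
#'   (one per bin), `normalized` flag.
#' @export
map_signal_to_bins <- function(records, bins, aggregator = c("wmean", "mean", "max"),
                               mark = "signal") {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(bins, "genome_bins"))
  if (is.data.frame(records)) {
    bad <- which(!is.finite(records[[4]]) | records[[3]] <= records[[2]])
    if (length(bad))
      .stopf("malformed signal record at line %d", bad[1])
    records <- GenomicRanges::GRanges(
      as.character(records[[1]]),
      IRanges::IRanges(start = records[[2]] + 1L, end = records[[3]]),
      score = as.numeric(records[[4]]))
  }
  values <- numeric(length(bins$gr))
  if (length(records)) {
    records <- records[as.character(GenomeInfoDb::seqnames(records)) %in%
                         names(bins$chrom_sizes)]
    # clip to chromosome bounds
    lens <- bins$chrom_sizes[as.character(GenomeInfoDb::seqnames(records))]
    GenomicRanges::start(records) <- pmax(GenomicRanges::start(records), 1L)
    GenomicRanges::end(records) <- pmin(GenomicRanges::end(records), lens)
    hits <- GenomicRanges::findOverlaps(bins$gr, records)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(bins$gr)[qh], IRanges::ranges(records)[sh]))
      v <- records$score[sh]
      dt <- data.table::data.table(bin = qh, w = ov, v = v)
      agg <- switch(aggregator,
        wmean = dt[, list(val = sum(w * v) / sum(w)), by = "bin"],
        mean  = dt[, list(val = mean(v)), by = "bin"],
        max   = dt[, list(val = max(v)), by = "bin"])
      values[agg$bin] <- agg$val
    }
  }
  structure(list(mark = mark, values = values, normalized = FALSE,
                 norm_bounds = NULL),
            class = "signal_track")
}

#' Construct a signal track directly from per-bin values
#'
#' @param mark Mark name.
#' @param values Numeric vector, one value per bin.
#' @param normalized Whether the values are already min-max normalized.
#' @return A `signal_track`.
#' @export
signal_track <- function(mark, values, normalized = FALSE) {
  structure(list(mark = mark, values = as.numeric(values),
                 normalized = normalized, norm_bounds = NULL),
            class = "signal_track")
}

#' Min-max normalize a signal track
#'
#' Maps values linearly onto [0, 1]; a constant track maps to all zeros
#' (it carries no information and a zero division is avoided).
#'
#' @param track A `signal_track` not yet normalized.
#' @return The normalized track, with the original bounds recorded in
#'   `norm_bounds`.
#' @export
minmax_normalize <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  if (isTRUE(track$normalized))
    .stopf("track '%s' is already normalized", track$mark)
  if (anyNA(track$values))
    .stopf("track '%s' contains NA/NaN values", track$mark)
  lo <- min(track$values); hi <- max(track$values)
  track$values <- if (hi > lo) (track$values - lo) / (hi - lo)
                  else numeric(length(track$values))
  track$normalized <- TRUE
  track$norm_bounds <- c(min = lo, max = hi)
  track
}

#' Expand reporter-assay peaks to a target width
#'
#' Each peak narrower than `target_width` is replaced by a `target_width`
#' interval centered on its midpoint (wider peaks are kept as they are, so
#' expansion never shrinks a peak), clipped to the chromosome; overlapping
#' results are merged.
#'
#' @param peaks `GRanges` of peaks.
#' @param target_width Target width in bp (default 400).
#' @param chrom_sizes Named vector of chromosome lengths used for clipping;
#'   taken from `seqlengths(peaks)` when omitted.
#' @return Merged `GRanges`.
#' @export
expand_peaks <- function(peaks, target_width = 400, chrom_sizes = NULL) {
  stopifnot(methods::is(peaks, "GRanges"))
  if (is.null(chrom_sizes)) chrom_sizes <- GenomeInfoDb::seqlengths(peaks)
  lens <- chrom_sizes[as.character(GenomeInfoDb::seqnames(peaks))]
  if (anyNA(lens))
    .stopf("peak on chromosome without a known length")
  if (any(GenomicRanges::start(peaks) < 1) ||
      any(GenomicRanges::end(peaks) > lens))
    .stopf("peak lies outside its chromosome")
  narrow <- IRanges::width(peaks) < target_width
  if (any(narrow))
    peaks[narrow] <- GenomicRanges::resize(peaks[narrow], width = target_width,
                                           fix = "center")
  GenomicRanges::start(peaks) <- pmax(GenomicRanges::start(peaks), 1L)
  GenomicRanges::end(peaks) <- pmin(GenomicRanges::end(peaks), lens)
  GenomicRanges::reduce(peaks)
}

#' Label bins by overlap with enhancer regions
#'
#' A bin is labeled enhancer iff it overlaps any region by at least 1 bp.
#'
#' @param bins A [tile_genome()] result.
#' @param regions `GRanges` of enhancer regions (empty set allowed).
#' @return Logical vector, one flag per bin (`TRUE` = enhancer).
#' @export
label_bins <- function(bins, regions) {
  stopifnot(inherits(bins, "genome_bins"))
  if (!length(regions)) return(logical(length(bins$gr)))
  IRanges::overlapsAny(bins$gr, regions, minoverlap = 1L)
}

#' Bundle bins, features and labels into a dataset
#'
#' @param bins A [tile_genome()] result.
#' @param tracks List of normalized `signal_track`s (names become the
#'   feature order).
#' @param labels Logical label per bin (enhancer = `TRUE`).
#' @return An object of class `bin_dataset`: `bins`, `features` (matrix,
#'   one named column per mark), `labels`, `feature_order`.
#' @export
bin_dataset <- function(bins, tracks, labels) {
  stopifnot(inherits(bins, "genome_bins"))
  n <- length(bins$gr)
  if (length(labels) != n)
    .stopf("labels length (%d) does not match bin count (%d)",
           length(labels), n)
  feats <- lapply(tracks, function(t) {
    if (inherits(t, "signal_track")) {
      if (length(t$values) != n)
        .stopf("track '%s' length does not match bin count", t$mark)
      t$values
    } else as.numeric(t)
  })
  marks <- if (!is.null(names(tracks)) && all(nzchar(names(tracks))))
    names(tracks) else vapply(tracks, `[[`, character(1), "mark")
  X <- do.call(cbind, feats)
  colnames(X) <- marks
  structure(list(bins = bins, features = X, labels = as.logical(labels),
                 feature_order = marks),
            class = "bin_dataset")
}

#' @export
print.bin_dataset <- function(x, ...) {
  cat(sprintf("bin dataset: %d bins x %d marks, %.2f%% enhancer\n",
              nrow(x$features), ncol(x$features), 100 * mean(x$labels)))
  invisible(x)
}

# subset a bin_dataset by bin index, keeping the bin grid bookkeeping
.subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$bins$gr <- dataset$bins$gr[idx]
  out$features <- dataset$features[idx, , drop = FALSE]
  out$labels <- dataset$labels[idx]
  out
}

#' Stratified sampling and train/test split of a bin dataset
#'
#' Samples `n` bins without replacement, preserving the genome-wide
#' enhancer:non-enhancer ratio to within one bin per class, then splits
#' train/test with the same stratification. Deterministic under `seed`.
#'
#' @param dataset A [bin_dataset()].
#' @param n Number of bins to sample (default 1e6, capped at the dataset
#'   size).
#' @param test_fraction Fraction of the sample held out for testing.
#' @param seed Integer seed.
#' @return List with `train` and `test` (both `bin_dataset`s) and the
#'   sampled indices.
#' @export
sample_training_set <- function(dataset, n = 1e6, test_fraction = 0.3,
                                seed = NULL) {
  stopifnot(inherits(dataset, "bin_dataset"))
  .check_fraction(test_fraction, "test_fraction")
  n_total <- nrow(dataset$features)
  n <- min(n, n_total)
  pos <- which(dataset$labels)
  neg <- which(!dataset$labels)
  if (!length(pos) || !length(neg))
    .stopf("both classes must be present genome-wide (have %d enhancer, %d non-enhancer bins)",
           length(pos), length(neg))
  n_pos <- round(n * length(pos) / n_total)
  n_pos <- max(1L, min(n_pos, length(pos)))
  n_neg <- n - n_pos
  .with_seed(seed, {
    s_pos <- sort(.resample(pos, n_pos))
    s_neg <- sort(.resample(neg, n_neg))
    t_pos <- sort(.resample(s_pos, round(test_fraction * n_pos)))
    t_neg <- sort(.resample(s_neg, round(test_fraction * n_neg)))
  })
  test_idx <- sort(c(t_pos, t_neg))
  train_idx <- sort(setdiff(c(s_pos, s_neg), test_idx))
  list(train = .subset_dataset(dataset, train_idx),
       test = .subset_dataset(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Build a labeled dataset from track and peak files
#'
#' Convenience wrapper over the read/tile/map/normalize/label steps: tiles
#' the genome, maps each signal file onto the bins, min-max normalizes,
#' expands peaks to 400 bp and labels overlapping bins.
#'
#' @param chrom_sizes_file Two-column TSV (chrom, size).
#' @param track_files Named character vector `mark = path` of
#'   bedGraph/wiggle files.
#' @param peaks_file BED file of reporter-assay enhancer peaks.
#' @param bin_width Bin width in bp.
#' @param exclude Chromosomes to exclude.
#' @param peak_width Peak expansion target (bp).
#' @return A [bin_dataset()].
#' @export
make_dataset <- function(chrom_sizes_file, track_files, peaks_file,
                         bin_width = 10, exclude = character(),
                         peak_width = 400) {
  sizes <- read_chrom_sizes(chrom_sizes_file)
  bins <- tile_genome(sizes, width = bin_width, exclude = exclude)
  tracks <- lapply(names(track_files), function(mark) {
    rec <- read_signal_track(track_files[[mark]])
    minmax_normalize(map_signal_to_bins(rec, bins, mark = mark))
  })
  names(tracks) <- names(track_files)
  peaks <- read_peaks(peaks_file)
  regions <- expand_peaks(peaks, target_width = peak_width,
                          chrom_sizes = sizes[!names(sizes) %in% exclude])
  bin_dataset(bins, tracks, label_bins(bins, regions))
}
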