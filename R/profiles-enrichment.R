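#' Region-anchored profiles, enrichment statistics and eRNA directionality
#'
#' Heatmap-style matrices of signal around region centers (size-sorted,
#' winsorized and rescaled), observed/expected enrichment of signal and of
#' genomic-feature overlap, TAD-border proximity, per-region body
#' percentile scores, and the log10 strand-ratio directionality score that
#' classifies enhancers as bidirectionally transcribed.
#'
#' @name profiles-enrichment
NULL

#' Signal matrix around region centers
#'
#' One row per region, columns at fixed offsets spanning +/- `flank` bp of
#' the region midpoint at bin resolution; rows sorted by region size,
#' largest first (ties keep coordinate order). Positions beyond chromosome
#' ends are NA.
#'
#' @param values Per-bin signal values.
#' @param bins The [tile_genome()] grid.
#' @param regions `GRanges` of regions.
#' @param flank Flank size in bp (default 5000).
#' @return A numeric matrix of class `profile_matrix` with attributes
#'   `positions` (bp offsets), `region_order` (indices into `regions`),
#'   `mode = "raw"`.
#' @export
profile_matrix <- function(values, bins, regions, flank = 5000) {
  stopifnot(inherits(bins, "genome_bins"))
  if (!length(regions)) .stopf("no regions given")
  bw <- bins$width
  offs <- seq(-flank, flank, by = bw)
  ord <- order(-IRanges::width(regions), GenomicRanges::start(regions))
  ch <- as.character(GenomeInfoDb::seqnames(regions))
  centers <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L
  mat <- matrix(NA_real_, length(regions), length(offs))
  for (k in seq_along(ord)) {
    i <- ord[k]
    pos <- centers[i] + offs
    len <- bins$chrom_sizes[[ch[i]]]
    ok <- pos >= 1 & pos <= len
    idx <- bins$offsets[[ch[i]]] + (pos[ok] - 1L) %/% bw + 1L
    mat[k, ok] <- values[idx]
  }
  structure(mat, positions = offs, region_order = ord, mode = "raw",
            class = c("profile_matrix", "matrix"))
}

#' Winsorize and rescale a profile matrix
#'
#' Unsigned mode (ChIP-style signal): negative entries are zeroed, positive
#' entries are capped at the `q` quantile of the positive entries and
#' rescaled to [0, 1]. Signed mode (stranded signal): positive and negative
#' entries are capped and rescaled separately onto [0, 1] and [-1, 0]. The
#' cap is the inverse-ECDF (type 1) quantile, which makes the transform
#' idempotent: re-applying it to its own output changes nothing.
#'
#' @param mat A `profile_matrix` (or plain matrix).
#' @param mode `"unsigned"` or `"signed"`.
#' @param q Winsorization quantile (default 0.95).
#' @param cap Optional explicit cap overriding the quantile.
#' @return The transformed matrix (attribute `mode` updated).
#' @export
winsorize_rescale <- function(mat, mode = c("unsigned", "signed"), q = 0.95,
                              cap = NULL) {
  mode <- match.arg(mode)
  m <- unclass(mat)
  pos <- m[!is.na(m) & m > 0]
  if (!length(pos)) {
    .warnf("matrix has no positive entries; returned unchanged")
    return(mat)
  }
  cap_pos <- if (!is.null(cap)) cap else
    unname(quantile(pos, q, type = 1, names = FALSE))
  if (mode == "unsigned") {
    m[m < 0] <- 0
    m <- pmin(m, cap_pos) / cap_pos
  } else {
    neg <- m[!is.na(m) & m < 0]
    p_idx <- !is.na(m) & m > 0
    m[p_idx] <- pmin(m[p_idx], cap_pos) / cap_pos
    if (length(neg)) {
      cap_neg <- if (!is.null(cap)) cap else
        unname(quantile(abs(neg), q, type = 1, names = FALSE))
      n_idx <- !is.na(m) & m < 0
      m[n_idx] <- -pmin(abs(m[n_idx]), cap_neg) / cap_neg
    }
  }
  structure(m, positions = attr(mat, "positions"),
            region_order = attr(mat, "region_order"),
            mode = mode, class = class(mat))
}

#' eRNA directionality score and class per region
#'
#' Nascent transcription is summed in 500 bp windows placed 500 bp outside
#' the region borders (downstream of the right border and upstream of the
#' left border, capturing divergent eRNA); the score is
#' `log10((P + pseudocount) / (N + pseudocount))` of the plus-strand sum P
#' and minus-strand magnitude sum N, so swapping the strand tracks negates
#' every score exactly. Regions with total flanking signal below
#' `transcription_floor` are non-transcribed; otherwise the class is
#' bidirectional when the score lies in [-0.5, 0.5], positive above,
#' negative below.
#'
#' @param plus,minus Per-bin values of the stranded tracks (minus may be
#'   stored negative; magnitudes are used).
#' @param bins The [tile_genome()] grid.
#' @param regions `GRanges` of regions.
#' @param window,offset Window geometry in bp (defaults 500/500).
#' @param pseudocount Added to both sums to keep the ratio finite at zero
#'   coverage (default 1 signal unit; use 0 for noise-free exact scores).
#' @param transcription_floor Total signal below which a region is
#'   non-transcribed.
#' @return Data frame `region_id`, `P`, `N`, `score`, `class`; regions
#'   whose flanking windows leave the chromosome get NA records.
#' @export
directionality_score <- function(plus, minus, bins, regions, window = 500,
                                 offset = 500, pseudocount = 1,
                                 transcription_floor = 1) {
  stopifnot(inherits(bins, "genome_bins"))
  n <- length(regions)
  ch <- as.character(GenomeInfoDb::seqnames(regions))
  s <- GenomicRanges::start(regions)
  e <- GenomicRanges::end(regions)
  P <- N <- score <- rep(NA_real_, n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ri <- .bin_index_range(bins, ch[i], e[i] + offset + 1L,
                           e[i] + offset + window)
    li <- .bin_index_range(bins, ch[i], s[i] - offset - window,
                           s[i] - offset - 1L)
    if (is.null(ri) || is.null(li)) next
    P[i] <- sum(abs(plus[c(li, ri)]))
    N[i] <- sum(abs(minus[c(li, ri)]))
    score[i] <- log10((P[i] + pseudocount) / (N[i] + pseudocount))
    cls[i] <- if (P[i] + N[i] < transcription_floor) "non_transcribed"
      else if (abs(score[i]) <= 0.5) "bidirectional"
      else if (score[i] > 0.5) "positive" else "negative"
  }
  data.frame(region_id = sprintf("region%05d", seq_len(n)),
             P = P, N = N, score = score, class = cls,
             stringsAsFactors = FALSE)
}

#' Observed/expected signal enrichment of a region group
#'
#' Observed is the mean track value over the bins inside the group's
#' regions; expected is the mean over all genome bins; the record carries
#' `log2(observed / expected)` with a small floor on the expected value.
#'
#' @param values Per-bin normalized signal.
#' @param regions Group regions (`GRanges`).
#' @param bins The bin grid.
#' @param floor Lower bound applied to `expected` (and `observed`) before
#'   the ratio.
#' @return List `observed`, `expected`, `log2_ratio`.
#' @export
obs_exp_signal_enrichment <- function(values, regions, bins, floor = 1e-9) {
  if (!length(regions)) .stopf("empty region group")
  inside <- IRanges::overlapsAny(bins$gr, regions)
  if (!any(inside)) .stopf("group regions overlap no bins")
  observed <- mean(values[inside])
  expected <- mean(values)
  list(observed = observed, expected = expected,
       log2_ratio = log2(max(observed, floor) / max(expected, floor)))
}

#' Partition the genome into annotation categories
#'
#' Builds disjoint category intervals from a gene annotation with the
#' precedence promoter > 5'UTR > 3'UTR > exon > first intron >
#' other introns > intergenic, so every base belongs to exactly one
#' category.
#'
#' @param annotation `GRanges` with `type` (gene/exon/five_prime_UTR/
#'   three_prime_UTR) and `Parent` columns, e.g. from
#'   [generate_annotation()] or [read_annotation()].
#' @param chrom_sizes Named chromosome lengths.
#' @param promoter_width Promoter size upstream of the TSS (bp).
#' @return Named `GRangesList`-like list of disjoint `GRanges`, one per
#'   category.
#' @export
annotation_categories <- function(annotation, chrom_sizes,
                                  promoter_width = 250) {
  genes <- annotation[annotation$type == "gene"]
  exons <- annotation[annotation$type == "exon"]
  utr5 <- annotation[annotation$type == "five_prime_UTR"]
  utr3 <- annotation[annotation$type == "three_prime_UTR"]
  promoters <- promoter_intervals(genes, chrom_sizes, width = promoter_width)
  # introns: gene bodies minus exons; the first intron is the one abutting
  # the most 5' exon of each gene
  introns_all <- GenomicRanges::GRanges()
  first_introns <- GenomicRanges::GRanges()
  parent_gene <- function(p) sub("\\.t1$", "", p)
  ex_by_gene <- split(exons, parent_gene(as.character(unlist(exons$Parent))))
  for (gid in names(ex_by_gene)) {
    g <- genes[genes$ID == gid]
    ex <- GenomicRanges::reduce(ex_by_gene[[gid]], ignore.strand = TRUE)
    ints <- GenomicRanges::setdiff(
      GenomicRanges::granges(g), GenomicRanges::granges(ex),
      ignore.strand = TRUE)
    if (!length(ints)) next
    introns_all <- c(introns_all, ints)
    first_idx <- if (as.character(GenomicRanges::strand(g)) == "+") 1L
                 else length(ints)
    first_introns <- c(first_introns, ints[first_idx])
  }
  other_introns <- GenomicRanges::setdiff(introns_all, first_introns,
                                          ignore.strand = TRUE)
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1L, as.integer(chrom_sizes)))
  layers <- list(promoter = promoters, five_prime_UTR = utr5,
                 three_prime_UTR = utr3, exon = exons,
                 first_intron = first_introns, other_intron = other_introns)
  out <- list()
  taken <- GenomicRanges::GRanges()
  for (nm in names(layers)) {
    layer <- GenomicRanges::reduce(GenomicRanges::granges(layers[[nm]]),
                                   ignore.strand = TRUE)
    layer <- GenomicRanges::setdiff(layer, taken, ignore.strand = TRUE)
    out[[nm]] <- layer
    taken <- GenomicRanges::reduce(c(taken, layer))
  }
  out$intergenic <- GenomicRanges::setdiff(genome, taken,
                                           ignore.strand = TRUE)
  out
}

#' Feature-overlap enrichment of a region set
#'
#' Observed is the fraction of region bases falling in each category;
#' expected is the genome-wide base fraction of that category.
#'
#' @param regions `GRanges` of regions.
#' @param categories Disjoint category list from [annotation_categories()].
#' @param chrom_sizes Named chromosome lengths (for the genome total).
#' @param floor Floor applied before the log ratio.
#' @return Data frame with one row per category: `category`, `observed`,
#'   `expected`, `log2_ratio`.
#' @export
feature_overlap_enrichment <- function(regions, categories, chrom_sizes,
                                       floor = 1e-9) {
  cat_gr <- lapply(categories, GenomicRanges::granges)
  for (i in seq_along(cat_gr)) for (j in seq_along(cat_gr)) {
    if (i < j && sum(IRanges::width(GenomicRanges::intersect(
          cat_gr[[i]], cat_gr[[j]], ignore.strand = TRUE))) > 0)
      .stopf("categories '%s' and '%s' overlap; resolve precedence first",
             names(categories)[i], names(categories)[j])
  }
  genome_total <- sum(as.numeric(chrom_sizes))
  region_total <- sum(IRanges::width(GenomicRanges::reduce(regions)))
  if (region_total == 0) .stopf("empty region set")
  rows <- lapply(names(categories), function(nm) {
    ov <- sum(as.numeric(IRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(GenomicRanges::granges(regions)), cat_gr[[nm]],
      ignore.strand = TRUE))))
    observed <- ov / region_total
    expected <- sum(as.numeric(IRanges::width(cat_gr[[nm]]))) / genome_total
    data.frame(category = nm, observed = observed, expected = expected,
               log2_ratio = log2(max(observed, floor) / max(expected, floor)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' TAD-border proximity flags
#'
#' @param regions `GRanges` of regions.
#' @param borders TAD borders as `GRanges` (positions or intervals).
#' @param distance Gap distance cutoff in bp (default 2000).
#' @return Logical vector: `TRUE` when the nearest border is within
#'   `distance` bp of the region.
#' @export
tad_proximity <- function(regions, borders, distance = 2000) {
  flags <- logical(length(regions))
  if (!length(borders) || !length(regions)) return(flags)
  hits <- GenomicRanges::distanceToNearest(regions, borders)
  flags[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(hits)$distance <= distance
  flags
}

#' Body percentile score of regions
#'
#' The `percentile`-th percentile (linear interpolation between order
#' statistics) of the track values over each region's bins.
#'
#' @param values Per-bin signal values.
#' @param bins The bin grid.
#' @param regions `GRanges` of regions.
#' @param percentile Percentile in (0, 100], default 95.
#' @return Numeric vector, one score per region.
#' @export
body_percentile_score <- function(values, bins, regions, percentile = 95) {
  stopifnot(inherits(bins, "genome_bins"))
  hits <- GenomicRanges::findOverlaps(bins$gr, regions)
  by_region <- split(S4Vectors::queryHits(hits),
                     factor(S4Vectors::subjectHits(hits),
                            levels = seq_along(regions)))
  vapply(seq_along(regions), function(i) {
    idx <- by_region[[i]]
    if (!length(idx))
      .stopf("region %d is shorter than one bin / overlaps no bin", i)
    unname(quantile(values[idx], percentile / 100, type = 7, names = FALSE))
  }, numeric(1))
}

#' Rank-based comparison of a score between region groups
#'
#' Two-sided Mann-Whitney U tests for every pair of groups.
#'
#' @param scores Numeric scores.
#' @param groups Group label per score.
#' @return Data frame `group1`, `group2`, `statistic`, `p_value`.
#' @export
compare_groups <- function(scores, groups) {
  gl <- unique(as.character(groups))
  pairs <- utils::combn(gl, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- scores[groups == pr[1]]
    b <- scores[groups == pr[2]]
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
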