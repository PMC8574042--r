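#' Synthetic genomes with planted enhancer rules
#'
#' The generator states a small, fully-seeded world mirroring what the
#' analysis assumes about real inputs: bounded per-mark signals whose
#' low/medium/high combinations (planted fuzzy rules) determine enhancer
#' labels, peak-shaped label regions of realistic widths, gene models with
#' promoters, promoter-anchored contact records with observed/expected
#' scores, zero-inflated lognormal expression, and stranded nascent
#' transcription with controllable strand asymmetry. All randomness flows
#' from a single seed, so every output is reproducible byte for byte.
#'
#' @name synthetic-data
NULL

.default_planted_rules <- function() {
  marks <- .default_mark_names(8)
  partitions <- lapply(setNames(marks, marks), fuzzy_partition)
  rules <- list(
    fuzzy_rule(c("H3K4me1", "H4K16ac"), c("high", "high"), "enhancer"),
    fuzzy_rule(c("H3K4me1", "H3K18ac"), c("high", "high"), "enhancer"),
    fuzzy_rule("H3K4me1", "low", "non_enhancer")
  )
  rule_base(rules, partitions)
}

.default_mark_names <- function(n) {
  pool <- c("H3K4me1", "H4K16ac", "H3K18ac", "H3K27ac", "H3K4me3",
            "H3K9ac", "H3K23ac", "H3K36me3", "H3K79me2", "H2Bubi",
            "H3K27me3", "H4K20me1")
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("mark%02d", seq_len(n - length(pool))))
}

#' Configuration for the synthetic generator
#'
#' Defaults describe a desk-scale fly-like test genome: a 2 Mb autosome
#' fragment, 8 marks, two planted enhancer rules (high H3K4me1 with either
#' high H4K16ac or high H3K18ac), 50 enhancers per Mb with widths of a few
#' hundred bp (reporter assays in fly cell lines annotate thousands of
#' enhancers of median size a few hundred bp across the ~120 Mb genome,
#' i.e. a few percent of bases), mild Gaussian signal noise and a 5%
#' label-flip rate emulating reporter-assay false calls.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_marks Number of signal tracks.
#' @param planted_rules A [rule_base()] of ground-truth rules; the default
#'   plants two two-mark enhancer rules.
#' @param enhancer_density Enhancer regions per Mb.
#' @param enhancer_width_range Width interval (bp).
#' @param min_separation Minimum gap enforced between planted enhancers (bp).
#' @param noise_sd Gaussian noise added to signals (signal units; signals
#'   are clipped back to [0, 1]).
#' @param label_noise_rate Fraction of bins whose label is flipped.
#' @param contact_model List with `p_contact_given_enhancer`,
#'   `p_contact_background` and `hic_bin` (anchor size, bp).
#' @param expression_model List with `meanlog`, `sdlog` (lognormal FPKM of
#'   enhancer-linked genes), `zero_inflation` (probability an unlinked gene
#'   is silent) and `bg_meanlog` for unlinked genes.
#' @param transcription_model List with `level` (signal per bin in the eRNA
#'   windows), `asymmetry` (plus:minus ratio; 1 = bidirectional),
#'   `window`/`offset` (bp) and `noise_sd`.
#' @param gene_density Genes per Mb for the synthetic annotation.
#' @param bin_width Bin width (bp).
#' @param background_max_firing Planted enhancer rules must fire below this
#'   level outside true enhancers (rejection sampling bound).
#' @param seed Integer seed determining every output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_sizes = c(chr2L = 1e6, chr2R = 1e6),
                             n_marks = 8,
                             planted_rules = NULL,
                             enhancer_density = 50,
                             enhancer_width_range = c(200, 1000),
                             min_separation = 1000,
                             noise_sd = 0.05,
                             label_noise_rate = 0.05,
                             contact_model = list(),
                             expression_model = list(),
                             transcription_model = list(),
                             gene_density = 20,
                             bin_width = 10,
                             background_max_firing = 0.5,
                             seed = 1) {
  if (is.null(planted_rules)) planted_rules <- .default_planted_rules()
  stopifnot(inherits(planted_rules, "rule_base"))
  if (any(chrom_sizes <= 0)) .stopf("chromosome sizes must be positive")
  if (any(enhancer_width_range <= 0) || diff(enhancer_width_range) < 0)
    .stopf("enhancer_width_range must be a positive increasing interval")
  .check_fraction(label_noise_rate, "label_noise_rate")
  if (noise_sd < 0) .stopf("noise_sd must be non-negative")
  contact_model <- modifyList(
    list(p_contact_given_enhancer = 0.8, p_contact_background = 0.05,
         hic_bin = 1000), contact_model)
  .check_fraction(contact_model$p_contact_given_enhancer,
                  "p_contact_given_enhancer")
  .check_fraction(contact_model$p_contact_background, "p_contact_background")
  expression_model <- modifyList(
    list(meanlog = 2, sdlog = 1, zero_inflation = 0.3, bg_meanlog = 0.5),
    expression_model)
  transcription_model <- modifyList(
    list(level = 10, asymmetry = 1, window = 500, offset = 500,
         noise_sd = 0), transcription_model)
  marks <- .default_mark_names(n_marks)
  planted_marks <- unique(unlist(lapply(planted_rules$rules, `[[`, "marks")))
  if (!all(planted_marks %in% marks))
    .stopf("planted rules reference marks beyond the %d generated ones (%s)",
           n_marks, paste(setdiff(planted_marks, marks), collapse = ", "))
  structure(list(chrom_sizes = chrom_sizes, n_marks = n_marks, marks = marks,
                 planted_rules = planted_rules,
                 enhancer_density = enhancer_density,
                 enhancer_width_range = enhancer_width_range,
                 min_separation = min_separation,
                 noise_sd = noise_sd, label_noise_rate = label_noise_rate,
                 contact_model = contact_model,
                 expression_model = expression_model,
                 transcription_model = transcription_model,
                 gene_density = gene_density, bin_width = bin_width,
                 background_max_firing = background_max_firing,
                 seed = seed),
            class = "synthetic_config")
}

# Place non-overlapping enhancer intervals by rejection sampling on the bin
# grid; widths are uniform in the configured range. Errors if the requested
# density cannot be placed after bounded retries.
.place_enhancers <- function(config) {
  bw <- config$bin_width
  out <- list()
  for (ch in names(config$chrom_sizes)) {
    len <- config$chrom_sizes[[ch]]
    n_target <- round(config$enhancer_density * len / 1e6)
    if (n_target == 0) next
    placed_start <- integer(0)
    placed_end <- integer(0)
    attempts <- 0L
    max_attempts <- 200L * n_target
    while (length(placed_start) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      w <- round(runif(1, config$enhancer_width_range[1],
                       config$enhancer_width_range[2]) / bw) * bw
      w <- max(bw, w)
      if (w + 2 > len) next
      s <- (sample.int((len - w) %/% bw, 1L) - 1L) * bw + 1L
      e <- s + w - 1L
      sep <- config$min_separation
      if (!length(placed_start) ||
          all(s > placed_end + sep | e < placed_start - sep)) {
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
      }
    }
    if (length(placed_start) < n_target)
      .stopf("could not place %d non-overlapping enhancers on %s (%d bp); lower enhancer_density",
             n_target, ch, len)
    ord <- order(placed_start)
    out[[ch]] <- GenomicRanges::GRanges(
      factor(rep(ch, length(ord)), levels = names(config$chrom_sizes)),
      IRanges::IRanges(placed_start[ord], placed_end[ord]))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  gr <- do.call(c, unname(out))
  GenomeInfoDb::seqlengths(gr) <- config$chrom_sizes
  gr
}

# Uniform draw on the lower membership function's plateau, where BOTH
# membership bounds equal 1, so planted antecedents hold exactly.
.draw_on_plateau <- function(set, n) {
  lo <- set$lower
  a <- max(lo[2], 0)
  b <- min(lo[3], 1)
  if (b < a) { a <- b <- (a + b) / 2 }
  runif(n, a, b)
}

# Max type-1 (upper-bound) firing of any planted enhancer rule, per row.
.planted_enhancer_firing <- function(config, X) {
  rules <- Filter(function(r) r$consequent == "enhancer",
                  config$planted_rules$rules)
  firing <- .firing_matrix(rules, X, config$planted_rules$partitions)
  apply(firing$upper, 1L, max)
}

#' Generate signal tracks and enhancer labels with planted rules
#'
#' Inside each true enhancer one planted enhancer rule is made to fire
#' exactly (antecedent marks drawn on the inner plateau of their linguistic
#' set, so both membership bounds are 1 before noise); outside, whole bins
#' are redrawn until no planted enhancer rule fires at or above
#' `background_max_firing`. Gaussian noise is then added (clipped to
#' [0, 1]) and a fraction of labels is flipped.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a [bin_dataset()], raw signals in [0, 1]),
#'   `truth` (true enhancer `GRanges`, planted rules, per-region rule index)
#'   and `config`.
#' @export
generate_tracks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    bins <- tile_genome(config$chrom_sizes, width = config$bin_width)
    n <- length(bins$gr)
    m <- config$n_marks
    enhancers <- .place_enhancers(config)
    X <- matrix(runif(n * m), n, m, dimnames = list(NULL, config$marks))

    # Background rejection: no planted enhancer rule may fire strongly.
    # Two care points keep the world learnable by quantile-anchored
    # partitions: (i) only one antecedent mark of the offending rule is
    # redrawn per round, preferring marks shared by the fewest planted
    # rules, so hub marks stay near-uniform; (ii) the planted partitions
    # are re-anchored at the empirical quantiles of the conditioned
    # background and the rejection repeated, so the partitions a learner
    # anchors at the data's quantiles coincide with the planted geometry.
    enh_rules <- Filter(function(r) r$consequent == "enhancer",
                        config$planted_rules$rules)
    partitions <- config$planted_rules$partitions
    mark_uses <- table(unlist(lapply(enh_rules, `[[`, "marks")))
    reject <- function(X, partitions) {
      for (round in 1:60) {
        firing <- .firing_matrix(enh_rules, X, partitions)$upper
        worst <- max.col(firing, ties.method = "first")
        bad <- which(firing[cbind(seq_len(nrow(X)), worst)] >=
                       config$background_max_firing)
        if (!length(bad)) break
        redraw_mark <- vapply(bad, function(i) {
          ms <- enh_rules[[worst[i]]]$marks
          uses <- as.integer(mark_uses[ms])
          .resample(ms[uses == min(uses)], 1L)
        }, character(1))
        X[cbind(bad, match(redraw_mark, config$marks))] <- runif(length(bad))
      }
      X
    }
    for (pass in 1:3) {
      X <- reject(X, partitions)
      partitions <- lapply(partitions, function(p)
        fuzzy_partition(p$mark,
                        anchors = unname(quantile(X[, p$mark],
                                                  c(0.25, 0.5, 0.75))),
                        overlap = p$overlap, fou = p$fou))
    }
    X <- reject(X, partitions)
    firing <- .firing_matrix(enh_rules, X, partitions)$upper
    bad <- which(apply(firing, 1L, max) >= config$background_max_firing)
    if (length(bad)) {
      # deterministic fallback: silence the first antecedent mark
      for (r in enh_rules) X[bad, r$marks[1]] <- 0
    }
    planted <- config$planted_rules
    planted$partitions <- partitions

    # plant enhancer signal: each region follows one enhancer rule
    enh_bins <- label_bins(bins, enhancers)
    region_rule <- integer(0)
    if (length(enhancers)) {
      region_rule <- rep(seq_along(enh_rules),
                         length.out = length(enhancers))
      ov <- GenomicRanges::findOverlaps(bins$gr, enhancers)
      bin_region <- S4Vectors::subjectHits(ov)
      bin_idx <- S4Vectors::queryHits(ov)
      for (j in seq_along(enh_rules)) {
        rows <- bin_idx[region_rule[bin_region] == j]
        if (!length(rows)) next
        r <- enh_rules[[j]]
        for (k in seq_along(r$marks)) {
          set <- partitions[[r$marks[k]]]$sets[[r$labels[k]]]
          X[rows, r$marks[k]] <- .draw_on_plateau(set, length(rows))
        }
      }
    }

    if (config$noise_sd > 0)
      X <- pmin(pmax(X + rnorm(length(X), sd = config$noise_sd), 0), 1)

    labels <- enh_bins
    if (config$label_noise_rate > 0) {
      flip <- sample.int(n, round(config$label_noise_rate * n))
      labels[flip] <- !labels[flip]
    }

    tracks <- lapply(setNames(config$marks, config$marks), function(mk)
      signal_track(mk, X[, mk], normalized = TRUE))
    list(dataset = bin_dataset(bins, tracks, labels),
         truth = list(true_enhancers = enhancers,
                      planted_rules = planted,
                      region_rule = region_rule),
         config = config)
  })
}

#' Generate a synthetic gene annotation
#'
#' Non-overlapping gene models (5'UTR, exons, introns, 3'UTR) placed
#' uniformly with at least 500 bp clearance (room for the 250 bp promoter).
#' Gene count per chromosome is `gene_density * Mb`.
#'
#' @param config A [synthetic_config()].
#' @return `GRanges` with `type` (gene/mRNA/exon/five_prime_UTR/
#'   three_prime_UTR), `ID` and `Parent` columns; exports as well-formed
#'   GFF3 via [write_annotation()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(.derive_seed(config$seed, 11L), {
    feats <- list()
    gid <- 0L
    for (ch in names(config$chrom_sizes)) {
      len <- config$chrom_sizes[[ch]]
      n_genes <- round(config$gene_density * len / 1e6)
      if (n_genes == 0) next
      clearance <- 500
      min_len <- 1500
      if (len < min_len + 2 * clearance)
        .stopf("chromosome %s (%d bp) too short for a gene model", ch, len)
      # carve the chromosome into n_genes equal slots; genes are placed
      # inside their slot so non-overlap (incl. promoters) is guaranteed
      slot <- len %/% n_genes
      if (slot < min_len + 2 * clearance)
        .stopf("chromosome %s too short for %d genes", ch, n_genes)
      for (i in seq_len(n_genes)) {
        gid <- gid + 1L
        slot_start <- (i - 1L) * slot + 1L
        glen <- round(runif(1, min_len, min(8000, slot - 2 * clearance)))
        gstart <- slot_start + clearance +
          sample.int(max(1L, slot - glen - 2L * clearance), 1L) - 1L
        gend <- gstart + glen - 1L
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("gene%04d", gid)
        n_exons <- sample(2:4, 1L)
        utr5 <- 200L
        utr3 <- 300L
        body <- glen - utr5 - utr3
        # alternate exons/introns across the body, first/last exon absorb
        # the UTRs
        cuts <- sort(sample.int(body - 1L, 2L * n_exons - 2L))
        bounds <- c(0L, cuts, body)
        seg_start <- gstart + utr5 + head(bounds, -1L)
        seg_end <- gstart + utr5 + bounds[-1L] - 1L
        is_exon <- seq_along(seg_start) %% 2L == 1L
        exon_start <- seg_start[is_exon]
        exon_end <- seg_end[is_exon]
        exon_start[1L] <- gstart            # absorb 5' (or 3') UTR
        exon_end[length(exon_end)] <- gend
        lv <- names(config$chrom_sizes)
        mk <- function(start, end, type, suffix) {
          GenomicRanges::GRanges(factor(rep(ch, length(start)), levels = lv),
                                 IRanges::IRanges(start, end),
                                 strand = strand, type = type,
                                 ID = sprintf("%s.%s", id, suffix),
                                 Parent = sprintf("%s.t1", id))
        }
        gene <- GenomicRanges::GRanges(factor(ch, levels = lv),
                                       IRanges::IRanges(gstart, gend),
                                       strand = strand, type = "gene",
                                       ID = id, Parent = NA_character_)
        mrna <- GenomicRanges::GRanges(factor(ch, levels = lv),
                                       IRanges::IRanges(gstart, gend),
                                       strand = strand, type = "mRNA",
                                       ID = sprintf("%s.t1", id), Parent = id)
        exons <- mk(exon_start, exon_end, "exon",
                    sprintf("exon%d", seq_along(exon_start)))
        if (strand == "+") {
          u5 <- mk(gstart, gstart + utr5 - 1L, "five_prime_UTR", "utr5")
          u3 <- mk(gend - utr3 + 1L, gend, "three_prime_UTR", "utr3")
        } else {
          u5 <- mk(gend - utr5 + 1L, gend, "five_prime_UTR", "utr5")
          u3 <- mk(gstart, gstart + utr3 - 1L, "three_prime_UTR", "utr3")
        }
        feats[[length(feats) + 1L]] <- c(gene, mrna, exons, u5, u3)
      }
    }
    if (!length(feats)) return(GenomicRanges::GRanges())
    ann <- do.call(c, feats)
    GenomeInfoDb::seqlengths(ann) <- config$chrom_sizes
    ann
  })
}

#' Generate promoter-anchored contact records
#'
#' Each true enhancer contacts the promoter of one gene with probability
#' `p_contact_given_enhancer` (the linked gene is recorded as ground truth);
#' each promoter additionally contacts a random background position with
#' probability `p_contact_background`. Anchors are `hic_bin`-sized;
#' observed/expected scores of planted links are drawn in [2, 8] so they
#' always exceed the default enrichment threshold.
#'
#' @param config A [synthetic_config()].
#' @param true_enhancers `GRanges` of planted enhancers.
#' @param annotation Gene annotation from [generate_annotation()].
#' @return List with `contacts` (a `contact_records` data frame) and
#'   `gene_links` (character vector: linked gene id per enhancer, NA when
#'   unlinked).
#' @export
generate_contacts <- function(config, true_enhancers, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- annotation[annotation$type == "gene"]
  if (!length(genes)) .stopf("annotation contains no genes")
  proms <- promoter_intervals(genes, config$chrom_sizes)
  hb <- config$contact_model$hic_bin
  anchor_of <- function(gr) {
    centers <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
    s <- ((centers - 1L) %/% hb) * hb + 1L
    lens <- config$chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))]
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = s, end = pmin(s + hb - 1L, lens))
  }
  .with_seed(.derive_seed(config$seed, 23L), {
    recs <- list()
    gene_links <- rep(NA_character_, length(true_enhancers))
    if (length(true_enhancers)) {
      ea <- anchor_of(true_enhancers)
      linked <- runif(length(true_enhancers)) <
        config$contact_model$p_contact_given_enhancer
      for (i in which(linked)) {
        g <- sample.int(length(genes), 1L)
        gene_links[i] <- genes$ID[g]
        pa <- anchor_of(proms[g])
        recs[[length(recs) + 1L]] <- data.frame(
          chrom1 = ea$chrom[i], start1 = ea$start[i], end1 = ea$end[i],
          chrom2 = pa$chrom, start2 = pa$start, end2 = pa$end,
          score = runif(1, 2, 8))
      }
    }
    bg <- which(runif(length(genes)) < config$contact_model$p_contact_background)
    for (g in bg) {
      pa <- anchor_of(proms[g])
      ch <- sample(names(config$chrom_sizes), 1L)
      pos <- sample.int(config$chrom_sizes[[ch]], 1L)
      s <- ((pos - 1L) %/% hb) * hb + 1L
      bga <- data.frame(chrom = ch, start = s,
                        end = min(s + hb - 1L, config$chrom_sizes[[ch]]))
      # background anchors must not touch a true enhancer
      if (length(true_enhancers) && IRanges::overlapsAny(
            GenomicRanges::GRanges(bga$chrom,
                                   IRanges::IRanges(bga$start, bga$end)),
            true_enhancers)) next
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = pa$chrom, start1 = pa$start, end1 = pa$end,
        chrom2 = bga$chrom, start2 = bga$start, end2 = bga$end,
        score = runif(1, 2, 8))
    }
    contacts <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                 chrom2 = character(), start2 = integer(), end2 = integer(),
                 score = numeric())
    class(contacts) <- c("contact_records", "data.frame")
    list(contacts = contacts, gene_links = gene_links)
  })
}

#' Generate a gene expression table
#'
#' Genes linked to an enhancer draw FPKM from a lognormal with the
#' configured location/scale; unlinked genes are zero-inflated with a lower
#' location.
#'
#' @param config A [synthetic_config()].
#' @param annotation Gene annotation.
#' @param gene_links Linked gene ids (from [generate_contacts()]).
#' @return Data frame `gene_id`, `fpkm`.
#' @export
generate_expression <- function(config, annotation, gene_links = character()) {
  genes <- annotation[annotation$type == "gene"]
  em <- config$expression_model
  .with_seed(.derive_seed(config$seed, 37L), {
    linked <- genes$ID %in% gene_links
    fpkm <- numeric(length(genes))
    fpkm[linked] <- rlnorm(sum(linked), em$meanlog, em$sdlog)
    n_un <- sum(!linked)
    silent <- runif(n_un) < em$zero_inflation
    vals <- rlnorm(n_un, em$bg_meanlog, em$sdlog)
    vals[silent] <- 0
    fpkm[!linked] <- vals
    data.frame(gene_id = genes$ID, fpkm = fpkm)
  })
}

#' Generate stranded nascent-transcription tracks around enhancers
#'
#' Plus-strand signal is laid in the window `offset` bp downstream of each
#' enhancer's right border and minus-strand signal (stored negative) in the
#' window upstream of the left border, emulating divergent eRNA
#' transcription. The per-region plus:minus ratio is `asymmetry`, so the
#' noise-free directionality score is exactly `log10(asymmetry)`.
#'
#' @param config A [synthetic_config()].
#' @param true_enhancers `GRanges` of enhancers.
#' @param asymmetry Plus:minus signal ratio, recycled per region; defaults
#'   to the configured `transcription_model$asymmetry`.
#' @return List with `plus` and `minus` per-bin value vectors (on the
#'   [tile_genome()] grid of the config) and the `bins`.
#' @export
generate_stranded_transcription <- function(config, true_enhancers,
                                            asymmetry = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  tm <- config$transcription_model
  if (is.null(asymmetry)) asymmetry <- tm$asymmetry
  asymmetry <- rep_len(asymmetry, max(1L, length(true_enhancers)))
  bins <- tile_genome(config$chrom_sizes, width = config$bin_width)
  plus <- numeric(length(bins$gr))
  minus <- numeric(length(bins$gr))
  if (length(true_enhancers)) {
    ch <- as.character(GenomeInfoDb::seqnames(true_enhancers))
    s <- GenomicRanges::start(true_enhancers)
    e <- GenomicRanges::end(true_enhancers)
    for (i in seq_along(true_enhancers)) {
      ri <- .bin_index_range(bins, ch[i], e[i] + tm$offset + 1L,
                             e[i] + tm$offset + tm$window)
      li <- .bin_index_range(bins, ch[i], s[i] - tm$offset - tm$window,
                             s[i] - tm$offset - 1L)
      if (!is.null(ri)) plus[ri] <- plus[ri] + tm$level * asymmetry[i]
      if (!is.null(li)) minus[li] <- minus[li] - tm$level
    }
  }
  if (tm$noise_sd > 0) {
    .with_seed(.derive_seed(config$seed, 41L), {
      plus <- pmax(plus + rnorm(length(plus), sd = tm$noise_sd), 0)
      minus <- pmin(minus + rnorm(length(minus), sd = tm$noise_sd), 0)
    })
  }
  list(plus = plus, minus = minus, bins = bins)
}

#' Run the whole generator
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset`, `truth` (including `gene_links`),
#'   `annotation`, `contacts`, `expression`, `transcription`, `config`.
#' @export
simulate_enhancer_genome <- function(config) {
  sim <- generate_tracks(config)
  annotation <- generate_annotation(config)
  cc <- generate_contacts(config, sim$truth$true_enhancers, annotation)
  expr <- generate_expression(config, annotation, cc$gene_links)
  tx <- generate_stranded_transcription(config, sim$truth$true_enhancers)
  sim$truth$gene_links <- cc$gene_links
  c(sim[c("dataset", "truth", "config")],
    list(annotation = annotation, contacts = cc$contacts, expression = expr,
         transcription = tx))
}

#' Write all generator outputs to a directory
#'
#' Emits chrom.sizes, one bedGraph per mark, a BED of true enhancers, the
#' GFF3 annotation, a BEDPE-like contacts TSV, an FPKM TSV, the stranded
#' transcription bedGraphs and a ground-truth JSON.
#'
#' @param sim Output of [simulate_enhancer_genome()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_synthetic_data <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(sim$config$chrom_sizes, file.path(outdir, "chrom.sizes"))
  for (mk in sim$dataset$feature_order)
    write_bedgraph(sim$dataset$bins, sim$dataset$features[, mk],
                   file.path(outdir, paste0(mk, ".bedGraph")))
  write_bed(sim$truth$true_enhancers, file.path(outdir, "true_enhancers.bed"))
  write_annotation(sim$annotation, file.path(outdir, "annotation.gff3"))
  write_contacts(sim$contacts, file.path(outdir, "contacts.tsv"))
  write_fpkm(sim$expression, file.path(outdir, "expression.tsv"))
  write_bedgraph(sim$transcription$bins, sim$transcription$plus,
                 file.path(outdir, "nascent_plus.bedGraph"))
  write_bedgraph(sim$transcription$bins, sim$transcription$minus,
                 file.path(outdir, "nascent_minus.bedGraph"))
  truth <- list(
    true_enhancers = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(sim$truth$true_enhancers)),
      start = GenomicRanges::start(sim$truth$true_enhancers) - 1L,
      end = GenomicRanges::end(sim$truth$true_enhancers)),
    gene_links = as.list(setNames(
      sim$truth$gene_links,
      sprintf("enh%04d", seq_along(sim$truth$gene_links)))),
    seed = sim$config$seed)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(outdir)
}
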