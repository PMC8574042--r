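test_that("profile_matrix samples around centers, largest region first", {
  bins <- tile_genome(c(A = 100000), width = 10)
  vals <- rep(3, length(bins))
  regions <- granges("A", c(20000, 50000), c(20500, 52000))  # 500 and 2000 bp
  pm <- profile_matrix(vals, bins, regions, flank = 5000)
  expect_equal(dim(pm), c(2L, 2 * 5000 / 10 + 1))
  expect_true(all(pm == 3))
  # row 1 is the 2000-bp region
  expect_equal(attr(pm, "region_order"), c(2L, 1L))
  # off-chromosome positions are NA
  edge <- granges("A", 1000, 1400)
  pme <- profile_matrix(vals, bins, edge, flank = 5000)
  expect_true(anyNA(pme))
  expect_error(profile_matrix(vals, bins, GenomicRanges::GRanges()),
               "no regions")
})

test_that("winsorize_rescale follows the stated transform and bounds", {
  m <- matrix(c(-1, 0, 5, 10), 1)
  out <- winsorize_rescale(m, "unsigned", cap = 10)
  expect_equal(as.numeric(out), c(0, 0, 0.5, 1))

  set.seed(5)
  m2 <- matrix(rnorm(400, sd = 3), 20)
  u <- winsorize_rescale(m2, "unsigned")
  expect_true(all(u >= 0 & u <= 1))
  s <- winsorize_rescale(m2, "signed")
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(max(s), 1)
  expect_equal(min(s), -1)
  expect_warning(winsorize_rescale(matrix(0, 2, 2)), "no positive")
})

test_that("winsorize_rescale is idempotent on its own output", {
  set.seed(6)
  for (mode in c("unsigned", "signed")) {
    m <- matrix(rnorm(500, sd = 2), 25)
    once <- winsorize_rescale(m, mode)
    twice <- winsorize_rescale(once, mode)
    expect_equal(unclass(twice), unclass(once), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("directionality score honours symmetry, ratios and the swap rule", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e5), enhancer_density = 20,
                          seed = 3)
  sim <- generate_tracks(cfg)
  bins <- sim$dataset$bins
  te <- sim$truth$true_enhancers

  # P = N > 0 -> score 0; P = 10 N -> score 1
  tx <- generate_stranded_transcription(cfg, te, asymmetry = 1)
  d <- directionality_score(tx$plus, tx$minus, bins, te, pseudocount = 0)
  ok <- !is.na(d$score)
  expect_equal(d$score[ok], rep(0, sum(ok)))

  # swap antisymmetry on random tracks and random regions
  set.seed(50)
  plus <- runif(length(bins), 0, 5)
  minus <- -runif(length(bins), 0, 5)
  starts <- sort(sample(seq(2000, 90000, by = 150), 500))
  regions <- granges("chrA", starts, starts + sample(100:800, 500, TRUE))
  d1 <- directionality_score(plus, minus, bins, regions)
  d2 <- directionality_score(-minus, -plus, bins, regions)
  expect_equal(d2$score, -d1$score, tolerance = 1e-12)

  # classification boundary at |0.5|
  expect_equal(d1$class[!is.na(d1$score) & abs(d1$score) <= 0.5][1],
               "bidirectional")
  # a region whose flank leaves the chromosome yields a missing record
  d_edge <- directionality_score(plus, minus, bins, granges("chrA", 100, 300))
  expect_true(is.na(d_edge$score))
})

test_that("obs/exp signal enrichment matches the flat-loop oracle", {
  bins <- tile_genome(c(A = 1e5), width = 10)  # 1e4 bins
  set.seed(9)
  vals <- runif(length(bins))
  regions <- granges("A", c(10000, 50000), c(15000, 52000))
  e <- obs_exp_signal_enrichment(vals, regions, bins)
  inside <- vapply(seq_along(bins$gr), function(i) {
    b0 <- (i - 1) * 10; b1 <- i * 10
    any(GenomicRanges::start(regions) - 1 < b1 &
          GenomicRanges::end(regions) > b0)
  }, logical(1))
  expect_equal(e$observed, mean(vals[inside]))
  expect_equal(e$expected, mean(vals))
  expect_equal(e$log2_ratio, log2(mean(vals[inside]) / mean(vals)))
  # whole genome against itself -> 0
  whole <- granges("A", 0, 1e5)
  expect_equal(obs_exp_signal_enrichment(vals, whole, bins)$log2_ratio, 0)
  expect_error(obs_exp_signal_enrichment(vals, GenomicRanges::GRanges(),
                                         bins), "empty")
})

test_that("feature overlap enrichment matches a base-count oracle", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 2e5), gene_density = 15,
                          seed = 4)
  ann <- generate_annotation(cfg)
  cats <- annotation_categories(ann, cfg$chrom_sizes)
  # categories are disjoint and cover the genome
  total <- sum(vapply(cats, function(g)
    sum(as.numeric(IRanges::width(g))), numeric(1)))
  expect_equal(total, 2e5)

  set.seed(41)
  starts <- sort(sample(seq(0, 198000, by = 100), 50))
  regions <- GenomicRanges::reduce(granges("chrA", starts, starts + 600))
  fe <- feature_overlap_enrichment(regions, cats, cfg$chrom_sizes)
  expect_equal(sum(fe$observed), 1, tolerance = 1e-12)
  expect_equal(sum(fe$expected), 1, tolerance = 1e-12)
  # oracle per category by explicit base counting
  rb <- unlist(lapply(seq_along(regions), function(i)
    GenomicRanges::start(regions[i]):GenomicRanges::end(regions[i])))
  for (nm in names(cats)) {
    cb <- unlist(lapply(seq_along(cats[[nm]]), function(i)
      GenomicRanges::start(cats[[nm]][i]):GenomicRanges::end(cats[[nm]][i])))
    expect_equal(fe$observed[fe$category == nm],
                 length(intersect(rb, cb)) / length(rb),
                 info = nm)
  }
  # all regions inside first introns -> observed 1 for that category
  fi <- cats$first_intron[IRanges::width(cats$first_intron) > 50]
  inside <- GenomicRanges::resize(fi[1:min(5, length(fi))], 30, fix = "center")
  fe2 <- feature_overlap_enrichment(inside, cats, cfg$chrom_sizes)
  expect_equal(fe2$observed[fe2$category == "first_intron"], 1)
  # overlapping categories are rejected
  bad <- cats
  bad$exon <- c(bad$exon, bad$promoter[1])
  expect_error(feature_overlap_enrichment(regions, bad, cfg$chrom_sizes),
               "overlap")
})

test_that("tad_proximity flags borders within the cutoff", {
  regions <- granges("A", 10000, 10500)
  expect_true(tad_proximity(regions, granges("A", 12000, 12001)))
  expect_false(tad_proximity(regions, granges("A", 13001, 13002)))
  # linear-scan oracle on random borders
  set.seed(14)
  starts <- sort(sample(seq(0, 95000, by = 500), 100))
  regs <- granges("A", starts, starts + 300)
  bpos <- sort(sample(0:99000, 30))
  borders <- granges("A", bpos, bpos + 1)
  got <- tad_proximity(regs, borders, 2000)
  want <- vapply(seq_along(regs), function(i) {
    g <- vapply(seq_along(borders), function(j) {
      d <- GenomicRanges::distance(regs[i], borders[j])
      ifelse(is.na(d), Inf, d)
    }, numeric(1))
    any(g <= 2000)
  }, logical(1))
  expect_equal(got, want)
})

test_that("body percentile score interpolates and scales linearly", {
  bins <- tile_genome(c(A = 1000), width = 10)
  vals <- 1:100
  region <- granges("A", 0, 1000)
  s <- body_percentile_score(vals, bins, region, 95)
  expect_equal(s, unname(quantile(1:100, 0.95)))  # sort-based oracle
  # constant region -> the constant
  expect_equal(body_percentile_score(rep(4, 100), bins, region), 4)
  # homogeneity
  expect_equal(body_percentile_score(2 * vals, bins, region), 2 * s)
  # a region overlapping no bin errors
  off <- GenomicRanges::GRanges("B", IRanges::IRanges(5, 20))
  expect_error(suppressWarnings(body_percentile_score(vals, bins, off)),
               "bin")
})

test_that("Mann-Whitney comparison rejects at about the nominal rate under the null", {
  set.seed(2024)
  rejections <- vapply(1:200, function(i) {
    scores <- rnorm(120)
    groups <- rep(c("common", "putative"), each = 60)
    compare_groups(scores, groups)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.12)
})
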