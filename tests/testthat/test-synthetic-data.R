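test_that("generate_tracks is deterministic and respects the zero-noise contract", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e5), noise_sd = 0,
                          label_noise_rate = 0, seed = 7)
  sim1 <- generate_tracks(cfg)
  sim2 <- generate_tracks(cfg)
  expect_identical(sim1$dataset$features, sim2$dataset$features)
  expect_identical(sim1$dataset$labels, sim2$dataset$labels)
  expect_identical(as.data.frame(sim1$truth$true_enhancers),
                   as.data.frame(sim2$truth$true_enhancers))

  # every true-enhancer bin satisfies its planted rule exactly; no
  # background bin fires strongly (at the generator's re-anchored
  # partitions, returned in the ground truth)
  planted <- sim1$truth$planted_rules
  enh_rules <- Filter(function(r) r$consequent == "enhancer", planted$rules)
  firing <- enhancerRules:::.firing_matrix(
    enh_rules, sim1$dataset$features, planted$partitions)
  best <- pmax(firing$lower[, 1], firing$lower[, 2])
  enh <- sim1$dataset$labels
  expect_true(all(best[enh] == 1))
  expect_true(all(firing$upper[!enh, ] < cfg$background_max_firing))
  # bounded signals
  expect_true(all(sim1$dataset$features >= 0 & sim1$dataset$features <= 1))
})

test_that("requested enhancer density is honoured without overlap", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e6), enhancer_density = 10,
                          min_separation = 500, seed = 11)
  sim <- generate_tracks(cfg)
  te <- sim$truth$true_enhancers
  expect_equal(length(te), 10L)
  # interval-set oracle: pairwise disjoint
  expect_equal(length(GenomicRanges::reduce(te)), 10L)
  w <- IRanges::width(te)
  expect_true(all(w >= cfg$enhancer_width_range[1] - cfg$bin_width &
                    w <= cfg$enhancer_width_range[2] + cfg$bin_width))
  # infeasible density errors
  bad <- synthetic_config(chrom_sizes = c(chrA = 2e4),
                          enhancer_density = 2000, seed = 1)
  expect_error(generate_tracks(bad), "could not place")
})

test_that("label noise flips the configured fraction of bins", {
  cfg0 <- synthetic_config(chrom_sizes = c(chrA = 2e5), noise_sd = 0,
                           label_noise_rate = 0, seed = 13)
  cfg1 <- synthetic_config(chrom_sizes = c(chrA = 2e5), noise_sd = 0,
                           label_noise_rate = 0.05, seed = 13)
  clean <- generate_tracks(cfg0)$dataset$labels
  noisy <- generate_tracks(cfg1)$dataset$labels
  expect_equal(sum(clean != noisy), round(0.05 * length(clean)))
})

test_that("generate_annotation produces consistent, round-tripping GFF3", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e6), gene_density = 20,
                          seed = 5)
  ann <- generate_annotation(cfg)
  genes <- ann[ann$type == "gene"]
  expect_equal(length(genes), 20L)
  # every exon within its gene span
  exons <- ann[ann$type == "exon"]
  gspan <- setNames(as.data.frame(genes)[, c("start", "end")], NULL)
  for (gid in genes$ID) {
    g <- genes[genes$ID == gid]
    ex <- exons[sub("\\.t1$", "", as.character(unlist(exons$Parent))) == gid]
    expect_true(all(GenomicRanges::start(ex) >= GenomicRanges::start(g)))
    expect_true(all(GenomicRanges::end(ex) <= GenomicRanges::end(g)))
  }
  # genes non-overlapping
  expect_equal(length(GenomicRanges::reduce(GenomicRanges::granges(genes))),
               length(genes))
  # 20 genes -> 20 promoters of 250 bp
  proms <- promoter_intervals(genes, cfg$chrom_sizes)
  expect_equal(length(proms), 20L)
  expect_true(all(IRanges::width(proms) == 250L))
  # GFF3 round-trip
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(length(back), length(ann))
  expect_equal(as.character(back$type), as.character(ann$type))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann))
  # too-short chromosome errors
  tiny <- synthetic_config(chrom_sizes = c(chrA = 1500), gene_density = 700,
                           seed = 1)
  expect_error(generate_annotation(tiny), "too short")
})

test_that("generate_contacts honours the probability limits", {
  cfg1 <- synthetic_config(chrom_sizes = c(chrA = 5e5),
                           contact_model = list(p_contact_given_enhancer = 1,
                                                p_contact_background = 0),
                           seed = 3)
  sim <- generate_tracks(cfg1)
  ann <- generate_annotation(cfg1)
  cc <- generate_contacts(cfg1, sim$truth$true_enhancers, ann)
  # p = 1: every enhancer linked; p_bg = 0: every contact has an enhancer
  # anchor
  expect_true(all(!is.na(cc$gene_links)))
  an <- enhancerRules:::.contact_anchors(cc$contacts)
  has_enh <- IRanges::overlapsAny(an$a1, sim$truth$true_enhancers) |
    IRanges::overlapsAny(an$a2, sim$truth$true_enhancers)
  expect_true(all(has_enh))
  expect_true(all(cc$contacts$score > 1))
})

test_that("linked fraction matches the binomial Monte-Carlo oracle", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e6),
                          enhancer_density = 10,
                          contact_model = list(p_contact_given_enhancer = 0.5,
                                               p_contact_background = 0),
                          seed = 1)
  sim <- generate_tracks(cfg)
  ann <- generate_annotation(cfg)
  fractions <- vapply(1:1000, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- s
    cc <- generate_contacts(cfg_s, sim$truth$true_enhancers, ann)
    mean(!is.na(cc$gene_links))
  }, numeric(1))
  expect_equal(mean(fractions), 0.5, tolerance = 0.05)
})

test_that("stranded transcription yields exact noise-free scores", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 2e5), enhancer_density = 20,
                          seed = 9)
  sim <- generate_tracks(cfg)
  te <- sim$truth$true_enhancers
  bins <- sim$dataset$bins

  tx1 <- generate_stranded_transcription(cfg, te, asymmetry = 1)
  d1 <- directionality_score(tx1$plus, tx1$minus, bins, te, pseudocount = 0)
  ok <- !is.na(d1$score)
  expect_true(any(ok))
  expect_equal(d1$score[ok], rep(0, sum(ok)))
  expect_true(all(d1$class[ok] == "bidirectional"))

  tx10 <- generate_stranded_transcription(cfg, te, asymmetry = 10)
  d10 <- directionality_score(tx10$plus, tx10$minus, bins, te,
                              pseudocount = 0)
  expect_equal(d10$score[ok], rep(1, sum(ok)), tolerance = 1e-12)
  expect_true(all(d10$class[ok] == "positive"))

  tx2 <- generate_stranded_transcription(cfg, te, asymmetry = 2)
  d2 <- directionality_score(tx2$plus, tx2$minus, bins, te, pseudocount = 0)
  expect_equal(d2$score[ok], rep(log10(2), sum(ok)), tolerance = 1e-12)
  expect_true(all(d2$class[ok] == "bidirectional"))  # 0.301 within [-0.5,0.5]
})

test_that("write_synthetic_data emits the full file set deterministically", {
  cfg <- synthetic_config(chrom_sizes = c(chrA = 1e5), seed = 21)
  sim <- simulate_enhancer_genome(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_data(sim, d1)
  write_synthetic_data(simulate_enhancer_genome(cfg), d2)
  files <- c("chrom.sizes", "H3K4me1.bedGraph", "true_enhancers.bed",
             "annotation.gff3", "contacts.tsv", "expression.tsv",
             "nascent_plus.bedGraph", "nascent_minus.bedGraph",
             "ground_truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]], label = f)
  }
})
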