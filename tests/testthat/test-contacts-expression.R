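make_contacts <- function(chrom1, start1, end1, chrom2, start2, end2,
                          score = 3) {
  df <- data.frame(chrom1 = chrom1, start1 = start1, end1 = end1,
                   chrom2 = chrom2, start2 = start2, end2 = end2,
                   score = score)
  class(df) <- c("contact_records", "data.frame")
  df
}

test_that("promoter_intervals is strand-aware and clipped", {
  sizes <- c(A = 10000)
  gp <- GenomicRanges::GRanges("A", IRanges::IRanges(1001, 2000),
                               strand = "+", ID = "g1")
  gm <- GenomicRanges::GRanges("A", IRanges::IRanges(200, 1000),
                               strand = "-", ID = "g2")
  pp <- promoter_intervals(gp, sizes)
  # + strand, TSS at 0-based 1000 -> promoter [750, 1000) 0-based
  expect_equal(GenomicRanges::start(pp), 751L)
  expect_equal(GenomicRanges::end(pp), 1000L)
  pm <- promoter_intervals(gm, sizes)
  # - strand, TSS at 0-based end 1000 -> promoter [1000, 1250) 0-based
  expect_equal(GenomicRanges::start(pm), 1001L)
  expect_equal(GenomicRanges::end(pm), 1250L)
  # near-origin TSS clips at chromosome start
  g0 <- GenomicRanges::GRanges("A", IRanges::IRanges(101, 400),
                               strand = "+", ID = "g3")
  p0 <- promoter_intervals(g0, sizes)
  expect_equal(GenomicRanges::start(p0), 1L)
  expect_equal(GenomicRanges::end(p0), 100L)
  bad <- GenomicRanges::GRanges("A", IRanges::IRanges(9000, 10500),
                                strand = "-", ID = "g4")
  expect_error(promoter_intervals(bad, sizes), "outside")
})

test_that("flag_enriched_contacts filters on the ratio threshold", {
  cc <- make_contacts("A", c(0, 0, 0), 1000, "A", 5000, 6000,
                      score = c(3, 1, 2))
  out <- flag_enriched_contacts(cc, 2)
  expect_equal(out$enriched, c(TRUE, FALSE, TRUE))
  # ratio 1.0 is never enriched for thresholds > 1
  expect_false(flag_enriched_contacts(cc, 1.5)$enriched[2])
  cc$score[1] <- -1
  expect_error(flag_enriched_contacts(cc, 2), "positive")
  # filter oracle on 100 synthetic records
  set.seed(8)
  big <- make_contacts("A", 0, 100, "A", 500, 600,
                       score = runif(100, 0.1, 5))
  expect_equal(flag_enriched_contacts(big, 2)$enriched, big$score >= 2)
})

test_that("linkage categories follow the proximity/contact rules", {
  sizes <- c(A = 200000)
  genes <- GenomicRanges::GRanges(
    "A", IRanges::IRanges(c(10001, 100001), c(12000, 102000)),
    strand = "+", ID = c("g1", "g2"))
  promoters <- promoter_intervals(genes, sizes)  # [9750,10000), [99750,100000)

  # region 3 kb from g1's promoter with a distal enriched contact to g2
  r1 <- granges("A", 5000, 6000)
  # region 50 kb from promoters with an enriched contact to g1
  r2 <- granges("A", 160000, 161000)
  # region near promoter with no distal contacts
  r3 <- granges("A", 8000, 9000)
  # region far away, no contacts
  r4 <- granges("A", 130000, 131000)
  regions <- c(r1, r2, r3, r4)

  contacts <- flag_enriched_contacts(make_contacts(
    "A", c(5000, 160000), c(6000, 161000),
    "A", c(99000, 9000), c(100000, 10000), score = 4), 2)
  lk <- link_enhancers_to_promoters(regions, promoters, contacts)
  expect_equal(lk$category,
               c("proximal", "distal_only", "proximal_only", "neither"))
  expect_equal(lk$contacted_genes[1], "g2")
  expect_equal(lk$contacted_genes[2], "g1")
  # partition: every region in exactly one category
  expect_true(all(lk$category %in% c("proximal", "distal_only",
                                     "proximal_only", "neither")))
})

test_that("linkage matches a brute-force distance+contact oracle", {
  set.seed(77)
  sizes <- c(A = 1e6)
  tss <- sort(sample(seq(5000, 990000, by = 1000), 40))
  genes <- GenomicRanges::GRanges("A", IRanges::IRanges(tss, tss + 800),
                                  strand = "+",
                                  ID = sprintf("g%02d", seq_along(tss)))
  promoters <- promoter_intervals(genes, sizes)
  starts <- sort(sample(seq(1000, 995000, by = 700), 200))
  regions <- granges("A", starts, starts + 500)
  # random region->gene contacts
  n_c <- 120
  ridx <- sample(200, n_c, replace = TRUE)
  gidx <- sample(40, n_c, replace = TRUE)
  contacts <- flag_enriched_contacts(make_contacts(
    "A", starts[ridx], starts[ridx] + 500,
    "A", GenomicRanges::start(promoters)[gidx] - 1,
    GenomicRanges::end(promoters)[gidx],
    score = runif(n_c, 1, 5)), 2)
  lk <- link_enhancers_to_promoters(regions, promoters, contacts)

  gap <- function(a, b) {  # gap between two GRanges (0 if overlapping)
    d <- GenomicRanges::distance(a, b)
    ifelse(is.na(d), Inf, d)
  }
  for (i in sample(200, 60)) {
    dmin <- min(vapply(seq_along(promoters), function(g)
      gap(regions[i], promoters[g]), numeric(1)))
    cgenes <- unique(gidx[contacts$enriched & ridx == i])
    has_distal <- length(cgenes) &&
      any(vapply(cgenes, function(g) gap(regions[i], promoters[g]) > 5000,
                 logical(1)))
    want <- if (dmin <= 5000 && has_distal) "proximal"
      else if (dmin <= 5000) "proximal_only"
      else if (length(cgenes)) "distal_only" else "neither"
    expect_equal(lk$category[i], want, info = paste("region", i))
  }
})

test_that("linked_expression takes the max FPKM over relevant genes", {
  sizes <- c(A = 100000)
  genes <- GenomicRanges::GRanges(
    "A", IRanges::IRanges(c(50001, 70001), c(52000, 72000)), strand = "+",
    ID = c("g1", "g2"))
  promoters <- promoter_intervals(genes, sizes)
  region <- granges("A", 1000, 2000)
  contacts <- flag_enriched_contacts(make_contacts(
    "A", c(1000, 1000), 2000, "A", c(49700, 69700), c(50000, 70000),
    score = 4), 2)
  lk <- link_enhancers_to_promoters(region, promoters, contacts)
  fpkm <- data.frame(gene_id = c("g1", "g2"), fpkm = c(2.0, 7.5))
  le <- linked_expression(lk, fpkm)
  expect_equal(le$max_fpkm, 7.5)
  expect_true(le$expressed)
  # single silent gene -> value 0, not expressed
  lk1 <- link_enhancers_to_promoters(region, promoters,
                                     contacts[1, , drop = FALSE])
  le1 <- linked_expression(lk1, data.frame(gene_id = c("g1", "g2"),
                                           fpkm = c(0, 9)))
  expect_equal(le1$max_fpkm, 0)
  expect_false(le1$expressed)
  # 'neither' region -> missing value
  far <- granges("A", 20000, 21000)
  lk2 <- link_enhancers_to_promoters(far, promoters, contacts[0, ])
  le2 <- linked_expression(lk2, fpkm)
  expect_true(is.na(le2$max_fpkm))
})

test_that("raising proximal_distance only moves regions toward proximal", {
  set.seed(99)
  sizes <- c(A = 5e5)
  tss <- seq(20000, 480000, by = 25000)
  genes <- GenomicRanges::GRanges("A", IRanges::IRanges(tss, tss + 500),
                                  strand = "+",
                                  ID = sprintf("g%02d", seq_along(tss)))
  promoters <- promoter_intervals(genes, sizes)
  starts <- sort(sample(seq(1000, 490000, by = 900), 80))
  regions <- granges("A", starts, starts + 400)
  contacts <- flag_enriched_contacts(make_contacts(
    "A", starts[1:30], starts[1:30] + 400,
    "A", GenomicRanges::start(promoters)[rep(1:10, 3)],
    GenomicRanges::end(promoters)[rep(1:10, 3)], score = 4), 2)
  lk5 <- link_enhancers_to_promoters(regions, promoters, contacts, 5000)
  lk10 <- link_enhancers_to_promoters(regions, promoters, contacts, 10000)
  prox5 <- lk5$category %in% c("proximal", "proximal_only")
  prox10 <- lk10$category %in% c("proximal", "proximal_only")
  expect_true(all(prox10[prox5]))
})

test_that("enhancer_enhancer_contacts counts distinct partners", {
  r <- granges("A", c(0, 5000, 10000), c(1000, 6000, 11000))
  cc <- flag_enriched_contacts(
    make_contacts("A", 0, 1000, "A", 5000, 6000, score = 4), 2)
  expect_equal(enhancer_enhancer_contacts(r, cc), c(1L, 1L, 0L))
  expect_equal(enhancer_enhancer_contacts(r, cc[0, ]), c(0L, 0L, 0L))
  # all-pairs oracle on random records
  set.seed(12)
  starts <- seq(0, 99000, by = 1000)
  regs <- granges("A", starts, starts + 800)
  n_c <- 60
  i1 <- sample(100, n_c, replace = TRUE)
  i2 <- sample(100, n_c, replace = TRUE)
  cc2 <- flag_enriched_contacts(make_contacts(
    "A", starts[i1], starts[i1] + 800, "A", starts[i2], starts[i2] + 800,
    score = runif(n_c, 1, 5)), 2)
  got <- enhancer_enhancer_contacts(regs, cc2)
  want <- integer(100)
  for (k in which(cc2$enriched)) {
    if (i1[k] != i2[k]) {
      want[i1[k]] <- want[i1[k]] + 1L
      want[i2[k]] <- want[i2[k]] + 1L
    }
  }
  # distinct partners, so recount uniquely
  partners <- lapply(seq_len(100), function(i) integer(0))
  for (k in which(cc2$enriched)) {
    if (i1[k] != i2[k]) {
      partners[[i1[k]]] <- union(partners[[i1[k]]], i2[k])
      partners[[i2[k]]] <- union(partners[[i2[k]]], i1[k])
    }
  }
  expect_equal(got, lengths(partners))
})
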