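# Shared fixtures, built in code at test time.

# small genome bins
tiny_bins <- function(sizes = c(chrA = 1000, chrB = 500), width = 10)
  tile_genome(sizes, width = width)

# a hand-built two-mark rule base with type-1 (degenerate) partitions
toy_rulebase <- function(fou = 0, dominance = c(1, 1)) {
  parts <- list(
    m1 = fuzzy_partition("m1", fou = fou),
    m2 = fuzzy_partition("m2", fou = fou))
  rule_base(list(
    fuzzy_rule(c("m1", "m2"), c("high", "high"), "enhancer", dominance[1]),
    fuzzy_rule("m1", "low", "non_enhancer", dominance[2])),
    parts)
}

# independent type-1 Mamdani implementation used as an oracle for the
# degenerate-FOU regression test: plain trapezoid memberships, min t-norm,
# dominance-weighted sum aggregation, ratio probability
type1_oracle_probability <- function(rulebase, X) {
  trap <- function(x, bp) {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]; d <- bp[4]
    ifelse(x >= b & x <= cc, 1,
      ifelse(x > a & x < b, (x - a) / (b - a),
        ifelse(x > cc & x < d, (d - x) / (d - cc), 0)))
  }
  vapply(seq_len(nrow(X)), function(i) {
    agg <- c(enhancer = 0, non_enhancer = 0)
    for (r in rulebase$rules) {
      f <- 1
      for (k in seq_along(r$marks)) {
        set <- rulebase$partitions[[r$marks[k]]]$sets[[r$labels[k]]]
        f <- min(f, trap(X[i, r$marks[k]], set$upper))
      }
      agg[r$consequent] <- agg[r$consequent] + r$dominance * f
    }
    if (sum(agg) == 0) rulebase$default_probability
    else unname(agg["enhancer"] / sum(agg))
  }, numeric(1))
}

# brute-force confusion matrix / metrics oracle
metrics_oracle <- function(p, y, threshold = 0.5) {
  pred <- p > threshold
  TP <- sum(pred & y); TN <- sum(!pred & !y)
  FP <- sum(pred & !y); FN <- sum(!pred & y)
  pos <- p[y]; neg <- p[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = (TP + TN) / (TP + TN + FP + FN),
       precision = TP / (TP + FP), recall = TP / (TP + FN),
       average_recall = (TP / (TP + FN) + TN / (TN + FP)) / 2,
       auc = auc, gini = 2 * auc - 1)
}

# exhaustive call+merge oracle: threshold runs, then try every merge of
# adjacent regions (gap <= max_gap, combined member-bin mean strictly above
# threshold) until no merge applies, scanning left to right
calling_oracle <- function(p, bin_width = 10, threshold = 0.8,
                           max_gap = 100) {
  n <- length(p)
  hot <- p >= threshold
  regions <- list()
  i <- 1
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1]) j <- j + 1
      regions[[length(regions) + 1]] <-
        list(start = (i - 1) * bin_width, end = j * bin_width,
             bins = i:j)
      i <- j + 1
    } else i <- i + 1
  }
  repeat {
    merged <- FALSE
    k <- 1
    while (k < length(regions)) {
      a <- regions[[k]]; b <- regions[[k + 1]]
      gap <- b$start - a$end
      if (gap <= max_gap &&
          mean(p[c(a$bins, b$bins)]) > threshold) {
        regions[[k]] <- list(start = a$start, end = b$end,
                             bins = c(a$bins, b$bins))
        regions[[k + 1]] <- NULL
        merged <- TRUE
      } else k <- k + 1
    }
    if (!merged) break
  }
  regions
}

jaccard_bp <- function(a, b) {
  inter <- sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::granges(a), GenomicRanges::granges(b))))
  uni <- sum(IRanges::width(GenomicRanges::union(
    GenomicRanges::granges(a), GenomicRanges::granges(b))))
  inter / uni
}

granges <- function(chrom, start0, end0, ...)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
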