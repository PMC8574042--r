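#' Evolutionary induction of a constrained fuzzy rule base
#'
#' A rule base of at most 50 rules, each with at most 3 antecedents, is
#' learned from a labeled bin dataset by a seeded genetic search over
#' variable-length rule lists. Candidate rules are harvested from the data
#' (all single- and two-antecedent linguistic patterns plus rules read off
#' individual training bins); the GA then selects and mutates a compact,
#' discriminative subset. Fitness is a weighted scalarization of balanced
#' accuracy minus parsimony penalties on rule and antecedent counts; the
#' rule/antecedent caps are hard constraints enforced by repair. Rule
#' dominance (the rule-quality score used for weighting and reporting) is
#' confidence x support on the training data, scaled to [0, 10] within each
#' consequent class.
#'
#' @name rule-induction
NULL

#' Induction configuration
#'
#' @param max_rules Maximum rules in the base (default 50).
#' @param max_antecedents Maximum antecedents per rule (1..3, default 3).
#' @param pop_size Population size.
#' @param generations Maximum generations.
#' @param crossover_rate Probability a child is produced by crossover.
#' @param mutation_rate Probability each child is mutated.
#' @param jitter_rate Probability a mutation jitters partition anchors.
#' @param weights Objective weights: `accuracy` (balanced accuracy),
#'   `rules` (rule-count penalty), `antecedents` (antecedent-count penalty).
#' @param elitism Number of best individuals copied unchanged.
#' @param patience Generations without improvement before early stop.
#' @param tol Minimum fitness improvement counted as progress.
#' @param fit_sample Bins used for fitness evaluation (stratified subsample
#'   of the training set when it is larger; final dominance is computed on
#'   the full training set).
#' @param overlap,fou Partition geometry passed to
#'   [initialize_partitions()].
#' @param seed Integer seed; fixes the whole search.
#' @return An object of class `induction_config`.
#' @export
induction_config <- function(max_rules = 50, max_antecedents = 3,
                             pop_size = 100, generations = 200,
                             crossover_rate = 0.7, mutation_rate = 0.4,
                             jitter_rate = 0.05,
                             weights = c(accuracy = 1, rules = 0.02,
                                         antecedents = 0.01),
                             elitism = 2, patience = 30, tol = 1e-4,
                             fit_sample = 20000,
                             overlap = 0.3, fou = 0.3, seed = 1) {
  if (max_rules < 2) .stopf("max_rules must be >= 2")
  if (!max_antecedents %in% 1:3)
    .stopf("max_antecedents must be 1, 2 or 3")
  .check_fraction(crossover_rate, "crossover_rate")
  .check_fraction(mutation_rate, "mutation_rate")
  .check_fraction(jitter_rate, "jitter_rate")
  structure(list(max_rules = max_rules, max_antecedents = max_antecedents,
                 pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, jitter_rate = jitter_rate,
                 weights = weights, elitism = elitism, patience = patience,
                 tol = tol, fit_sample = fit_sample, overlap = overlap,
                 fou = fou, seed = seed),
            class = "induction_config")
}

#' Quantile-anchored fuzzy partitions for every mark
#'
#' Each mark gets a low/medium/high partition anchored at its empirical
#' 25th/50th/75th percentile ([fuzzy_partition()] geometry). Constant marks
#' (degenerate quantiles) are flagged and excluded from rule search.
#'
#' @param dataset A [bin_dataset()] with normalized features.
#' @param overlap Ramp overlap fraction.
#' @param fou Footprint-of-uncertainty fraction.
#' @return Named list of [fuzzy_partition()]; degenerate marks are recorded
#'   in `attr(, "degenerate")`.
#' @export
initialize_partitions <- function(dataset, overlap = 0.3, fou = 0.3) {
  stopifnot(inherits(dataset, "bin_dataset"))
  marks <- dataset$feature_order
  degenerate <- character(0)
  parts <- list()
  for (m in marks) {
    q <- unname(quantile(dataset$features[, m], c(0.25, 0.5, 0.75),
                         names = FALSE))
    if (any(diff(q) <= 1e-6)) {
      degenerate <- c(degenerate, m)
      next
    }
    parts[[m]] <- fuzzy_partition(m, anchors = q, overlap = overlap,
                                  fou = fou)
  }
  if (length(degenerate))
    .warnf("degenerate (near-constant) mark(s) excluded from rule search: %s",
           paste(degenerate, collapse = ", "))
  attr(parts, "degenerate") <- degenerate
  parts
}

# ---- internal GA machinery --------------------------------------------------

.rule_key <- function(r) {
  ord <- order(r$marks)
  paste(r$consequent,
        paste(r$marks[ord], r$labels[ord], sep = "=", collapse = "&"))
}

# membership cache: one entry per distinct partition geometry, covering
# every mark (so all individuals sharing the geometry share the entry)
.mu_for <- function(cache, partitions, X, marks = names(partitions)) {
  sig <- paste(vapply(partitions, function(p)
    paste(format(p$anchors, digits = 10), collapse = ","), character(1)),
    collapse = ";")
  if (!is.null(cache[[sig]])) return(cache[[sig]])
  mu <- lapply(partitions, function(p) .partition_memberships(p, X[, p$mark]))
  cache[[sig]] <- mu
  mu
}

# confidence x support dominance for each rule, raw (unscaled)
.raw_dominance <- function(mid, cls, y) {
  tot <- colSums(mid)
  in_class <- vapply(seq_along(cls), function(j) {
    yy <- if (cls[j] == "enhancer") y else !y
    sum(mid[yy, j])
  }, numeric(1))
  conf <- ifelse(tot > 0, in_class / tot, 0)
  supp <- in_class / nrow(mid)
  conf * supp
}

.scale_dominance <- function(raw, cls) {
  scale <- c(enhancer = 0, non_enhancer = 0)
  for (cl in .CLASSES) {
    mx <- suppressWarnings(max(raw[cls == cl]))
    scale[cl] <- if (is.finite(mx) && mx > 0) 10 / mx else 0
  }
  list(dominance = pmin(raw * scale[cls], 10), scale = scale)
}

.balanced_accuracy <- function(pred, y) {
  tpr <- if (any(y)) mean(pred[y]) else 0
  tnr <- if (any(!y)) mean(!pred[!y]) else 0
  (tpr + tnr) / 2
}

# fitness from a precomputed midpoint-firing matrix (one column per rule):
# dominance, inference probabilities, balanced accuracy at the 0.5 operating
# point and the penalized scalar objective. When `dom_idx`/`score_idx` are
# given (disjoint halves of the fitness subset), dominance is estimated on
# one half and accuracy scored on the other — cross-fitting that stops the
# search from crediting rules which merely memorise label-noise bins.
.fitness_from_mid <- function(mid, cls, y, n_ant, cfg, dom_idx = NULL,
                              score_idx = NULL) {
  if (is.null(dom_idx)) dom_idx <- seq_len(nrow(mid))
  if (is.null(score_idx)) score_idx <- seq_len(nrow(mid))
  raw <- .raw_dominance(mid[dom_idx, , drop = FALSE], cls, y[dom_idx])
  sc <- .scale_dominance(raw, cls)
  is_enh <- cls == "enhancer"
  ms <- mid[score_idx, , drop = FALSE]
  agg_e <- as.vector(ms[, is_enh, drop = FALSE] %*% sc$dominance[is_enh])
  agg_n <- as.vector(ms[, !is_enh, drop = FALSE] %*% sc$dominance[!is_enh])
  total <- agg_e + agg_n
  p <- ifelse(total > 0, agg_e / total, 0.5)
  bal <- .balanced_accuracy(p > 0.5, y[score_idx])
  w <- cfg$weights
  fit <- w[["accuracy"]] * bal -
    w[["rules"]] * ncol(mid) / cfg$max_rules -
    w[["antecedents"]] * n_ant / (cfg$max_rules * cfg$max_antecedents)
  list(fitness = fit, balanced_accuracy = bal, dominance = sc$dominance,
       scale = sc$scale)
}

# midpoint firing column of one rule; cached by rule key for the base
# partition geometry (the common case), recomputed directly otherwise
.rule_col <- function(rule, X, partitions, mu, col_cache = NULL) {
  key <- .rule_key(rule)
  if (!is.null(col_cache) && !is.null(col_cache[[key]]))
    return(col_cache[[key]])
  f <- .firing_matrix(list(rule), X, partitions, mu)
  col <- (f$lower[, 1L] + f$upper[, 1L]) / 2
  if (!is.null(col_cache)) col_cache[[key]] <- col
  col
}

# evaluate an individual on the fitness subset
.eval_individual <- function(ind, feat, y, base_partitions, cfg, cache,
                             col_cache = NULL) {
  X <- feat
  jittered <- !is.null(ind$partitions)
  partitions <- if (jittered) ind$partitions else base_partitions
  mu <- .mu_for(cache, partitions, X)
  cc <- if (jittered) NULL else col_cache
  cols <- lapply(ind$rules, function(r) .rule_col(r, X, partitions, mu, cc))
  mid <- do.call(cbind, cols)
  cls <- vapply(ind$rules, `[[`, character(1), "consequent")
  n_ant <- sum(lengths(lapply(ind$rules, `[[`, "marks")))
  res <- .fitness_from_mid(mid, cls, y, n_ant, cfg, cfg$dom_idx,
                           cfg$score_idx)
  for (j in seq_along(ind$rules)) ind$rules[[j]]$dominance <- res$dominance[j]
  ind$fitness <- res$fitness
  ind$balanced_accuracy <- res$balanced_accuracy
  ind
}

# drop rules that do not pay their way: try removing each rule from the
# individual and keep the removal with the best fitness gain, repeating
# until no single removal helps (base-partition individuals only)
.prune_individual <- function(ind, y, cfg, col_cache) {
  repeat {
    if (length(ind$rules) <= 2L) return(ind)
    keys <- vapply(ind$rules, .rule_key, character(1))
    cols <- lapply(keys, function(k) col_cache[[k]])
    if (any(vapply(cols, is.null, logical(1)))) return(ind)
    mid <- do.call(cbind, cols)
    cls <- vapply(ind$rules, `[[`, character(1), "consequent")
    nant <- lengths(lapply(ind$rules, `[[`, "marks"))
    cur <- .fitness_from_mid(mid, cls, y, sum(nant), cfg, cfg$dom_idx,
                             cfg$score_idx)$fitness
    best_gain <- 0
    drop_j <- 0L
    for (j in seq_along(ind$rules)) {
      keep <- setdiff(seq_along(ind$rules), j)
      if (!all(.CLASSES %in% cls[keep])) next
      f <- .fitness_from_mid(mid[, keep, drop = FALSE], cls[keep], y,
                             sum(nant[keep]), cfg, cfg$dom_idx,
                             cfg$score_idx)$fitness
      if (f - cur > best_gain + 1e-12) { best_gain <- f - cur; drop_j <- j }
    }
    if (drop_j == 0L) return(ind)
    ind$rules <- ind$rules[-drop_j]
    ind$fitness <- NULL
  }
}

# inject fresh candidate rules read off currently misclassified bins
# (covering-style pool refresh keyed to where the best individual fails)
.inject_candidates <- function(pool, best, X, y, partitions, cfg, cache,
                               col_cache, n_bins = 40L) {
  mu <- .mu_for(cache, partitions, X)
  cols <- lapply(best$rules, function(r)
    .rule_col(r, X, partitions, mu, col_cache))
  mid <- do.call(cbind, cols)
  cls <- vapply(best$rules, `[[`, character(1), "consequent")
  res <- .fitness_from_mid(mid, cls, y, 1, cfg)
  is_enh <- cls == "enhancer"
  agg_e <- as.vector(mid[, is_enh, drop = FALSE] %*% res$dominance[is_enh])
  agg_n <- as.vector(mid[, !is_enh, drop = FALSE] %*% res$dominance[!is_enh])
  p <- ifelse(agg_e + agg_n > 0, agg_e / (agg_e + agg_n), 0.5)
  mis <- which((p > 0.5) != y)
  if (!length(mis)) return(invisible(NULL))
  take <- .resample(mis, min(n_bins, length(mis)))
  marks <- names(partitions)
  med_quality <- stats::median(pool$quality)
  for (i in take) {
    ups <- vapply(marks, function(m) {
      v <- vapply(.LING_LABELS, function(l) mu[[m]][[l]][i, "upper"],
                  numeric(1))
      c(max(v), which.max(v))
    }, numeric(2))
    labs <- .LING_LABELS[ups[2L, ]]
    ord <- order(-ups[1L, ])
    k <- .resample(seq_len(cfg$max_antecedents), 1L)
    ms <- marks[ord[seq_len(k)]]
    rule <- fuzzy_rule(ms, labs[match(ms, marks)],
                       if (y[i]) "enhancer" else "non_enhancer")
    key <- .rule_key(rule)
    if (key %in% pool$keys) next
    pool$rules[[length(pool$rules) + 1L]] <- rule
    pool$class <- c(pool$class, rule$consequent)
    pool$quality <- c(pool$quality, med_quality)
    pool$keys <- c(pool$keys, key)
    .rule_col(rule, X, partitions, mu, col_cache)
  }
  invisible(NULL)
}

# greedy set-cover seed: starting from the strongest enhancer rule, keep
# adding the pool rule that most improves fitness; gives the GA a
# coordinated starting point (discriminative enhancer rules plus the
# non-enhancer guards that damp partial firing in the background)
.greedy_build <- function(pool, y, cfg, max_size = 14L) {
  P <- length(pool$rules)
  sel <- which(pool$class == "enhancer")[1L]
  best <- -Inf
  while (length(sel) < min(max_size, cfg$max_rules)) {
    gain_best <- -Inf
    pick <- 0L
    for (j in seq_len(P)) {
      if (j %in% sel) next
      s <- c(sel, j)
      n_ant <- sum(lengths(lapply(pool$rules[s], `[[`, "marks")))
      f <- .fitness_from_mid(pool$mid[, s, drop = FALSE], pool$class[s],
                             y, n_ant, cfg, cfg$dom_idx,
                             cfg$score_idx)$fitness
      if (f > gain_best) { gain_best <- f; pick <- j }
    }
    if (pick == 0L || gain_best <= best + 1e-9) break
    sel <- c(sel, pick)
    best <- gain_best
  }
  list(rules = pool$rules[sel], partitions = NULL)
}

# hard-constraint repair: dedupe, cap antecedents and rule count, ensure
# both consequent classes are represented
.repair <- function(ind, pool, cfg) {
  rules <- ind$rules
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    if (length(r$marks) > cfg$max_antecedents) {
      keep <- seq_len(cfg$max_antecedents)
      rules[[j]] <- fuzzy_rule(r$marks[keep], r$labels[keep], r$consequent,
                               r$dominance)
    }
  }
  keys <- vapply(rules, .rule_key, character(1))
  rules <- rules[!duplicated(keys)]
  if (length(rules) > cfg$max_rules)
    rules <- rules[seq_len(cfg$max_rules)]
  cls <- vapply(rules, `[[`, character(1), "consequent")
  for (cl in .CLASSES) {
    if (!any(cls == cl)) {
      cand <- pool$rules[pool$class == cl]
      add <- cand[[1L]]
      if (length(rules) >= cfg$max_rules) rules <- rules[-length(rules)]
      rules <- c(rules, list(add))
      cls <- vapply(rules, `[[`, character(1), "consequent")
    }
  }
  ind$rules <- rules
  ind
}

# Harvest candidate rules from the data: every singleton and mark-pair
# linguistic pattern (consequent assigned by lift over the class prior) plus
# rules read off sampled bins (strongest memberships first). Returns the
# pool ordered by discriminative quality.
.candidate_pool <- function(X, y, partitions, cfg) {
  marks <- names(partitions)
  mu <- lapply(setNames(marks, marks), function(m)
    .partition_memberships(partitions[[m]], X[, m]))
  prior_e <- mean(y)
  mk_rule <- function(ms, ls) {
    f <- rep(1, nrow(X))
    for (k in seq_along(ms)) {
      mm <- mu[[ms[k]]][[ls[k]]]
      f <- pmin(f, (mm[, "lower"] + mm[, "upper"]) / 2)
    }
    tot <- sum(f)
    if (tot <= 0) return(NULL)
    conf_e <- sum(f[y]) / tot
    lift_e <- conf_e / max(prior_e, 1e-12)
    lift_n <- (1 - conf_e) / max(1 - prior_e, 1e-12)
    cl <- if (lift_e >= lift_n) "enhancer" else "non_enhancer"
    supp <- (if (cl == "enhancer") sum(f[y]) else sum(f[!y])) / nrow(X)
    list(rule = fuzzy_rule(ms, ls, cl), class = cl,
         quality = max(lift_e, lift_n) * supp, col = f)
  }
  cands <- list()
  for (m in marks) for (l in .LING_LABELS) {
    cands[[length(cands) + 1L]] <- mk_rule(m, l)
  }
  if (length(marks) <= 12L && cfg$max_antecedents >= 2L) {
    prs <- utils::combn(marks, 2L, simplify = FALSE)
    for (pr in prs) for (l1 in .LING_LABELS) for (l2 in .LING_LABELS) {
      cands[[length(cands) + 1L]] <- mk_rule(pr, c(l1, l2))
    }
  }
  # bin-derived rules: read the strongest linguistic pattern off sampled bins
  for (cl_val in c(TRUE, FALSE)) {
    idx <- which(y == cl_val)
    if (!length(idx)) next
    take <- idx[sample.int(length(idx), min(100L, length(idx)))]
    for (i in take) {
      strengths <- vapply(marks, function(m) {
        ups <- vapply(.LING_LABELS, function(l) mu[[m]][[l]][i, "upper"],
                      numeric(1))
        max(ups)
      }, numeric(1))
      labs <- vapply(marks, function(m) {
        ups <- vapply(.LING_LABELS, function(l) mu[[m]][[l]][i, "upper"],
                      numeric(1))
        .LING_LABELS[which.max(ups)]
      }, character(1))
      ord <- order(-strengths)
      for (k in seq_len(min(cfg$max_antecedents, length(marks)))) {
        ms <- marks[ord[seq_len(k)]]
        cands[[length(cands) + 1L]] <- mk_rule(ms, labs[ms])
      }
    }
  }
  cands <- Filter(Negate(is.null), cands)
  # guarantee both consequent classes exist in the pool (repair relies on it)
  have <- vapply(cands, `[[`, character(1), "class")
  for (cl in .CLASSES) {
    if (!cl %in% have) {
      lab <- if (cl == "enhancer") "high" else "low"
      cands[[length(cands) + 1L]] <- list(
        rule = fuzzy_rule(marks[1], lab, cl), class = cl, quality = 1e-6,
        col = mk_rule(marks[1], lab)$col)
    }
  }
  keys <- vapply(cands, function(cc) .rule_key(cc$rule), character(1))
  cands <- cands[!duplicated(keys)]
  quality <- vapply(cands, `[[`, numeric(1), "quality")
  ord <- order(-quality)
  cands <- cands[ord]
  list(rules = lapply(cands, `[[`, "rule"),
       class = vapply(cands, `[[`, character(1), "class"),
       quality = vapply(cands, `[[`, numeric(1), "quality"),
       mid = do.call(cbind, lapply(cands, `[[`, "col")),
       keys = vapply(cands, function(cc) .rule_key(cc$rule), character(1)))
}

# quality-biased half the time, uniform the other half (exploration)
.sample_pool_rule <- function(pool, class = NULL) {
  idx <- seq_along(pool$rules)
  if (!is.null(class)) idx <- idx[pool$class == class]
  w <- if (runif(1) < 0.5) pool$quality[idx] + 1e-9
       else rep(1, length(idx))
  pool$rules[[.resample(idx, 1L, prob = w / sum(w))]]
}

.mutate <- function(ind, pool, partitions, cfg, marks) {
  op <- sample(c("add", "drop", "mark", "label", "consequent", "ant_add",
                 "ant_drop"), 1L)
  rules <- ind$rules
  j <- sample.int(length(rules), 1L)
  r <- rules[[j]]
  if (op == "add") {
    rules <- c(rules, list(.sample_pool_rule(pool)))
  } else if (op == "drop" && length(rules) > 2L) {
    rules <- rules[-j]
  } else if (op == "mark") {
    k <- sample.int(length(r$marks), 1L)
    free <- setdiff(marks, r$marks)
    if (length(free)) {
      r$marks[k] <- sample(free, 1L)
      rules[[j]] <- r
    }
  } else if (op == "label") {
    k <- sample.int(length(r$marks), 1L)
    r$labels[k] <- sample(setdiff(.LING_LABELS, r$labels[k]), 1L)
    rules[[j]] <- r
  } else if (op == "consequent") {
    r$consequent <- setdiff(.CLASSES, r$consequent)
    rules[[j]] <- r
  } else if (op == "ant_add" && length(r$marks) < cfg$max_antecedents) {
    free <- setdiff(marks, r$marks)
    if (length(free)) {
      m <- sample(free, 1L)
      r$marks <- c(r$marks, m)
      r$labels <- c(r$labels, sample(.LING_LABELS, 1L))
      rules[[j]] <- r
    }
  } else if (op == "ant_drop" && length(r$marks) > 1L) {
    k <- sample.int(length(r$marks), 1L)
    r$marks <- r$marks[-k]
    r$labels <- r$labels[-k]
    rules[[j]] <- r
  }
  ind$rules <- rules
  # occasional anchor jitter opens a new partition geometry for the whole
  # individual
  if (runif(1) < cfg$jitter_rate) {
    parts <- if (is.null(ind$partitions)) partitions else ind$partitions
    m <- sample(names(parts), 1L)
    anc <- parts[[m]]$anchors + rnorm(3L, sd = 0.02)
    anc <- pmin(pmax(sort(anc), 0.01), 0.99)
    if (!is.unsorted(anc, strictly = TRUE)) {
      parts[[m]] <- fuzzy_partition(m, anchors = anc,
                                    overlap = parts[[m]]$overlap,
                                    fou = parts[[m]]$fou)
      ind$partitions <- parts
    }
  }
  ind
}

.crossover <- function(p1, p2) {
  all_rules <- c(p1$rules, p2$rules)
  keep <- runif(length(all_rules)) < 0.5
  if (!any(keep)) keep[sample.int(length(all_rules), 1L)] <- TRUE
  list(rules = all_rules[keep],
       partitions = if (runif(1) < 0.5) p1$partitions else p2$partitions)
}

#' Induce a fuzzy rule base from labeled bins
#'
#' Runs the seeded evolutionary search described in
#' \link[=rule-induction]{the module overview} and returns the best feasible
#' rule base, with every rule's dominance recomputed on the full training
#' set. The best fitness per generation is recorded in
#' `attr(, "history")` and never decreases (elitism).
#'
#' @param train A [bin_dataset()] containing both classes.
#' @param config An [induction_config()].
#' @param partitions Optional precomputed partitions; defaults to
#'   [initialize_partitions()] on `train`.
#' @return A [rule_base()].
#' @export
induce_rulebase <- function(train, config = induction_config(),
                            partitions = NULL) {
  stopifnot(inherits(train, "bin_dataset"),
            inherits(config, "induction_config"))
  y_all <- train$labels
  if (!any(y_all) || all(y_all))
    .stopf("training data must contain both classes")
  if (is.null(partitions))
    partitions <- initialize_partitions(train, config$overlap, config$fou)
  marks <- names(partitions)
  if (!length(marks)) .stopf("no usable (non-degenerate) marks")

  .with_seed(config$seed, {
    n <- nrow(train$features)
    if (n > config$fit_sample) {
      pos <- which(y_all); neg <- which(!y_all)
      n_pos <- max(1L, round(config$fit_sample * length(pos) / n))
      fit_idx <- sort(c(.resample(pos, min(n_pos, length(pos))),
                        .resample(neg, config$fit_sample - n_pos)))
    } else fit_idx <- seq_len(n)
    X <- train$features[fit_idx, marks, drop = FALSE]
    y <- y_all[fit_idx]
    # disjoint stratified halves of the fitness subset for cross-fitting
    pos_f <- which(y); neg_f <- which(!y)
    config$dom_idx <- sort(c(pos_f[c(TRUE, FALSE)], neg_f[c(TRUE, FALSE)]))
    config$score_idx <- setdiff(seq_along(y), config$dom_idx)

    pool <- list2env(.candidate_pool(X, y, partitions, config),
                     new.env(parent = emptyenv()))
    cache <- new.env(parent = emptyenv())
    col_cache <- new.env(parent = emptyenv())
    for (j in seq_along(pool$keys))
      col_cache[[pool$keys[j]]] <- pool$mid[, j]

    new_individual <- function() {
      k <- sample(2:8, 1L)
      idx <- sample.int(length(pool$rules), min(k, length(pool$rules)),
                        prob = pool$quality + 1e-9)
      list(rules = pool$rules[idx], partitions = NULL)
    }
    seeds <- lapply(c(14L, 8L, 5L), function(k)
      .greedy_build(pool, y, config, max_size = k))
    pop <- c(seeds, lapply(seq_len(config$pop_size - length(seeds)),
                           function(i) new_individual()))
    pop <- lapply(pop, .repair, pool = pool, cfg = config)
    pop <- lapply(pop, .eval_individual, feat = X, y = y,
                  base_partitions = partitions, cfg = config, cache = cache,
                  col_cache = col_cache)

    history <- numeric(0)
    best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
    stall <- 0L
    for (gen in seq_len(config$generations)) {
      fits <- vapply(pop, `[[`, numeric(1), "fitness")
      ord <- order(-fits)
      elite <- pop[ord[seq_len(config$elitism)]]
      tournament <- function() {
        idx <- sample.int(length(pop), 3L)
        pop[[idx[which.max(fits[idx])]]]
      }
      children <- vector("list", config$pop_size - config$elitism)
      for (i in seq_along(children)) {
        child <- if (runif(1) < config$crossover_rate)
          .crossover(tournament(), tournament())
        else tournament()[c("rules", "partitions")]
        if (runif(1) < config$mutation_rate)
          child <- .mutate(child, pool, partitions, config, marks)
        children[[i]] <- .repair(child, pool, config)
      }
      children <- lapply(children, .eval_individual, feat = X, y = y,
                         base_partitions = partitions, cfg = config,
                         cache = cache, col_cache = col_cache)
      pop <- c(elite, children)
      gen_best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
      # memetic step: prune the generation best, keep it if it improved
      if (is.null(gen_best$partitions)) {
        pruned <- .prune_individual(gen_best, y, config, col_cache)
        if (is.null(pruned$fitness)) {
          pruned <- .eval_individual(pruned, X, y, partitions, config,
                                     cache, col_cache)
          if (pruned$fitness > gen_best$fitness) {
            gen_best <- pruned
            pop[[1L]] <- pruned
          }
        }
      }
      if (gen_best$fitness > best$fitness + config$tol) {
        best <- gen_best
        stall <- 0L
      } else {
        if (gen_best$fitness > best$fitness) best <- gen_best
        stall <- stall + 1L
      }
      history <- c(history, best$fitness)
      if (stall >= config$patience) break
      if (gen %% 10L == 0L && is.null(best$partitions))
        .inject_candidates(pool, best, X, y, partitions, config, cache,
                           col_cache)
    }

    # final dominance on the full training set
    final_parts <- if (is.null(best$partitions)) partitions else best$partitions
    Xf <- train$features[, marks, drop = FALSE]
    firing <- .firing_matrix(best$rules, Xf, final_parts)
    mid <- (firing$lower + firing$upper) / 2
    cls <- vapply(best$rules, `[[`, character(1), "consequent")
    raw <- .raw_dominance(mid, cls, y_all)
    sc <- .scale_dominance(raw, cls)
    rules <- best$rules
    for (j in seq_along(rules)) rules[[j]]$dominance <- sc$dominance[j]
    rb <- rule_base(rules, final_parts,
                    dominance_scale = sc$scale)
    attr(rb, "history") <- history
    attr(rb, "balanced_accuracy") <- best$balanced_accuracy
    rb
  })
}

#' Parse a rule literal
#'
#' Grammar: `"mark=label & mark=label => consequent"`, e.g.
#' `"H3K4me1=high & H3K27ac=high => enhancer"`.
#'
#' @param text Rule string.
#' @return A [fuzzy_rule()] (dominance 1 until computed on data).
#' @export
parse_rule <- function(text) {
  parts <- strsplit(text, "=>", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    .stopf("rule must contain '=>': %s", text)
  consequent <- gsub("[ -]", "_", trimws(parts[2]))
  ants <- strsplit(parts[1], "&", fixed = TRUE)[[1]]
  kv <- lapply(ants, function(a) {
    p <- trimws(strsplit(a, "=", fixed = TRUE)[[1]])
    if (length(p) != 2L) .stopf("bad antecedent '%s'", a)
    p
  })
  fuzzy_rule(vapply(kv, `[`, character(1), 1),
             vapply(kv, `[`, character(1), 2),
             consequent)
}

#' Append an expert rule to a trained rule base
#'
#' The rule is appended with its dominance computed on the training data
#' and scaled with the rule base's stored per-class dominance scale;
#' existing rules are untouched. Appending a rule identical to an existing
#' one is a no-op with a warning.
#'
#' @param rulebase A trained [rule_base()].
#' @param rule A [fuzzy_rule()] or a rule string for [parse_rule()].
#' @param train The training [bin_dataset()] used to weight the rule.
#' @param max_rules Rule-count cap (default 50).
#' @return The extended [rule_base()].
#' @export
add_expert_rule <- function(rulebase, rule, train, max_rules = 50) {
  stopifnot(inherits(rulebase, "rule_base"))
  if (is.character(rule)) rule <- parse_rule(rule)
  stopifnot(inherits(rule, "fuzzy_rule"))
  if (length(rulebase$rules) + 1L > max_rules)
    .stopf("adding this rule would exceed the %d-rule cap", max_rules)
  keys <- vapply(rulebase$rules, .rule_key, character(1))
  if (.rule_key(rule) %in% keys) {
    .warnf("expert rule duplicates an existing rule; not inserted")
    return(rulebase)
  }
  missing_marks <- setdiff(rule$marks, names(rulebase$partitions))
  if (length(missing_marks))
    .stopf("no partition for expert-rule mark(s): %s",
           paste(missing_marks, collapse = ", "))
  X <- train$features[, rule$marks, drop = FALSE]
  firing <- .firing_matrix(list(rule), X, rulebase$partitions)
  mid <- (firing$lower + firing$upper) / 2
  raw <- .raw_dominance(mid, rule$consequent, train$labels)
  scale <- rulebase$dominance_scale
  rule$dominance <- if (!is.null(scale) && scale[[rule$consequent]] > 0)
    min(raw * scale[[rule$consequent]], 10) else 1
  rulebase$rules <- c(rulebase$rules, list(rule))
  rulebase
}

#' Evaluate a rule base on a labeled dataset
#'
#' Per-bin probabilities are thresholded (predicted enhancer iff
#' probability strictly exceeds `threshold`, so the ignorance default of
#' 0.5 maps to non-enhancer at the default operating point). Metrics follow
#' the confusion-matrix formulas: accuracy (TP+TN)/(TP+TN+FP+FN), precision
#' TP/(TP+FP), recall TP/(TP+FN), average recall (mean of per-class
#' recalls), rank-based AUC and gini = 2 AUC - 1.
#'
#' @param rulebase A [rule_base()].
#' @param dataset A labeled [bin_dataset()].
#' @param threshold Classification threshold in (0, 1); this is the model
#'   operating point, distinct from the 0.8 region-calling threshold.
#' @return List with `confusion` (`TP`,`TN`,`FP`,`FN`) and `report`
#'   (accuracy, precision, recall, average_recall, auc, gini).
#' @export
evaluate_rulebase <- function(rulebase, dataset, threshold = 0.5) {
  p <- predict_probability(rulebase, dataset$features)
  res <- classification_metrics(p, dataset$labels, threshold)
  res$probabilities <- p
  res
}

#' Confusion-matrix metrics from probabilities and labels
#'
#' Predicted enhancer iff probability strictly exceeds `threshold`.
#' Accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall TP/(TP+FN),
#' average recall (mean of per-class recalls), rank-statistic AUC with
#' midranks for ties, gini = 2 AUC - 1.
#'
#' @param p Probabilities in [0, 1].
#' @param y Logical labels (`TRUE` = enhancer).
#' @param threshold Classification threshold in (0, 1).
#' @return List with `confusion` (TP/TN/FP/FN) and `report`.
#' @export
classification_metrics <- function(p, y, threshold = 0.5) {
  if (!.is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    .stopf("threshold must lie strictly inside (0, 1)")
  stopifnot(length(p) == length(y))
  pred <- p > threshold
  cm <- c(TP = sum(pred & y), TN = sum(!pred & !y),
          FP = sum(pred & !y), FN = sum(!pred & y))
  auc <- .rank_auc(p, y)
  report <- list(
    accuracy = (cm[["TP"]] + cm[["TN"]]) / sum(cm),
    precision = if (cm[["TP"]] + cm[["FP"]] > 0)
      cm[["TP"]] / (cm[["TP"]] + cm[["FP"]]) else NA_real_,
    recall = if (cm[["TP"]] + cm[["FN"]] > 0)
      cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NA_real_,
    average_recall = (
      (if (any(y)) mean(pred[y]) else NA_real_) +
      (if (any(!y)) mean(!pred[!y]) else NA_real_)) / 2,
    auc = auc,
    gini = 2 * auc - 1)
  list(confusion = cm, report = report)
}

# Mann-Whitney/rank statistic AUC with midranks for ties
.rank_auc <- function(p, y) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Apply a trained rule base to another dataset
#'
#' Pure inference without refitting (e.g. a model trained in one cell line
#' predicting enhancers in another). Marks in the dataset that the rule
#' base never references are ignored with a warning; a referenced mark that
#' is absent is an error.
#'
#' @param rulebase A [rule_base()].
#' @param other_dataset A [bin_dataset()].
#' @return Per-bin enhancer probabilities.
#' @export
cross_cell_apply <- function(rulebase, other_dataset) {
  stopifnot(inherits(other_dataset, "bin_dataset"))
  used <- .rulebase_marks(rulebase)
  have <- colnames(other_dataset$features)
  missing_marks <- setdiff(used, have)
  if (length(missing_marks))
    .stopf("dataset lacks mark(s) referenced by the rule base: %s",
           paste(missing_marks, collapse = ", "))
  extra <- setdiff(have, names(rulebase$partitions))
  if (length(extra))
    .warnf("ignoring mark(s) unknown to the rule base: %s",
           paste(extra, collapse = ", "))
  predict_probability(rulebase, other_dataset$features)
}
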