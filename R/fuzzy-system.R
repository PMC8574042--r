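#' Interval type-2 fuzzy sets, partitions, rules and inference
#'
#' Histone-modification signals are described linguistically as low, medium or
#' high. Each linguistic term is an interval type-2 fuzzy set: a pair of
#' trapezoidal membership functions (lower and upper bound) on the normalized
#' signal axis [0, 1]. The gap between the two trapezoids (footprint of
#' uncertainty) encodes how fuzzy the class boundary itself is, so mark
#' classifications "do not have stringent borders" but overlap.
#'
#' @name fuzzy-system
NULL

.LING_LABELS <- c("low", "medium", "high")
.CLASSES <- c("enhancer", "non_enhancer")

# ---- trapezoids -------------------------------------------------------------

# Evaluate a trapezoid given breakpoints a <= b <= c <= d. Value 1 on [b, c],
# linear ramps on [a, b] and [c, d], 0 outside. a == b (or c == d) encodes a
# vertical edge / shoulder.
.trapezoid <- function(x, bp) {
  a <- bp[1L]; b <- bp[2L]; cc <- bp[3L]; d <- bp[4L]
  y <- numeric(length(x))
  on_plateau <- x >= b & x <= cc
  y[on_plateau] <- 1
  if (b > a) {
    up <- x > a & x < b
    y[up] <- (x[up] - a) / (b - a)
  }
  if (d > cc) {
    dn <- x > cc & x < d
    y[dn] <- (d - x[dn]) / (d - cc)
  }
  y
}

.check_breakpoints <- function(bp, what) {
  if (!is.numeric(bp) || length(bp) != 4L || anyNA(bp))
    .stopf("%s breakpoints must be 4 finite numbers", what)
  if (is.unsorted(bp))
    .stopf("%s breakpoints must be non-decreasing (a <= b <= c <= d), got [%s]",
           what, paste(format(bp), collapse = ", "))
  invisible(bp)
}

#' Create an interval type-2 fuzzy set
#'
#' @param label Linguistic label, one of `"low"`, `"medium"`, `"high"`.
#' @param upper Breakpoints `c(a, b, c, d)` of the upper trapezoid.
#' @param lower Breakpoints of the lower trapezoid; defaults to `upper`,
#'   which degenerates to an ordinary (type-1) fuzzy set.
#' @param anchor Characteristic position of the set on [0, 1] (the empirical
#'   quantile it was anchored at); used only for ordering and reporting.
#' @return An object of class `fuzzy_set`.
#' @export
fuzzy_set <- function(label, upper, lower = upper, anchor = NA_real_) {
  label <- match.arg(label, .LING_LABELS)
  .check_breakpoints(upper, "upper")
  .check_breakpoints(lower, "lower")
  if (lower[1] < upper[1] || lower[2] < upper[2] ||
      lower[3] > upper[3] || lower[4] > upper[4])
    .stopf("lower trapezoid must lie within the upper trapezoid")
  structure(list(label = label, upper = upper, lower = lower, anchor = anchor),
            class = "fuzzy_set")
}

#' Evaluate interval membership of a fuzzy set
#'
#' Returns the lower and upper membership grades of `x` in `set`. Values
#' outside [0, 1] are clipped with a warning (normalized signals should not
#' leave the unit interval).
#'
#' @param set A [fuzzy_set()].
#' @param x Numeric vector of normalized signal values.
#' @return A two-column matrix with columns `lower` and `upper`.
#' @export
membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_set"))
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    .warnf("membership: clipping %d value(s) outside [0, 1]",
           sum(x < 0 | x > 1, na.rm = TRUE))
    x <- pmin(pmax(x, 0), 1)
  }
  cbind(lower = .trapezoid(x, set$lower), upper = .trapezoid(x, set$upper))
}

# ---- partitions -------------------------------------------------------------

#' Build a low/medium/high partition anchored at three signal values
#'
#' The three sets are anchored at `anchors` (typically the 25th, 50th and
#' 75th percentile of the mark). Crisp boundaries sit midway between adjacent
#' anchors; `overlap` widens the linear ramps around each boundary as a
#' fraction of the anchor spacing (0 = crisp partition whose supports touch
#' but do not intersect). `fou` opens a footprint of uncertainty by shifting
#' the upper/lower trapezoids outward/inward by that fraction of the ramp
#' half-width, producing the interval type-2 sets.
#'
#' @param mark Mark name.
#' @param anchors Increasing numeric vector of length 3 inside (0, 1).
#' @param overlap Ramp overlap fraction in [0, 1].
#' @param fou Footprint-of-uncertainty fraction in [0, 1].
#' @return An object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(mark, anchors = c(0.25, 0.5, 0.75),
                            overlap = 0.3, fou = 0.3) {
  if (length(anchors) != 3L || is.unsorted(anchors, strictly = TRUE))
    .stopf("anchors must be 3 strictly increasing values, got [%s]",
           paste(format(anchors), collapse = ", "))
  .check_fraction(overlap, "overlap")
  .check_fraction(fou, "fou")
  b12 <- (anchors[1] + anchors[2]) / 2
  b23 <- (anchors[2] + anchors[3]) / 2
  w12 <- overlap * (anchors[2] - anchors[1]) / 2
  w23 <- overlap * (anchors[3] - anchors[2]) / 2
  base <- list(
    low    = c(0, 0, b12 - w12, b12 + w12),
    medium = c(b12 - w12, b12 + w12, b23 - w23, b23 + w23),
    high   = c(b23 - w23, b23 + w23, 1, 1)
  )
  u <- fou * min(w12, w23)
  sets <- lapply(.LING_LABELS, function(lab) {
    bp <- base[[lab]]
    shoulder_left <- bp[1] == bp[2]
    shoulder_right <- bp[3] == bp[4]
    upper <- c(if (shoulder_left) bp[1:2] else bp[1:2] - u,
               if (shoulder_right) bp[3:4] else bp[3:4] + u)
    lower <- c(if (shoulder_left) bp[1:2] else bp[1:2] + u,
               if (shoulder_right) bp[3:4] else bp[3:4] - u)
    if (lower[2] > lower[3]) lower[2] <- lower[3] <- mean(lower[2:3])
    fuzzy_set(lab, upper = upper, lower = lower,
              anchor = anchors[match(lab, .LING_LABELS)])
  })
  names(sets) <- .LING_LABELS
  structure(list(mark = mark, sets = sets, anchors = anchors,
                 overlap = overlap, fou = fou),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("fuzzy partition for %s (anchors %s)\n", x$mark,
              paste(format(x$anchors, digits = 3), collapse = "/")))
  invisible(x)
}

# Lower/upper membership of x in every set of a partition, as a named list of
# two-column matrices. The workhorse behind vectorized inference.
.partition_memberships <- function(partition, x) {
  x <- pmin(pmax(x, 0), 1)
  lapply(partition$sets, function(s)
    cbind(lower = .trapezoid(x, s$lower), upper = .trapezoid(x, s$upper)))
}

# ---- rules and rule bases ---------------------------------------------------

#' Create a fuzzy IF/THEN rule
#'
#' @param marks Character vector (1..3) of distinct mark names.
#' @param labels Linguistic label per mark (`"low"`, `"medium"`, `"high"`).
#' @param consequent `"enhancer"` or `"non_enhancer"`.
#' @param dominance Non-negative rule-quality weight (confidence x support of
#'   the rule on training data, scaled to [0, 10] per class at induction).
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(marks, labels, consequent, dominance = 1) {
  marks <- as.character(marks)
  labels <- as.character(labels)
  if (length(marks) < 1L || length(marks) > 3L)
    .stopf("a rule must have between 1 and 3 antecedents, got %d", length(marks))
  if (anyDuplicated(marks))
    .stopf("antecedent marks must be distinct within a rule")
  if (length(labels) != length(marks) || !all(labels %in% .LING_LABELS))
    .stopf("labels must match marks and be one of %s",
           paste(.LING_LABELS, collapse = "/"))
  consequent <- match.arg(consequent, .CLASSES)
  if (!.is_scalar_number(dominance) || dominance < 0)
    .stopf("dominance must be a non-negative number")
  structure(list(marks = marks, labels = labels, consequent = consequent,
                 dominance = dominance),
            class = "fuzzy_rule")
}

#' @export
format.fuzzy_rule <- function(x, ...) {
  ante <- paste(sprintf("%s is %s", x$marks, x$labels), collapse = " AND ")
  sprintf("IF %s THEN %s", ante, x$consequent)
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  cat(format(x), sprintf("  [dominance %.3g]\n", x$dominance))
  invisible(x)
}

#' Assemble a rule base
#'
#' @param rules List of [fuzzy_rule()] objects (at most 50).
#' @param partitions Named list of [fuzzy_partition()], one per mark used.
#' @param default_class Class returned when no rule fires.
#' @param default_probability Enhancer probability when no rule fires;
#'   defaults to 0.5 (ignorance), below the 0.8 calling threshold so silent
#'   bins are never called enhancers.
#' @param dominance_scale Internal per-class scale mapping raw
#'   confidence x support onto [0, 10]; kept so expert rules added later are
#'   weighted on the same scale.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(rules, partitions, default_class = "non_enhancer",
                      default_probability = 0.5, dominance_scale = NULL) {
  if (!length(rules)) .stopf("a rule base needs at least one rule")
  if (length(rules) > 50L)
    .stopf("a rule base is limited to 50 rules, got %d", length(rules))
  lapply(rules, function(r) stopifnot(inherits(r, "fuzzy_rule")))
  used <- unique(unlist(lapply(rules, `[[`, "marks")))
  missing_parts <- setdiff(used, names(partitions))
  if (length(missing_parts))
    .stopf("no partition provided for mark(s): %s",
           paste(missing_parts, collapse = ", "))
  .check_fraction(default_probability, "default_probability")
  structure(list(rules = rules, partitions = partitions,
                 default_class = match.arg(default_class, .CLASSES),
                 default_probability = default_probability,
                 dominance_scale = dominance_scale),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("rule base: %d rules over %d marks\n",
              length(x$rules), length(x$partitions)))
  for (i in seq_along(x$rules))
    cat(sprintf("%3d. %s  [dominance %.2f]\n", i, format(x$rules[[i]]),
                x$rules[[i]]$dominance))
  invisible(x)
}

.rulebase_marks <- function(rulebase)
  unique(unlist(lapply(rulebase$rules, `[[`, "marks")))

#' Firing strength of one rule on one feature vector
#'
#' Antecedents are combined with the minimum t-norm, applied separately to
#' the lower and upper membership grades.
#'
#' @param rule A [fuzzy_rule()].
#' @param features Named numeric vector of normalized mark values.
#' @param partitions Named list of [fuzzy_partition()].
#' @return `c(lower, upper)` firing strength.
#' @export
rule_firing <- function(rule, features, partitions) {
  missing_marks <- setdiff(rule$marks, names(features))
  if (length(missing_marks))
    .stopf("rule references mark(s) absent from features: %s",
           paste(missing_marks, collapse = ", "))
  lo <- 1; up <- 1
  for (k in seq_along(rule$marks)) {
    m <- membership(partitions[[rule$marks[k]]]$sets[[rule$labels[k]]],
                    features[[rule$marks[k]]])
    lo <- min(lo, m[, "lower"])
    up <- min(up, m[, "upper"])
  }
  c(lower = lo, upper = up)
}

# Vectorized lower/upper firing of every rule over a feature matrix.
# Returns list(lower = n x R matrix, upper = n x R matrix).
.firing_matrix <- function(rules, X, partitions, mu = NULL) {
  marks <- unique(unlist(lapply(rules, `[[`, "marks")))
  if (is.null(mu)) {
    mu <- lapply(setNames(marks, marks), function(m)
      .partition_memberships(partitions[[m]], X[, m]))
  }
  n <- nrow(X)
  R <- length(rules)
  lo <- matrix(1, n, R)
  up <- matrix(1, n, R)
  for (j in seq_len(R)) {
    r <- rules[[j]]
    for (k in seq_along(r$marks)) {
      mm <- mu[[r$marks[k]]][[r$labels[k]]]
      lo[, j] <- pmin(lo[, j], mm[, "lower"])
      up[, j] <- pmin(up[, j], mm[, "upper"])
    }
  }
  list(lower = lo, upper = up)
}

# Core probability computation shared by infer()/predict_probability().
# Dominance-weighted sum per class, interval midpoint type reduction,
# probability = enhancer aggregate / total aggregate.
.probability_from_firing <- function(rules, firing, default_probability) {
  dom <- vapply(rules, `[[`, numeric(1), "dominance")
  cls <- vapply(rules, `[[`, character(1), "consequent")
  mid <- (firing$lower + firing$upper) / 2
  is_enh <- cls == "enhancer"
  agg_e <- as.vector(mid[, is_enh, drop = FALSE] %*% dom[is_enh])
  agg_n <- as.vector(mid[, !is_enh, drop = FALSE] %*% dom[!is_enh])
  total <- agg_e + agg_n
  p <- ifelse(total > 0, agg_e / total, default_probability)
  list(probability = p, midpoint = mid, enhancer_agg = agg_e,
       non_enhancer_agg = agg_n)
}

#' Enhancer probability for a matrix of feature vectors
#'
#' Vectorized inference: one probability per row of `X`.
#'
#' @param rulebase A [rule_base()].
#' @param X Numeric matrix with one column per mark (named).
#' @return Numeric vector of enhancer probabilities in [0, 1].
#' @export
predict_probability <- function(rulebase, X) {
  stopifnot(inherits(rulebase, "rule_base"))
  if (!length(rulebase$rules)) .stopf("empty rule base")
  marks <- .rulebase_marks(rulebase)
  missing_marks <- setdiff(marks, colnames(X))
  if (length(missing_marks))
    .stopf("feature matrix lacks mark(s) referenced by rules: %s",
           paste(missing_marks, collapse = ", "))
  firing <- .firing_matrix(rulebase$rules, X, rulebase$partitions)
  .probability_from_firing(rulebase$rules, firing,
                           rulebase$default_probability)$probability
}

#' Fuzzy inference for a single feature vector
#'
#' @param rulebase A [rule_base()].
#' @param features Named numeric vector of normalized mark values.
#' @return A list with `probability` and `fired`, a data frame of fired rules
#'   (index, rendered text, midpoint firing strength, dominance, consequent)
#'   sorted by firing strength descending.
#' @export
infer <- function(rulebase, features) {
  stopifnot(inherits(rulebase, "rule_base"))
  X <- matrix(as.numeric(features), nrow = 1,
              dimnames = list(NULL, names(features)))
  marks <- .rulebase_marks(rulebase)
  missing_marks <- setdiff(marks, colnames(X))
  if (length(missing_marks))
    .stopf("features lack mark(s) referenced by rules: %s",
           paste(missing_marks, collapse = ", "))
  firing <- .firing_matrix(rulebase$rules, X, rulebase$partitions)
  res <- .probability_from_firing(rulebase$rules, firing,
                                  rulebase$default_probability)
  strength <- res$midpoint[1, ]
  fired_idx <- which(strength > 0)
  ord <- fired_idx[order(-strength[fired_idx], fired_idx)]
  fired <- data.frame(
    rule = ord,
    text = vapply(rulebase$rules[ord], format, character(1)),
    firing = strength[ord],
    dominance = vapply(rulebase$rules[ord], `[[`, numeric(1), "dominance"),
    consequent = vapply(rulebase$rules[ord], `[[`, character(1), "consequent"),
    stringsAsFactors = FALSE
  )
  list(probability = res$probability[1], fired = fired)
}

#' Render a linguistic explanation of one inference
#'
#' Each fired rule is printed as `IF <mark> is <label> [AND ...] THEN <class>`
#' together with its firing strength, ordered by strength (ties broken by
#' rule index). When nothing fires, a note about the default class is
#' returned instead.
#'
#' @inheritParams infer
#' @return Character vector of report lines (zero fired rules gives a single
#'   default-class note).
#' @export
explain <- function(rulebase, features) {
  res <- infer(rulebase, features)
  if (!nrow(res$fired)) {
    return(sprintf(
      "No rule fired; default class '%s' with probability %.2f.",
      rulebase$default_class, rulebase$default_probability))
  }
  c(sprintf("Enhancer probability: %.3f", res$probability),
    sprintf("%s  (firing %.3f, dominance %.2f)",
            res$fired$text, res$fired$firing, res$fired$dominance))
}

# ---- serialization ----------------------------------------------------------

#' Write a rule base to JSON (plus optional human-readable rules text)
#'
#' @param rulebase A [rule_base()].
#' @param path Output JSON path.
#' @param txt_path Optional path for a plain-text rendering of the rules.
#' @return `path`, invisibly.
#' @export
write_rulebase <- function(rulebase, path, txt_path = NULL) {
  obj <- list(
    default_class = rulebase$default_class,
    default_probability = rulebase$default_probability,
    dominance_scale = if (!is.null(rulebase$dominance_scale))
      as.list(rulebase$dominance_scale) else NULL,
    partitions = lapply(rulebase$partitions, function(p) list(
      mark = p$mark, anchors = p$anchors, overlap = p$overlap, fou = p$fou,
      sets = lapply(p$sets, function(s) list(
        label = s$label, upper = s$upper, lower = s$lower, anchor = s$anchor))
    )),
    rules = lapply(rulebase$rules, function(r) list(
      marks = r$marks, labels = r$labels, consequent = r$consequent,
      dominance = r$dominance))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt_path)) {
    lines <- vapply(seq_along(rulebase$rules), function(i)
      sprintf("%3d. %s  [dominance %.2f]", i, format(rulebase$rules[[i]]),
              rulebase$rules[[i]]$dominance), character(1))
    writeLines(lines, txt_path)
  }
  invisible(path)
}

#' Read a rule base from JSON
#'
#' @param path JSON path written by [write_rulebase()].
#' @return A [rule_base()].
#' @export
read_rulebase <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  partitions <- lapply(obj$partitions, function(p) {
    part <- fuzzy_partition(p$mark, anchors = as.numeric(unlist(p$anchors)),
                            overlap = p$overlap, fou = p$fou)
    # restore exact stored breakpoints (jittered partitions need not match
    # the constructor geometry bit-for-bit)
    part$sets <- lapply(p$sets, function(s)
      fuzzy_set(s$label, upper = as.numeric(unlist(s$upper)),
                lower = as.numeric(unlist(s$lower)),
                anchor = as.numeric(s$anchor)))
    names(part$sets) <- vapply(part$sets, `[[`, character(1), "label")
    part
  })
  names(partitions) <- vapply(partitions, `[[`, character(1), "mark")
  rules <- lapply(obj$rules, function(r)
    fuzzy_rule(unlist(r$marks), unlist(r$labels), r$consequent, r$dominance))
  dscale <- if (is.null(obj$dominance_scale)) NULL else
    unlist(obj$dominance_scale)
  rule_base(rules, partitions, default_class = obj$default_class,
            default_probability = obj$default_probability,
            dominance_scale = dscale)
}
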