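#' @importFrom stats quantile rnorm runif rbinom rlnorm setNames
#' @importFrom utils head tail write.table read.table modifyList
NULL

.datatable.aware <- TRUE

# data.table columns used with non-standard evaluation
utils::globalVariables(c("bin", "w", "v", "val", "run", "chrom", "hot", "p",
                         "score", "start", "end"))

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stage-specific seed from a master seed, kept within 32-bit range.
.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587L)
}

# sample() semantics without the length-1 numeric surprise
.resample <- function(x, size, prob = NULL)
  x[sample.int(length(x), size, prob = prob)]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_fraction <- function(x, name) {
  if (!.is_scalar_number(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single number in [0, 1], got %s", name,
           paste(format(x), collapse = ", "))
  invisible(x)
}
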