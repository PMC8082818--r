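## Internal helpers: seed derivation, count-matrix coercion, input checks.

# Counter-based seed derivation: every randomized sub-task (subsample b,
# permutation b, gene j shuffle, ...) gets its own seed computed from the
# master seed, a purpose tag and a counter, so results are independent of
# execution order and worker scheduling. Kept strictly below 2^31.
.deriveSeed <- function(seed, purpose, counter = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(purpose) * 10000019 + as.numeric(counter) * 7919
  as.integer(s %% 2147483629) + 1L
}

.purpose <- c(subsample = 1L, permutation = 2L, shuffle = 3L,
              simulation = 4L, zeroinfl = 5L)

# Coerce supported inputs to the internal convention: a cells x genes
# matrix with dimnames. SingleCellExperiment / SummarizedExperiment store
# genes in rows and are transposed.
.coerceCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
    m <- t(as.matrix(m))
  } else if (is(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- as.matrix(x)
  } else {
    stop("unsupported counts container: ", class(x)[1])
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("gene", seq_len(ncol(m)))
  .checkCounts(m)
  m
}

.checkCounts <- function(m) {
  v <- if (is(m, "Matrix")) m@x else m
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(abs(v - round(v)) > 1e-8)) stop("counts must be integers")
  if (anyDuplicated(rownames(m))) stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate gene identifiers")
  invisible(TRUE)
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
      abs(x - round(x)) > 1e-8 || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(round(x))
}

.assertFraction <- function(x, name, open = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1)))
    stop(sprintf("'%s' must be a fraction in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"))
  as.numeric(x)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
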