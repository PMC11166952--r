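# Abundance and expression transforms used by both association stages.
# Microbial abundances are compositional and zero-heavy, so every log-based
# transform is preceded by a matrix-wide pseudocount equal to the smallest
# strictly positive entry of that matrix.

#' Add a matrix-wide pseudocount to a microbial abundance matrix
#'
#' Increments every entry by the smallest strictly positive value of the
#' matrix, so that a subsequent log or centered-log-ratio transform is
#' defined everywhere. The pseudocount is a property of the whole matrix,
#' not of individual features or samples.
#'
#' @param m Non-negative numeric matrix (features x samples).
#' @return The matrix with the pseudocount added; all entries are strictly
#'   positive. Attributes (domain, rank, ...) are preserved.
#' @examples
#' add_pseudocount(matrix(c(0, 2, 1, 4), 2)) # pseudocount is 1
#' @export
add_pseudocount <- function(m) {
  m <- as_abundance_matrix(m)
  pos <- m[m > 0]
  if (length(pos) == 0L) {
    stop("degenerate matrix: all entries are zero, no pseudocount can be defined")
  }
  m + min(pos)
}

#' Elementwise natural-log transform
#'
#' @param m Strictly positive numeric matrix, typically the output of
#'   [add_pseudocount()].
#' @return `log(m)`, attributes preserved.
#' @export
log_transform <- function(m) {
  m <- as_abundance_matrix(m, allow_zero = FALSE)
  out <- log(m)
  out
}

#' Centered-log-ratio transform
#'
#' Per sample (column), each entry becomes `log(x) - mean(log(x))` over the
#' features of that sample, the standard compositional-data convention.
#' Every output column sums to zero.
#'
#' @param m Strictly positive numeric matrix (features x samples).
#' @return CLR-transformed matrix; attributes preserved. A single-feature
#'   matrix degenerates to all zeros and triggers a warning.
#' @export
clr_transform <- function(m) {
  m <- as_abundance_matrix(m, allow_zero = FALSE)
  if (nrow(m) == 1L) {
    warning("CLR of a single-feature matrix is identically zero")
  }
  lg <- log(m)
  out <- sweep(lg, 2L, colMeans(lg), "-")
  keep <- attributes(m)
  keep$dim <- NULL
  keep$dimnames <- NULL
  for (a in names(keep)) attr(out, a) <- keep[[a]]
  out
}

#' Center and scale a gene's expression values
#'
#' Subtracts the mean and divides by the unbiased (n-1) sample standard
#' deviation, the convention used before both regression stages. Idempotent
#' up to floating-point tolerance.
#'
#' @param v Numeric vector of length >= 2 with nonzero variance.
#' @return Vector with mean 0 and sample SD 1.
#' @export
center_scale <- function(v) {
  if (!is.numeric(v) || length(v) < 2L) {
    stop("center_scale() needs a numeric vector with at least 2 values")
  }
  if (anyNA(v)) stop("center_scale() does not accept missing values")
  s <- stats::sd(v)
  if (s == 0) {
    stop("constant gene: zero variance, cannot be centered and scaled")
  }
  out <- (v - mean(v)) / s
  names(out) <- names(v)
  out
}

#' Apply the full microbial transform used by the association stages
#'
#' Convenience composition of [add_pseudocount()] with either
#' [log_transform()] or [clr_transform()]. The transform name is recorded as
#' an attribute so downstream results can be tagged with their provenance.
#'
#' @param m Non-negative abundance matrix (features x samples).
#' @param transform `"log"` or `"clr"`.
#' @return Transformed matrix with attribute `transform` set.
#' @export
transform_microbes <- function(m, transform = c("log", "clr")) {
  transform <- match.arg(transform)
  out <- switch(transform,
    log = log_transform(add_pseudocount(m)),
    clr = clr_transform(add_pseudocount(m))
  )
  attr(out, "transform") <- transform
  out
}

# Shared validation for abundance matrices.
as_abundance_matrix <- function(m, allow_zero = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a numeric matrix of abundances")
  }
  if (anyNA(m)) stop("abundance matrix contains missing values")
  if (allow_zero) {
    if (any(m < 0)) stop("abundance matrix contains negative values")
  } else if (any(m <= 0)) {
    stop("domain error: matrix has non-positive entries; apply add_pseudocount() first")
  }
  m
}
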