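# Interval algebra on 0-based half-open intervals, backed by IRanges.
#
# Intervals are integer matrices with columns (start, end), start < end,
# 0-based half-open (BED convention). All exported interval operations accept
# and return this representation; conversion to the 1-based closed IRanges
# representation is internal.

as_interval_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  if (is.data.frame(x)) x <- as.matrix(x[, c("start", "end")])
  if (!is.matrix(x)) x <- matrix(x, ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "integer"
  colnames(x) <- c("start", "end")
  if (any(x[, 1L] >= x[, 2L]))
    stop("invalid interval: start must be < end (0-based half-open)", call. = FALSE)
  if (any(x[, 1L] < 0L)) stop("negative interval start", call. = FALSE)
  x
}

ir_from_half_open <- function(m) {
  m <- as_interval_matrix(m)
  IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L])
}

half_open_from_ir <- function(ir) {
  m <- cbind(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
  storage.mode(m) <- "integer"
  m
}

#' Merge a set of intervals into disjoint sorted intervals
#'
#' Computes the union of a set of 0-based half-open intervals. Abutting
#' intervals (`end == start` of the next) are merged, matching half-open set
#' semantics.
#'
#' @param x interval matrix (columns `start`, `end`), data frame with those
#'   columns, or a vector coercible to one; may be empty.
#' @return integer matrix of disjoint intervals sorted by start.
#' @export
#' @examples
#' merge_intervals(rbind(c(0, 10), c(5, 15), c(20, 30)))
merge_intervals <- function(x) {
  half_open_from_ir(IRanges::reduce(ir_from_half_open(x)))
}

#' Subtract one interval set from another
#'
#' Returns the bases of `a` not covered by `b`, as disjoint sorted 0-based
#' half-open intervals (the `subtractBed` operation).
#'
#' @param a,b interval matrices (columns `start`, `end`); `b` may be empty.
#' @return integer matrix of disjoint intervals sorted by start.
#' @export
#' @examples
#' subtract_intervals(rbind(c(0, 100)), rbind(c(40, 60)))
subtract_intervals <- function(a, b) {
  half_open_from_ir(IRanges::setdiff(ir_from_half_open(a), ir_from_half_open(b)))
}

# Intersection of two interval sets (internal; used by conservation averaging).
intersect_intervals <- function(a, b) {
  half_open_from_ir(IRanges::intersect(ir_from_half_open(a), ir_from_half_open(b)))
}

# Total number of bases covered by an interval set (after union).
interval_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) return(0L)
  sum(m[, 2L] - m[, 1L])
}
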