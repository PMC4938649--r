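#' Signed deletion/duplication size at a rearrangement junction
#'
#' A rearrangement cut is described on the reference by two 1-based
#' coordinates: `five_prime`, the last retained base on the 5' side of the
#' cut, and `three_prime`, the first retained base on the 3' side. When the
#' two retained bases are not adjacent in the reference, bases between them
#' were lost (a deletion, negative delta); when `three_prime` lies at or
#' before `five_prime`, the overlapping bases appear on both sides of the
#' junction in the derived chromosome (a duplication, positive delta).
#' Adjacent coordinates (`three_prime == five_prime + 1`) give a clean join
#' with delta 0.
#'
#' Equivalently, `delta` is the length change of a toy chromosome in which
#' the prefix ending at `five_prime` is joined to the suffix starting at
#' `three_prime`.
#'
#' @param five_prime 1-based reference coordinate of the last retained base
#'   on the 5' side of the junction. Vectorised.
#' @param three_prime 1-based reference coordinate of the first retained
#'   base on the 3' side. Vectorised.
#' @return Integer vector of signed base-pair deltas: negative = deletion,
#'   positive = duplication, zero = clean join.
#' @examples
#' junction_delta(6925034, 6926125)   # -1090 (1090 bases lost)
#' junction_delta(16383781, 16383775) # +7 (7 bases doubled)
#' junction_delta(23050763, 23050764) # 0 (clean join)
#' @export
junction_delta <- function(five_prime, three_prime) {
  five_prime <- as.numeric(five_prime)
  three_prime <- as.numeric(three_prime)
  if (any(!is.finite(five_prime)) || any(!is.finite(three_prime)) ||
      any(five_prime < 1) || any(three_prime < 1)) {
    stop("invalid coordinate: junction coordinates must be positive (1-based)")
  }
  delta <- ifelse(three_prime > five_prime,
                  -(three_prime - five_prime - 1),
                  five_prime - three_prime + 1)
  as.integer(delta)
}

#' Interval span in megabases, rounded half-up
#'
#' Computes `(right - left) / 1e6` and rounds half-up to `decimals` places,
#' the convention used when quoting inverted-segment and crossover-tract
#' sizes (e.g. a tract at 9,216,999-10,625,261 spans 1.4 Mb).
#'
#' @param left,right 1-based coordinates with `right >= left`. Vectorised.
#' @param decimals Number of decimal places (default 1).
#' @return Numeric vector of spans in Mb.
#' @export
span_mb <- function(left, right, decimals = 1L) {
  if (any(right < left)) stop("invalid interval: right < left")
  x <- (right - left) / 1e6
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Published balancer breakpoint coordinates
#'
#' The molecularly resolved inversion breakpoints of the third-chromosome
#' balancers TM3, TM6 and TM6B (dm6 coordinates): one row per cut with the
#' 5' and 3' retained-base coordinates, the signed junction delta, and the
#' affected gene or region. The two In(3R)C cuts shared by all three
#' balancers were never localised and are not included.
#'
#' @return A data.frame with columns `balancer`, `inversion`, `chrom`,
#'   `bands`, `five_prime`, `three_prime`, `delta`, `affected`.
#' @export
balancer_breakpoints <- function() {
  path <- system.file("extdata", "balancer_breakpoints.tsv",
                      package = "balancerseq", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published small lesions carried by third-chromosome balancers
#'
#' Characterised point lesions and small deletions (dm6 coordinates) carried
#' by TM3, TM6 and TM6B, used for reading-frame classification of deletions
#' overlapping coding sequence.
#'
#' @return A data.frame with columns `gene`, `allele`, `balancer`, `chrom`,
#'   `start`, `end`, `type`.
#' @export
balancer_lesions <- function() {
  path <- system.file("extdata", "balancer_lesions.tsv",
                      package = "balancerseq", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
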