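#' Call crossover tracts from the rare-SNP window matrix
#'
#' Per stock, maximal runs of windows containing at least one rare SNP
#' (allowing up to `max_gap` empty windows inside a run) with at least
#' `min_windows` signal windows become tracts. Tract boundaries are refined
#' to the outermost rare SNPs in the run, and each boundary carries a
#' confidence interval extending to the nearest flanking shared-by-all SNP
#' present in that stock (or the chromosome end): the true exchange point
#' lies between the last allele of one haplotype and the first allele of
#' the other.
#'
#' Tracts are typed against the breakpoint list: *SCO* if the tract lies
#' wholly distal to the distal-most breakpoint (toward coordinate 1, the
#' telomere of the poorly balanced arm) or reaches a chromosome end outside
#' the breakpoint span; *DCO* if it lies strictly between two consecutive
#' breakpoints (inside one inverted segment); otherwise *unclassified*.
#' With no breakpoints supplied all tracts are *unclassified*. The distance
#' from each boundary to the nearest breakpoint is reported, along with
#' rounded-Mb display columns (exact coordinates remain the primary
#' output).
#'
#' The run-calling rule (min_windows, max_gap, boundary refinement) is this
#' package's formalisation of the heatmap-based tract reading; it is
#' recorded in the output attributes.
#'
#' @param wm A `window_matrix` from [rare_snp_windows()].
#' @param panel The `panel_matrix` the window matrix came from.
#' @param breakpoints Integer vector of breakpoint coordinates (e.g. from
#'   [call_breakpoints()] junctions or a karyotype), or `NULL`.
#' @param min_windows Minimum signal windows per tract (default 3).
#' @param max_gap Maximum empty windows bridged within a run (default 2).
#' @return A data.frame, one row per tract: `stock, chrom, start, end,
#'   type, n_rare_snps, ci_start_lo, ci_start_hi, ci_end_lo, ci_end_hi,
#'   dist_start_bp, dist_end_bp, start_mb, end_mb`.
#' @export
call_tracts <- function(wm, panel, breakpoints = NULL, min_windows = 3L,
                        max_gap = 2L) {
  stopifnot(inherits(wm, "window_matrix"), inherits(panel, "panel_matrix"))
  bp <- sort(unique(as.integer(breakpoints)))
  L <- wm$chrom_length
  rare <- panel$k <= wm$max_share
  shared <- panel$k == length(panel$stocks)
  out <- list()
  for (j in seq_along(panel$stocks)) {
    sig <- which(wm$counts[, j] > 0L)
    if (!length(sig)) next
    # group signal windows into runs allowing max_gap empty windows
    run_id <- cumsum(c(1L, diff(sig) > max_gap + 1L))
    for (r in unique(run_id)) {
      idx <- sig[run_id == r]
      if (length(idx) < min_windows) next
      span_lo <- wm$start[idx[1]]
      span_hi <- wm$end[idx[length(idx)]]
      mine <- panel$presence[, j] & rare &
        panel$snps$pos >= span_lo & panel$snps$pos <= span_hi
      pos <- panel$snps$pos[mine]
      if (!length(pos)) next
      tstart <- min(pos); tend <- max(pos)
      anchors <- panel$snps$pos[panel$presence[, j] & shared]
      lo_anchor <- anchors[anchors < tstart]
      hi_anchor <- anchors[anchors > tend]
      ci_start_lo <- if (length(lo_anchor)) max(lo_anchor) else 1L
      ci_end_hi <- if (length(hi_anchor)) min(hi_anchor) else L
      type <- "unclassified"
      if (length(bp)) {
        if (tend < bp[1]) type <- "SCO"
        else if (tstart > bp[length(bp)]) type <- "SCO"
        else {
          between <- findInterval(tstart, bp)
          if (between >= 1 && between < length(bp) &&
              tstart > bp[between] && tend < bp[between + 1L]) {
            type <- "DCO"
          }
        }
      }
      dist_bp <- function(x) if (length(bp)) min(abs(x - bp)) else NA_integer_
      out[[length(out) + 1L]] <- data.frame(
        stock = panel$stocks[j], chrom = wm$chrom,
        start = tstart, end = tend, type = type,
        n_rare_snps = length(pos),
        ci_start_lo = ci_start_lo, ci_start_hi = tstart,
        ci_end_lo = tend, ci_end_hi = ci_end_hi,
        dist_start_bp = dist_bp(tstart), dist_end_bp = dist_bp(tend),
        start_mb = span_mb(0, tstart, 1), end_mb = span_mb(0, tend, 1),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    stock = character(), chrom = character(), start = integer(),
    end = integer(), type = character(), n_rare_snps = integer(),
    ci_start_lo = integer(), ci_start_hi = integer(), ci_end_lo = integer(),
    ci_end_hi = integer(), dist_start_bp = integer(),
    dist_end_bp = integer(), start_mb = numeric(), end_mb = numeric(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "calling_rule") <- list(min_windows = as.integer(min_windows),
                                    max_gap = as.integer(max_gap),
                                    max_share = wm$max_share,
                                    window = wm$window)
  res
}

#' Stock-pair relatedness from overlapping tracts
#'
#' For each pair of overlapping tracts from different stocks, reports the
#' reciprocal overlap fraction and the genotype identity of the rare SNPs
#' inside the overlap (Jaccard over (pos, alt) keys). Pairs exceeding both
#' thresholds are flagged as likely sharing a common origin — the signature
#' of related stocks that inherited the same exchange event.
#'
#' @param tracts Output of [call_tracts()].
#' @param panel The `panel_matrix`.
#' @param min_overlap_frac Minimum reciprocal overlap fraction (default
#'   0.5).
#' @param min_identity Minimum rare-SNP identity fraction (default 0.9).
#' @param max_share Rare-SNP sharing threshold (default: the one recorded
#'   in `tracts`).
#' @return A data.frame: `stock_a, stock_b, start, end` (of the overlap),
#'   `overlap_frac, identity, likely_common_origin`.
#' @export
shared_tracts <- function(tracts, panel, min_overlap_frac = 0.5,
                          min_identity = 0.9, max_share = NULL) {
  if (is.null(max_share)) {
    max_share <- attr(tracts, "calling_rule")$max_share %||%
      length(panel$stocks)
  }
  rare <- panel$k <= max_share
  res <- list()
  if (nrow(tracts) >= 2) {
    for (a in seq_len(nrow(tracts) - 1L)) {
      for (b in seq(a + 1L, nrow(tracts))) {
        if (tracts$stock[a] == tracts$stock[b]) next
        lo <- max(tracts$start[a], tracts$start[b])
        hi <- min(tracts$end[a], tracts$end[b])
        if (lo > hi) next
        ov <- hi - lo + 1L
        frac <- min(ov / (tracts$end[a] - tracts$start[a] + 1L),
                    ov / (tracts$end[b] - tracts$start[b] + 1L))
        in_ov <- rare & panel$snps$pos >= lo & panel$snps$pos <= hi
        ka <- which(in_ov & panel$presence[, tracts$stock[a]])
        kb <- which(in_ov & panel$presence[, tracts$stock[b]])
        ident <- if (length(ka) + length(kb) == 0) NA_real_ else
          length(intersect(ka, kb)) / length(union(ka, kb))
        res[[length(res) + 1L]] <- data.frame(
          stock_a = tracts$stock[a], stock_b = tracts$stock[b],
          start = lo, end = hi, overlap_frac = frac, identity = ident,
          likely_common_origin = !is.na(ident) &&
            frac >= min_overlap_frac && ident >= min_identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res) else data.frame(
    stock_a = character(), stock_b = character(), start = integer(),
    end = integer(), overlap_frac = numeric(), identity = numeric(),
    likely_common_origin = logical(), stringsAsFactors = FALSE)
}

#' Write called tracts as TSV
#' @param tracts Output of [call_tracts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
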