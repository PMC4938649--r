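#' Build a SNP-by-stock panel matrix from per-stock VCFs
#'
#' Loads one heterozygous VCF per stock, applies the panel filters — records
#' with QUAL below `qual_min` are removed (a record at exactly `qual_min`
#' is kept), indels are dropped entirely — and assembles a presence matrix
#' over the union of passing sites. A SNP is "present" in a stock iff that
#' stock has a passing record at the same position with the same alternate
#' allele; because stocks are sequenced as balancer/reference heterozygotes,
#' every heterozygous SNP is treated as a SNP on the balancer chromosome.
#'
#' @param vcf_paths Named character vector of VCF paths (>= 2); names are
#'   the stock ids (file base names otherwise).
#' @param qual_min QUAL threshold; records with `QUAL < qual_min` are
#'   filtered out (default 200).
#' @param drop_indels Drop records whose REF or ALT is longer than 1 bp
#'   (default TRUE).
#' @return A `panel_matrix`: list with `snps` (data.frame chrom/pos/ref/alt),
#'   `presence` (logical SNP x stock matrix), `stocks`, and `k` (per-SNP
#'   sharing counts).
#' @export
load_panel <- function(vcf_paths, qual_min = 200, drop_indels = TRUE) {
  if (length(vcf_paths) < 2) stop("load_panel needs >= 2 stock VCFs")
  ids <- names(vcf_paths) %||% tools::file_path_sans_ext(basename(vcf_paths))
  if (is.null(names(vcf_paths))) names(vcf_paths) <- ids

  per_stock <- lapply(seq_along(vcf_paths), function(i) {
    v <- tryCatch(vcfR::read.vcfR(vcf_paths[i], verbose = FALSE),
                  error = function(e) stop("malformed VCF ", vcf_paths[i],
                                           ": ", conditionMessage(e)))
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (!nrow(fix)) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE))
    }
    qual <- suppressWarnings(as.numeric(fix$QUAL))
    keep <- !is.na(qual) & qual >= qual_min
    # heterozygous-SNP-as-balancer convention: keep het genotypes when a
    # genotype column exists
    if (ncol(v@gt) >= 2) {
      gt <- vcfR::extract.gt(v, element = "GT")[, 1]
      keep <- keep & grepl("0", gt) & grepl("1", gt)
    }
    fix <- fix[keep, , drop = FALSE]
    # split multi-allelic records into one row per alternate allele
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    n <- lengths(alts)
    out <- data.frame(chrom = rep(fix$CHROM, n),
                      pos = rep(as.integer(fix$POS), n),
                      ref = rep(fix$REF, n), alt = unlist(alts),
                      stringsAsFactors = FALSE)
    if (drop_indels) {
      out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L, , drop = FALSE]
    }
    out
  })

  all <- unique(do.call(rbind, per_stock))
  all <- all[order(all$chrom, all$pos, all$alt), , drop = FALSE]
  rownames(all) <- NULL
  if (!nrow(all)) warning("empty panel: zero passing sites")
  key <- function(d) paste(d$chrom, d$pos, d$alt, sep = ":")
  presence <- matrix(FALSE, nrow(all), length(per_stock),
                     dimnames = list(NULL, ids))
  for (i in seq_along(per_stock)) {
    presence[key(all) %in% key(per_stock[[i]]), i] <- TRUE
  }
  structure(list(snps = all, presence = presence, stocks = ids,
                 k = as.integer(rowSums(presence))),
            class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat("panel_matrix:", nrow(x$snps), "SNPs x", length(x$stocks), "stocks\n")
  if (length(x$k)) {
    cat("  unique (k=1):", sum(x$k == 1L),
        " shared-by-all:", sum(x$k == length(x$stocks)), "\n")
  }
  invisible(x)
}

#' Per-SNP sharing counts
#'
#' The number of stocks carrying each SNP. A SNP observed in only one stock
#' is a "unique polymorphism"; one carried by every stock is shared-by-all.
#'
#' @param panel A `panel_matrix`.
#' @return A data.frame: `chrom, pos, alt, k, label` where `label` is
#'   `"unique"`, `"shared-by-all"`, or `"shared"`.
#' @export
share_counts <- function(panel) {
  stopifnot(inherits(panel, "panel_matrix"))
  n <- length(panel$stocks)
  data.frame(panel$snps[, c("chrom", "pos", "alt")], k = panel$k,
             label = ifelse(panel$k == 1L, "unique",
                            ifelse(panel$k == n, "shared-by-all", "shared")),
             stringsAsFactors = FALSE)
}

#' Rare-SNP counts in fixed windows (heatmap matrix)
#'
#' Counts, per stock and fixed window, the SNPs shared by at most
#' `max_share` stocks — the plotting rule behind the crossover heatmaps
#' ("SNPs in 10-kb windows if present in five or fewer stocks"). For
#' 3-stock panels the alternative any-SNP-not-shared-by-all rule is
#' `max_share = n_stocks - 1`.
#'
#' @param panel A `panel_matrix`.
#' @param max_share Maximum sharing count for a SNP to be counted
#'   (default 5).
#' @param window Window size in bp (default 10,000); windows tile from
#'   position 1 in the reference frame.
#' @param chrom_length Optional chromosome length (otherwise the last
#'   window is the one containing the last SNP).
#' @param exclude Optional intervals to exclude (BED path, GRanges or
#'   data.frame with start/end), e.g. centromere-proximal heterochromatin;
#'   windows overlapping an excluded interval are dropped.
#' @return A `window_matrix`: list with `counts` (window x stock matrix),
#'   `start`/`end` (window coordinates), `window`, `max_share`.
#' @export
rare_snp_windows <- function(panel, max_share = 5L, window = 10000L,
                             chrom_length = NULL, exclude = NULL) {
  stopifnot(inherits(panel, "panel_matrix"))
  window <- as.integer(window)
  if (is.null(chrom_length)) {
    chrom_length <- if (nrow(panel$snps)) max(panel$snps$pos) else window
  }
  n_win <- as.integer((chrom_length - 1L) %/% window + 1L)
  start <- (seq_len(n_win) - 1L) * window + 1L
  rare <- panel$k <= max_share
  widx <- (panel$snps$pos - 1L) %/% window + 1L
  counts <- vapply(seq_along(panel$stocks), function(j) {
    sel <- rare & panel$presence[, j]
    tabulate(widx[sel], nbins = n_win)
  }, integer(n_win))
  counts <- matrix(counts, nrow = n_win,
                   dimnames = list(NULL, panel$stocks))
  keep <- rep(TRUE, n_win)
  if (!is.null(exclude)) {
    iv <- mask_intervals(exclude)
    keep <- !IRanges::overlapsAny(
      IRanges::IRanges(start, start + window - 1L),
      IRanges::IRanges(iv$start, iv$end))
  }
  structure(list(counts = counts[keep, , drop = FALSE],
                 start = start[keep], end = pmin(start + window - 1L,
                                                 chrom_length)[keep],
                 window = window, max_share = as.integer(max_share),
                 chrom = if (nrow(panel$snps)) panel$snps$chrom[1] else "chr",
                 chrom_length = as.integer(chrom_length)),
            class = "window_matrix")
}

#' @export
print.window_matrix <- function(x, ...) {
  cat("window_matrix:", nrow(x$counts), "windows of", x$window, "bp x",
      ncol(x$counts), "stocks (max_share", x$max_share, ")\n")
  invisible(x)
}

#' Write the heatmap matrix as TSV
#'
#' One row per window (`chrom`, `start`, `end`), one column per stock: the
#' plotting-ready heatmap matrix.
#'
#' @param wm A `window_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_matrix <- function(wm, path) {
  out <- data.frame(chrom = wm$chrom, start = wm$start, end = wm$end,
                    wm$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
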