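#' Random reference chromosome sequence
#'
#' @param ref_length Length in bp (>= 1000).
#' @param seed RNG seed; the same seed reproduces the same sequence.
#' @return A [Biostrings::DNAString] of uppercase A/C/G/T, uniform base
#'   composition.
#' @export
make_reference <- function(ref_length, seed = 1L) {
  ref_length <- as.integer(ref_length)
  if (ref_length < 1000) stop("ref_length must be >= 1 kb")
  with_seed(seed, {
    Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), ref_length,
                                       replace = TRUE), collapse = ""))
  })
}

# deterministic SNP set for one haplotype over [lo, hi]:
# positions Bernoulli(density), alt drawn uniformly from the non-ref bases
haplotype_snps <- function(refseq, lo, hi, density, seed) {
  with_seed(seed, {
    n <- stats::rbinom(1L, hi - lo + 1L, density)
    if (n == 0) {
      return(data.frame(pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    }
    pos <- sort(sample.int(hi - lo + 1L, n)) + lo - 1L
    refb <- as.character(Biostrings::extractAt(refseq,
                                               IRanges::IRanges(pos, pos)))
    alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    data.frame(pos = pos, ref = refb, alt = alt, stringsAsFactors = FALSE)
  })
}

#' Simulate a balancer stock panel with crossover history
#'
#' Builds the ancestral balancer haplotype (karyotype + lineage SNPs), then
#' derives each stock from it. A stock may receive a single crossover (SCO)
#' at a uniform position distal to the distal-most breakpoint — replacing
#' the balancer's distal tip, and hence its SNPs, with a normal-sequence
#' donor homolog carrying its own SNPs — and/or double crossovers (DCOs)
#' that swap an internal interval of an inverted segment for donor sequence.
#' Every event is recorded in the returned truth set.
#'
#' Because stocks are "sequenced" against the reference strain itself, every
#' SNP a stock carries is heterozygous and attributable to the balancer (or
#' to donor sequence acquired by crossover): the heterozygous-SNP-as-
#' balancer convention.
#'
#' @param config A [sim_config()].
#' @param refseq Optional pre-built reference ([make_reference()] is called
#'   otherwise).
#' @return A list with elements `reference` (DNAString), `map`
#'   ([balancer_map()]), `stocks` (named list of per-stock SNP data.frames
#'   with columns pos/ref/alt/origin), and `truth`
#'   (`junctions`, `tracts`, `breakpoints`, `sco_points`).
#' @export
derive_panel <- function(config, refseq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(refseq)) refseq <- make_reference(config$ref_length, config$seed)
  map <- apply_karyotype(balancer_map(config$chrom, config$ref_length),
                         config$karyotype)
  jx <- junction_table(map)
  breakpoints <- sort(unique(c(jx$five_prime, jx$three_prime)))
  # with no rearrangements the whole chromosome is "distal"
  bp_min <- if (length(breakpoints)) min(breakpoints) else config$ref_length

  # inverted segments in the reference frame, for DCO validation
  inv <- map$segments[map$segments$strand == "-", , drop = FALSE]
  for (spec in config$dco_specs) {
    iv <- spec$interval
    inside <- any(iv[1] >= inv$ref_start & iv[2] <= inv$ref_end)
    if (!inside) {
      stop("invalid config: DCO interval [", iv[1], ", ", iv[2],
           "] is not inside an inverted segment")
    }
  }

  stocks_ids <- sprintf("s%02d", seq_len(config$n_stocks))
  ancestral <- haplotype_snps(refseq, 1L, config$ref_length,
                              config$snp_density, config$seed + 1L)
  ancestral$origin <- "balancer"

  # which stocks carry an SCO, and where
  sco <- if (!is.null(config$sco_stocks)) {
    seq_len(config$n_stocks) %in% config$sco_stocks
  } else {
    with_seed(config$seed + 2L,
              stats::runif(config$n_stocks) < config$sco_rate)
  }
  hi <- bp_min - config$sco_exclusion - 1L
  if (any(sco) && hi < 1) stop("invalid config: no room for SCOs distal to ",
                               bp_min, " with exclusion ", config$sco_exclusion)
  sco_points <- with_seed(config$seed + 3L, {
    pts <- rep(NA_integer_, config$n_stocks)
    pts[sco] <- sample.int(hi, sum(sco), replace = TRUE)
    pts
  })
  if (!is.null(config$sco_points)) {
    stopifnot(!is.null(config$sco_stocks),
              length(config$sco_points) == length(config$sco_stocks))
    if (any(config$sco_points > hi)) {
      stop("invalid config: explicit crossover point beyond the distal region")
    }
    sco_points[config$sco_stocks] <- as.integer(config$sco_points)
  }

  # donor haplotype cache so a shared donor label yields identical alleles
  donor_cache <- new.env(parent = emptyenv())
  donor_snps <- function(donor, lo, hi) {
    key <- donor
    if (!exists(key, envir = donor_cache)) {
      dseed <- config$seed + 7919L +
        sum(utf8ToInt(donor) * seq_along(utf8ToInt(donor)))
      assign(key, haplotype_snps(refseq, 1L, config$ref_length,
                                 config$donor_snp_density, dseed %% 2147483647L),
             envir = donor_cache)
    }
    d <- get(key, envir = donor_cache)
    d <- d[d$pos >= lo & d$pos <= hi, , drop = FALSE]
    if (nrow(d)) d$origin <- paste0("donor:", donor)
    d
  }

  tracts <- list()
  stocks <- stats::setNames(vector("list", config$n_stocks), stocks_ids)
  for (i in seq_len(config$n_stocks)) {
    snps <- ancestral
    if (sco[i]) {
      x <- sco_points[i]
      donor <- paste0("sco_", stocks_ids[i])
      snps <- snps[snps$pos > x, , drop = FALSE]
      snps <- rbind(donor_snps(donor, 1L, x), snps)
      tracts[[length(tracts) + 1L]] <-
        data.frame(stock = stocks_ids[i], start = 1L, end = x,
                   type = "SCO", donor = donor, stringsAsFactors = FALSE)
    }
    for (spec in config$dco_specs) {
      if (!(i %in% spec$stocks)) next
      iv <- as.integer(spec$interval)
      donor <- spec$donor %||% paste0("dco_", stocks_ids[i])
      snps <- snps[snps$pos < iv[1] | snps$pos > iv[2], , drop = FALSE]
      snps <- rbind(snps, donor_snps(donor, iv[1], iv[2]))
      tracts[[length(tracts) + 1L]] <-
        data.frame(stock = stocks_ids[i], start = iv[1], end = iv[2],
                   type = "DCO", donor = donor, stringsAsFactors = FALSE)
    }
    snps <- snps[order(snps$pos), , drop = FALSE]
    rownames(snps) <- NULL
    stocks[[i]] <- snps
  }

  truth_tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(stock = character(), start = integer(), end = integer(),
               type = character(), donor = character(), stringsAsFactors = FALSE)
  list(reference = refseq, map = map, stocks = stocks,
       truth = list(junctions = jx, tracts = truth_tracts,
                    breakpoints = breakpoints, sco_points = sco_points))
}

#' Write a per-stock heterozygous VCF
#'
#' Emits the stock's SNPs as heterozygous (balancer/reference) records with
#' QUAL drawn from the configured log-normal model, interleaving indel
#' records at `indel_fraction` (these exist to exercise the downstream
#' drop-indels filter, not as detectable events). The output is sorted,
#' plain-text VCF 4.2.
#'
#' @param snps Per-stock SNP data.frame (`pos`, `ref`, `alt`) as produced by
#'   [derive_panel()].
#' @param path Output file path.
#' @param config A [sim_config()] (supplies chrom, QUAL model,
#'   indel_fraction).
#' @param refseq Reference sequence, needed to spell indel REF alleles.
#' @param stock Stock id written into the sample column.
#' @param seed RNG seed for QUAL values and indel placement.
#' @return `path`, invisibly.
#' @export
emit_stock_vcf <- function(snps, path, config, refseq, stock = "s01",
                           seed = config$seed) {
  with_seed(seed, {
    n_snv <- nrow(snps)
    n_indel <- round(config$indel_fraction / max(1 - config$indel_fraction, 1e-9)
                     * n_snv)
    rec <- data.frame(pos = snps$pos, ref = snps$ref, alt = snps$alt,
                      stringsAsFactors = FALSE)
    if (n_indel > 0) {
      ipos <- sort(sample.int(config$ref_length - 6L, n_indel))
      iref <- as.character(Biostrings::extractAt(
        refseq, IRanges::IRanges(ipos, ipos + 3L)))
      # deletions: REF is 4 bp, ALT its first base
      rec <- rbind(rec, data.frame(pos = ipos, ref = iref,
                                   alt = substr(iref, 1, 1),
                                   stringsAsFactors = FALSE))
    }
    rec <- rec[order(rec$pos, rec$alt), , drop = FALSE]
    qual <- stats::rlnorm(nrow(rec), config$qual_meanlog, config$qual_sdlog)
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=balancerseq-simulator",
      sprintf("##contig=<ID=%s,length=%d>", config$chrom, config$ref_length),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", stock)
    )
    if (nrow(rec)) {
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\t.\tGT\t0/1",
                                config$chrom, rec$pos, rec$ref, rec$alt, qual))
    }
    writeLines(lines, path)
  })
  invisible(path)
}

#' Write VCFs for every stock of a panel
#'
#' @param panel Result of [derive_panel()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used to build the panel.
#' @return Named character vector of VCF paths.
#' @export
panel_vcfs <- function(panel, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(panel$stocks)
  paths <- stats::setNames(file.path(dir, paste0(ids, ".vcf")), ids)
  for (i in seq_along(ids)) {
    emit_stock_vcf(panel$stocks[[i]], paths[i], config, panel$reference,
                   stock = ids[i], seed = config$seed + 100L + i)
  }
  paths
}
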