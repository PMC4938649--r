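#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the sequencing design the analysis is built for: a multiply inverted
#' chromosome carried over a reference-strain homolog, balancer-lineage SNPs
#' at ~6.2 per kb (the density implied by ~43,000 informative SNPs over a
#' 6.9-Mb interval), an 18-stock panel, 150-bp paired-end reads from ~600-bp
#' fragments plus a large-insert (2-12 kb) mate-pair library, and per-stock
#' heterozygous variant calls with a QUAL field spanning the 200 filter
#' threshold.
#'
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical outputs.
#' @param chrom Simulated chromosome name.
#' @param ref_length Reference length in bp.
#' @param karyotype List of [rearrangement()] objects applied in order, or
#'   `NULL` for the bundled default karyotype (one 2-cut inversion and one
#'   3-cut rearrangement; see [default_karyotype()]).
#' @param snp_density Balancer-lineage SNPs per bp (default 0.0062).
#' @param donor_snp_density SNP density of normal-sequence donor homologs
#'   relative to the reference (default: same as `snp_density`).
#' @param n_stocks Panel size.
#' @param sco_rate Probability that a stock carries a single crossover
#'   distal to the distal-most breakpoint (ignored when `sco_stocks` set).
#' @param sco_stocks Optional explicit vector of stock indices carrying
#'   single crossovers.
#' @param sco_points Optional explicit crossover points (bp), parallel to
#'   `sco_stocks`; by default points are drawn uniformly over the distal
#'   region.
#' @param sco_exclusion Minimum distance (bp) between a crossover point and
#'   the distal-most breakpoint (default 0; 2e6 mimics the observed 2-Mb
#'   buffer).
#' @param dco_specs List of double-crossover specs, each
#'   `list(stocks =, interval = c(a, b), donor = NULL)`; `interval` must lie
#'   inside an inverted segment. A shared `donor` label gives the listed
#'   stocks identical donor alleles (a common-origin event).
#' @param read_length Read length in bp.
#' @param pe_insert_mean,pe_insert_sd Paired-end fragment length (bp).
#' @param mp_insert_range Mate-pair fragment length range (bp).
#' @param mp_orientation Orientation convention of the mate-pair library
#'   after processing, `"fr"` or `"rf"`; a library parameter, not an
#'   assertion about any particular protocol.
#' @param coverage Fold sequence coverage per library.
#' @param base_error Per-base substitution error rate.
#' @param qual_meanlog,qual_sdlog Log-normal model for VCF QUAL scores. The
#'   defaults describe deep-coverage heterozygous SNV calls: most records
#'   far above the 200 filter threshold with a small (~0.3%) low-quality
#'   tail, so the filter is exercised without making call dropout a
#'   dominant noise source.
#' @param indel_fraction Fraction of emitted variant records that are
#'   indels (present only to exercise the drop-indels filter).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chrS",
                       ref_length = 5e6,
                       karyotype = NULL,
                       snp_density = 0.0062,
                       donor_snp_density = snp_density,
                       n_stocks = 18L,
                       sco_rate = 11 / 18,
                       sco_stocks = NULL,
                       sco_points = NULL,
                       sco_exclusion = 0L,
                       dco_specs = list(),
                       read_length = 150L,
                       pe_insert_mean = 600,
                       pe_insert_sd = 60,
                       mp_insert_range = c(2000L, 12000L),
                       mp_orientation = "fr",
                       coverage = 30,
                       base_error = 0,
                       qual_meanlog = log(700),
                       qual_sdlog = 0.45,
                       indel_fraction = 0.05) {
  if (is.null(karyotype)) karyotype <- default_karyotype(ref_length)
  rates <- c(snp_density, donor_snp_density, sco_rate, base_error,
             indel_fraction)
  if (any(rates < 0 | rates > 1)) stop("invalid config: rates must lie in [0, 1]")
  stopifnot(ref_length >= 1000, n_stocks >= 1, coverage >= 0,
            read_length >= 20, mp_insert_range[1] <= mp_insert_range[2])
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              ref_length = as.integer(ref_length), karyotype = karyotype,
              snp_density = snp_density,
              donor_snp_density = donor_snp_density,
              n_stocks = as.integer(n_stocks), sco_rate = sco_rate,
              sco_stocks = sco_stocks, sco_points = sco_points,
              sco_exclusion = as.integer(sco_exclusion),
              dco_specs = dco_specs, read_length = as.integer(read_length),
              pe_insert_mean = pe_insert_mean, pe_insert_sd = pe_insert_sd,
              mp_insert_range = as.integer(mp_insert_range),
              mp_orientation = match.arg(mp_orientation, c("fr", "rf")),
              coverage = coverage, base_error = base_error,
              qual_meanlog = qual_meanlog, qual_sdlog = qual_sdlog,
              indel_fraction = indel_fraction)
  class(cfg) <- "sim_config"
  cfg
}

#' Default synthetic karyotype
#'
#' Two sequentially superimposed events on a chromosome of length
#' `ref_length`: a 2-cut inversion whose distal cut carries a 1090-bp
#' deletion (the size observed at the distal-most TM3 cut) and whose
#' proximal cut is clean, followed by a 3-cut rearrangement (both internal
#' segments inverted in place) with small deletions and one duplication at
#' its cuts — five junctions in total.
#'
#' @param ref_length Reference length in bp (>= 1 Mb for the default
#'   coordinates, which scale with `ref_length`).
#' @return List of [rearrangement()] objects.
#' @export
default_karyotype <- function(ref_length = 5e6) {
  u <- function(f) as.integer(round(f * ref_length))
  list(
    rearrangement("InvA", list(c(u(0.24), u(0.24) + 1091L),
                               c(u(0.44), u(0.44) + 1L))),
    rearrangement("InvB3", list(c(u(0.58), u(0.58) + 6L),
                                c(u(0.70), u(0.70) - 2L),
                                c(u(0.86), u(0.86) + 29L)))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$chrom, x$ref_length, "bp,", x$n_stocks, "stocks,",
      length(x$karyotype), "karyotype events, seed", x$seed, "\n")
  invisible(x)
}
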