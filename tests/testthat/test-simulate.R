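test_that("reference simulation is seed-deterministic with uniform composition", {
  a <- make_reference(10000, seed = 5)
  b <- make_reference(10000, seed = 5)
  c <- make_reference(10000, seed = 6)
  expect_identical(as.character(a), as.character(b))
  expect_false(as.character(a) == as.character(c))
  big <- make_reference(100000, seed = 7)
  counts <- Biostrings::alphabetFrequency(big)[c("A", "C", "G", "T")]
  # each base within 4 binomial SDs of n/4
  sd4 <- 4 * sqrt(100000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 25000) < sd4))
  expect_error(make_reference(10), ">= 1 kb")
})

test_that("a crossover-free panel is SNP-identical across stocks", {
  cfg <- sim_config(seed = 31, ref_length = 2e5, n_stocks = 4, sco_rate = 0,
                    karyotype = list(rearrangement(
                      "inv", list(c(50000L, 50001L), c(150000L, 150001L)))))
  panel <- derive_panel(cfg)
  for (j in 2:4) expect_identical(panel$stocks[[j]], panel$stocks[[1]])
  expect_identical(nrow(panel$truth$tracts), 0L)
})

test_that("single crossovers replace the distal tip with donor haplotype", {
  cfg <- sim_config(seed = 32, ref_length = 4e5, n_stocks = 2,
                    sco_stocks = 1:2,
                    karyotype = list(rearrangement(
                      "inv", list(c(200000L, 200001L), c(350000L, 350001L)))))
  panel <- derive_panel(cfg)
  for (j in 1:2) {
    x <- panel$truth$sco_points[j]
    snps <- panel$stocks[[j]]
    expect_lt(x, 200000)
    # no balancer-lineage SNPs distal to the crossover point
    expect_true(all(snps$pos[snps$origin == "balancer"] > x))
    # donor alleles confined to the exchanged tip
    expect_true(all(snps$pos[snps$origin != "balancer"] <= x))
    tr <- panel$truth$tracts[panel$truth$tracts$stock == names(panel$stocks)[j], ]
    expect_identical(tr$end, x)
    expect_identical(tr$type, "SCO")
  }
  # independent donors: the two tips differ
  d1 <- panel$stocks[[1]]; d2 <- panel$stocks[[2]]
  lim <- min(panel$truth$sco_points)
  expect_false(identical(d1[d1$pos <= lim, c("pos", "alt")],
                         d2[d2$pos <= lim, c("pos", "alt")]))
})

test_that("a configured DCO swaps one internal interval in one stock only", {
  karyo <- list(rearrangement("inv", list(c(100000L, 100001L),
                                          c(350000L, 350001L))))
  cfg <- sim_config(seed = 33, ref_length = 4e5, n_stocks = 3, sco_rate = 0,
                    karyotype = karyo,
                    dco_specs = list(list(stocks = 2L,
                                          interval = c(150000L, 250000L))))
  panel <- derive_panel(cfg)
  s2 <- panel$stocks[[2]]
  inside <- s2$pos >= 150000 & s2$pos <= 250000
  expect_true(all(s2$origin[inside] != "balancer"))
  expect_true(all(s2$origin[!inside] == "balancer"))
  expect_identical(panel$stocks[[1]], panel$stocks[[3]])
  expect_identical(panel$truth$tracts$type, "DCO")
  # DCO intervals must fall inside an inverted segment
  bad <- sim_config(seed = 33, ref_length = 4e5, n_stocks = 3,
                    sco_rate = 0, karyotype = karyo,
                    dco_specs = list(list(stocks = 2L,
                                          interval = c(10L, 50000L))))
  expect_error(derive_panel(bad), "not inside an inverted segment")
})

test_that("reads from an unrearranged chromosome are (almost) all concordant", {
  cfg <- sim_config(seed = 34, ref_length = 2e5, karyotype = list())
  map <- balancer_map(cfg$chrom, cfg$ref_length)
  pe <- simulate_read_pairs(map, cfg, "pe", coverage = 20, seed = 35)
  pairs <- classify_pairs(pe)
  expect_identical(sum(pairs$class == "split"), 0L)
  # only the insert-size tail beyond the +/- 3 SD bounds may be flagged
  expect_lt(mean(pairs$class == "discordant"), 0.01)
})

test_that("junction-straddling mate pairs appear at the expected rate", {
  fx <- caller_fixture()
  pairs <- classify_pairs(fx$mp)
  # derived-frame junction positions are the segment boundaries
  seg_len <- fx$map$segments$ref_end - fx$map$segments$ref_start + 1L
  bnd <- cumsum(seg_len)[-nrow(fx$map$segments)]
  rl <- fx$cfg$read_length
  fl <- mean(fx$cfg$mp_insert_range)
  expected <- 30 * (fl - 2 * rl) / (2 * rl)   # straddlers per junction
  frag <- fx$mp[!fx$mp$supp & fx$mp$mate == 1L, ]
  frag2 <- fx$mp[!fx$mp$supp & fx$mp$mate == 2L, ]
  m <- match(frag$qname, frag2$qname)
  lo <- frag$de; hi <- frag2$ds[m]   # gap between the two reads
  disc <- frag$qname %in% pairs$qname[pairs$class == "discordant"]
  for (b in bnd) {
    n_obs <- sum(disc & lo < b & hi > b, na.rm = TRUE)
    expect_lt(abs(n_obs - expected), 3 * sqrt(expected) + 3)
  }
})

test_that("every discordant or split fragment straddles a true junction", {
  fx <- caller_fixture()
  pairs <- classify_pairs(fx$mp)
  seg_len <- fx$map$segments$ref_end - fx$map$segments$ref_start + 1L
  bnd <- cumsum(seg_len)[-nrow(fx$map$segments)]
  bad_q <- pairs$qname[pairs$class %in% c("discordant", "split")]
  recs <- fx$mp[fx$mp$qname %in% bad_q, ]
  frag_lo <- tapply(recs$ds, recs$qname, min)
  frag_hi <- tapply(recs$de, recs$qname, max)
  straddles <- vapply(seq_along(frag_lo), function(i) {
    any(bnd >= frag_lo[i] & bnd < frag_hi[i])
  }, logical(1))
  expect_true(all(straddles))
})

test_that("junction-crossing reads yield split records at high coverage", {
  fx <- caller_fixture()
  pairs <- classify_pairs(fx$mp)
  expect_gt(sum(pairs$class == "split"), 0L)
  # both junctions collect at least one split record
  ev <- breakpoint_events(fx$mp, pairs)
  expect_true(any(!is.na(ev$clip_high) & abs(ev$clip_high - 150000) <= 1))
  expect_true(any(!is.na(ev$clip_high) & abs(ev$clip_high - 400000) <= 1))
})

test_that("simulated SAM and VCF outputs are byte-identical across reruns", {
  cfg <- sim_config(seed = 36, ref_length = 5e4, n_stocks = 2, sco_rate = 0,
                    karyotype = list(rearrangement(
                      "inv", list(c(20000L, 20001L), c(40000L, 40001L)))))
  run <- function() {
    d <- tempfile(); dir.create(d)
    panel <- derive_panel(cfg)
    reads <- simulate_read_pairs(panel$map, cfg, "pe", coverage = 5,
                                 refseq = panel$reference, seed = 37)
    write_sam(reads, file.path(d, "r.sam"), cfg$chrom, cfg$ref_length)
    panel_vcfs(panel, d, cfg)
    emit_fixtures(panel, d, cfg,
                  mask_intervals = data.frame(start = 100L, end = 200L))
    d
  }
  d1 <- run(); d2 <- run()
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("VCF emission honours the indel fraction and QUAL model", {
  cfg <- sim_config(seed = 38, ref_length = 1e5, n_stocks = 2,
                    sco_rate = 0, indel_fraction = 0, karyotype = list())
  panel <- derive_panel(cfg)
  v <- tempfile(fileext = ".vcf")
  emit_stock_vcf(panel$stocks[[1]], v, cfg, panel$reference, seed = 39)
  x <- vcfR::read.vcfR(v, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(x), stringsAsFactors = FALSE)
  expect_true(all(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1))

  # a constant high-QUAL model leaves nothing for the < 200 filter
  cfg_hi <- sim_config(seed = 38, ref_length = 1e5, n_stocks = 2,
                       sco_rate = 0, indel_fraction = 0,
                       qual_meanlog = log(500), qual_sdlog = 0,
                       karyotype = list())
  emit_stock_vcf(panel$stocks[[1]], v, cfg_hi, panel$reference, seed = 39)
  x <- vcfR::read.vcfR(v, verbose = FALSE)
  q <- as.numeric(vcfR::getFIX(x)[, "QUAL"])
  expect_identical(sum(q < 200), 0L)

  # low-QUAL tail mass matches the model within 3 binomial SDs
  cfg_t <- sim_config(seed = 38, ref_length = 1e6, n_stocks = 2,
                      sco_rate = 0, indel_fraction = 0,
                      qual_meanlog = log(300), qual_sdlog = 0.5,
                      karyotype = list())
  panel_t <- derive_panel(cfg_t)
  emit_stock_vcf(panel_t$stocks[[1]], v, cfg_t, panel_t$reference, seed = 40)
  x <- vcfR::read.vcfR(v, verbose = FALSE)
  q <- as.numeric(vcfR::getFIX(x)[, "QUAL"])
  p <- stats::plnorm(200, log(300), 0.5)
  expect_lt(abs(sum(q < 200) - length(q) * p),
            3 * sqrt(length(q) * p * (1 - p)))

  # indels interleave at the configured fraction
  cfg_i <- sim_config(seed = 38, ref_length = 1e5, n_stocks = 2,
                      sco_rate = 0, indel_fraction = 0.2, karyotype = list())
  emit_stock_vcf(panel$stocks[[1]], v, cfg_i, panel$reference, seed = 41)
  x <- vcfR::read.vcfR(v, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(x), stringsAsFactors = FALSE)
  frac <- mean(nchar(fix$REF) > 1)
  expect_lt(abs(frac - 0.2), 0.02)
  expect_false(is.unsorted(as.integer(fix$POS)))
})

test_that("zero coverage yields an empty record stream, not an error", {
  cfg <- sim_config(seed = 42, ref_length = 1e5, karyotype = list())
  map <- balancer_map(cfg$chrom, cfg$ref_length)
  expect_message(out <- simulate_read_pairs(map, cfg, "pe", coverage = 0),
                 "zero fragments")
  expect_identical(nrow(out), 0L)
})
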