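test_that("pair classification follows orientation, insert and clip rules", {
  bounds <- c(200, 1000)
  # FR pair, insert within bounds, no clips -> concordant
  p <- classify_pairs(make_pair(1000, "+", 1400, "-"),
                      insert_bounds = bounds)
  expect_identical(p$class, "concordant")
  # both mates on the same strand (inversion-flank geometry) -> discordant
  p <- classify_pairs(make_pair(1000, "+", 1400, "+"),
                      insert_bounds = bounds)
  expect_identical(p$class, "discordant")
  # huge insert -> discordant
  p <- classify_pairs(make_pair(1000, "+", 9000, "-"),
                      insert_bounds = bounds)
  expect_identical(p$class, "discordant")
  # 40-bp soft-clip with a supplementary placement -> split (precedence)
  p <- classify_pairs(make_pair(1000, "+", 9000, "-", clip1 = 40,
                                supp1 = TRUE),
                      insert_bounds = bounds, min_clip = 20)
  expect_identical(p$class, "split")
  # same clip but below min_clip threshold -> not split
  p <- classify_pairs(make_pair(1000, "+", 1400, "-", clip1 = 10,
                                supp1 = TRUE),
                      insert_bounds = bounds, min_clip = 20)
  expect_false(p$class == "split")
  # unmapped mate -> unusable
  rec <- make_pair(1000, "+", 1400, "-")
  rec$flag[2] <- rec$flag[2] + 4L
  p <- classify_pairs(rec, insert_bounds = bounds)
  expect_identical(p$class, "unusable")
})

test_that("mask filtering equals a brute-force point-in-interval scan", {
  ev0 <- data.frame(qname = "q", type = "discordant", pos = 500L,
                    strand = "+", clip_high = NA_integer_,
                    clip_low = NA_integer_, library = "pe",
                    stringsAsFactors = FALSE)
  # empty mask is the identity
  expect_identical(nrow(mask_filter(ev0, data.frame(start = integer(),
                                                    end = integer()))), 1L)
  # an event anchored at a masked base is removed
  expect_identical(
    nrow(suppressMessages(mask_filter(ev0, data.frame(start = 400,
                                                      end = 600)))), 0L)
  set.seed(201)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ev <- ev0[rep(1, n), ]
    ev$pos <- sample.int(1000, n)
    m <- sample(1:5, 1)
    st <- sort(sample.int(900, m))
    mask <- data.frame(start = st, end = st + sample(10:80, m, replace = TRUE))
    keep_bf <- vapply(ev$pos, function(p) {
      !any(p >= mask$start & p <= mask$end)
    }, logical(1))
    got <- suppressMessages(mask_filter(ev, mask))
    expect_identical(sort(got$pos), sort(ev$pos[keep_bf]))
  }
})

test_that("the window rule is strict: 11 anchors pass, 10 do not", {
  mk <- function(n) {
    data.frame(qname = sprintf("q%d", seq_len(n)), type = "discordant",
               pos = as.integer(seq(10, 990, length.out = n)), strand = "+",
               clip_high = NA_integer_, clip_low = NA_integer_,
               library = "pe", stringsAsFactors = FALSE)
  }
  expect_identical(nrow(window_scan(mk(10))), 0L)
  w <- window_scan(mk(11))
  expect_identical(nrow(w), 1L)
  expect_identical(w$start, 1L)
  expect_identical(w$support, 11L)
})

test_that("window counts equal a brute-force histogram by anchor", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    ev <- data.frame(qname = sprintf("q%d", seq_len(n)),
                     type = sample(c("split", "discordant"), n, TRUE),
                     pos = sample.int(20000, n, replace = TRUE),
                     strand = "+", clip_high = NA_integer_,
                     clip_low = NA_integer_, library = "pe",
                     stringsAsFactors = FALSE)
    w <- window_scan(ev, window_size = 1000, min_support = 0)
    bf <- table((ev$pos - 1) %/% 1000)
    bf <- bf[order(as.integer(names(bf)))]
    expect_identical(w$support, as.integer(bf))
    expect_identical((w$start - 1L) %/% 1000L, as.integer(names(bf)))
  }
})

test_that("raising min_support never adds candidate windows", {
  set.seed(203)
  ev <- data.frame(qname = sprintf("q%d", 1:500), type = "discordant",
                   pos = sample.int(10000, 500, replace = TRUE),
                   strand = "+", clip_high = NA_integer_,
                   clip_low = NA_integer_, library = "pe",
                   stringsAsFactors = FALSE)
  prev <- window_scan(ev, min_support = 0)$start
  for (ms in c(5, 10, 20, 40)) {
    cur <- window_scan(ev, min_support = ms)$start
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("a single inversion yields two region links, one per junction", {
  fx <- caller_fixture()
  calls <- call_breakpoints(fx$mp)
  expect_identical(nrow(calls$regions), 2L)
  expect_identical(nrow(calls$links), 2L)
  # the two links carry the inversion's +/+ and -/- discordant signatures
  sig <- sort(paste0(calls$links$strand_a, calls$links$strand_b))
  expect_identical(sig, c("++", "--"))
})

test_that("a three-cut rearrangement yields three linked junctions", {
  cfg <- sim_config(seed = 73, ref_length = 8e5,
                    karyotype = list(rearrangement(
                      "tb", list(c(150000L, 150001L), c(400000L, 400001L),
                                 c(650000L, 650001L)))))
  map <- apply_karyotype(balancer_map(cfg$chrom, cfg$ref_length),
                         cfg$karyotype)
  mp <- simulate_read_pairs(map, cfg, "mp", coverage = 30, seed = 74)
  calls <- call_breakpoints(mp)
  expect_identical(nrow(calls$regions), 3L)
  expect_identical(nrow(calls$links), 3L)
  truth <- junction_table(map)
  for (i in seq_len(nrow(truth))) {
    expect_true(any(calls$junctions$five_prime == truth$five_prime[i] &
                      calls$junctions$three_prime == truth$three_prime[i] &
                      calls$junctions$delta == truth$delta[i]))
  }
})

test_that("unshared discordant pairs never link regions", {
  regions <- data.frame(region = 1:2, chrom = "chrT",
                        start = c(1L, 5001L), end = c(1000L, 6000L),
                        n_windows = 1L, support = 20L)
  # all pairs anchored twice in region 1: nothing links 1 and 2
  ev <- data.frame(qname = rep(sprintf("q%d", 1:10), each = 2),
                   type = "discordant", pos = rep(c(100L, 900L), 10),
                   strand = "+", clip_high = NA_integer_,
                   clip_low = NA_integer_, library = "pe",
                   stringsAsFactors = FALSE)
  expect_identical(nrow(pair_junctions(regions, ev)), 0L)
})

test_that("split-read consensus refines junctions to the base pair", {
  fx <- caller_fixture()
  calls <- call_breakpoints(fx$mp)
  truth <- junction_table(fx$map)
  expect_true(all(calls$junctions$resolution == "bp"))
  expect_identical(sort(calls$junctions$five_prime), sort(truth$five_prime))
  expect_identical(sort(calls$junctions$three_prime), sort(truth$three_prime))
  expect_true(all(calls$junctions$delta == 0L))
})

test_that("without split reads the call degrades to window resolution", {
  region <- data.frame(region = 1L, chrom = "chrT", start = 1001L,
                       end = 2000L, n_windows = 1L, support = 12L)
  ev <- data.frame(qname = sprintf("q%d", 1:12), type = "discordant",
                   pos = as.integer(seq(1010, 1990, length.out = 12)),
                   strand = "+", clip_high = NA_integer_,
                   clip_low = NA_integer_, library = "pe",
                   stringsAsFactors = FALSE)
  j <- refine_breakpoint(region, ev)
  expect_identical(j$resolution, "window")
  expect_identical(j$five_prime, 1500L)
  expect_true(is.na(j$delta))
})

test_that("tied clip consensus is flagged ambiguous, smaller coordinate first", {
  region <- data.frame(region = 1L, chrom = "chrT", start = 1L, end = 1000L,
                       n_windows = 1L, support = 4L)
  ev <- data.frame(qname = sprintf("q%d", 1:4), type = "split",
                   pos = c(400L, 400L, 450L, 450L), strand = "+",
                   clip_high = c(500L, 500L, 520L, 520L),
                   clip_low = c(600L, 600L, 600L, 600L),
                   library = "pe", stringsAsFactors = FALSE)
  j <- refine_breakpoint(region, ev)
  expect_true(j$ambiguous)
  expect_identical(j$five_prime, 500L)
  expect_identical(j$alt_five_prime, 520L)
})

test_that("SAM round trip preserves the evidence the caller needs", {
  fx <- caller_fixture()
  sam <- tempfile(fileext = ".sam")
  write_sam(fx$mp, sam, fx$cfg$chrom, fx$cfg$ref_length)
  back <- read_sam(sam)
  expect_identical(nrow(back), nrow(fx$mp))
  calls <- call_breakpoints(sam)
  truth <- junction_table(fx$map)
  expect_identical(sort(calls$junctions$five_prime), sort(truth$five_prime))
})

test_that("junction exports are written in all three formats", {
  fx <- caller_fixture()
  calls <- call_breakpoints(fx$mp)
  tsv <- tempfile(); bedpe <- tempfile(); vcf <- tempfile()
  write_junctions(calls, tsv, "tsv")
  write_junctions(calls, bedpe, "bedpe")
  write_junctions(calls, vcf, "vcf")
  expect_identical(nrow(utils::read.delim(tsv)), nrow(calls$junctions))
  expect_identical(length(readLines(bedpe)), nrow(calls$links))
  expect_true(any(grepl("SVTYPE=BND", readLines(vcf))))
})
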