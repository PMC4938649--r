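test_that("panel loading applies the QUAL boundary and indel filters exactly", {
  d <- tempfile(); dir.create(d)
  v1 <- write_tiny_vcf(data.frame(
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "ATTC"),
    alt = c("G", "T", "A", "A"),
    qual = c(199, 200, 500, 900)), file.path(d, "a.vcf"))
  v2 <- write_tiny_vcf(data.frame(
    pos = c(200L, 300L),
    ref = c("C", "G"),
    alt = c("T", "A"),
    qual = c(250, 150)), file.path(d, "b.vcf"))
  p <- load_panel(c(a = v1, b = v2), qual_min = 200)
  # QUAL 199 excluded, QUAL 200 included, indel excluded despite QUAL 900
  expect_identical(p$snps$pos, c(200L, 300L))
  # stock b's pos-300 record fails QUAL, so the site is absent from b
  expect_identical(p$k, c(2L, 1L))
  expect_identical(unname(p$presence[2, ]), c(TRUE, FALSE))
})

test_that("the same position with different alternate alleles makes two rows", {
  d <- tempfile(); dir.create(d)
  v1 <- write_tiny_vcf(data.frame(pos = 500L, ref = "A", alt = "G",
                                  qual = 500), file.path(d, "a.vcf"))
  v2 <- write_tiny_vcf(data.frame(pos = 500L, ref = "A", alt = "T",
                                  qual = 500), file.path(d, "b.vcf"))
  p <- load_panel(c(a = v1, b = v2))
  expect_identical(nrow(p$snps), 2L)
  expect_identical(p$k, c(1L, 1L))
  # set-union oracle over (pos, alt) keys
  expect_identical(paste(p$snps$pos, p$snps$alt),
                   sort(unique(c("500 G", "500 T"))))
})

test_that("an empty panel warns but returns a valid zero-row matrix", {
  d <- tempfile(); dir.create(d)
  v1 <- write_tiny_vcf(data.frame(pos = integer(), ref = character(),
                                  alt = character(), qual = numeric()),
                       file.path(d, "a.vcf"))
  v2 <- write_tiny_vcf(data.frame(pos = 10L, ref = "A", alt = "C",
                                  qual = 10), file.path(d, "b.vcf"))
  expect_warning(p <- load_panel(c(a = v1, b = v2)), "empty panel")
  expect_identical(nrow(p$snps), 0L)
  expect_identical(dim(p$presence), c(0L, 2L))
})

# build a panel_matrix directly from a boolean presence matrix
panel_from_matrix <- function(m, pos = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 100L
  structure(list(
    snps = data.frame(chrom = "chrT", pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE),
    presence = m, stocks = colnames(m),
    k = as.integer(rowSums(m))), class = "panel_matrix")
}

test_that("sharing counts equal brute-force row sums with correct labels", {
  set.seed(301)
  for (i in 1:20) {
    n_snp <- sample(5:60, 1); n_stock <- sample(3:18, 1)
    m <- matrix(runif(n_snp * n_stock) < 0.4, n_snp, n_stock,
                dimnames = list(NULL, sprintf("s%02d", 1:n_stock)))
    m[rowSums(m) == 0, 1] <- TRUE   # every SNP is seen somewhere
    p <- panel_from_matrix(m)
    sc <- share_counts(p)
    bf <- apply(m, 1, sum)
    expect_identical(sc$k, as.integer(bf))
    expect_identical(sc$label[sc$k == 1], rep("unique", sum(bf == 1)))
    expect_identical(sc$label[sc$k == n_stock],
                     rep("shared-by-all", sum(bf == n_stock)))
  }
})

test_that("rare-SNP window counts match a brute-force double loop", {
  set.seed(302)
  for (i in 1:10) {
    n_snp <- sample(20:120, 1); n_stock <- 6
    m <- matrix(runif(n_snp * n_stock) < 0.5, n_snp, n_stock,
                dimnames = list(NULL, sprintf("s%02d", 1:n_stock)))
    m[rowSums(m) == 0, 1] <- TRUE
    pos <- sort(sample.int(50000, n_snp))
    p <- panel_from_matrix(m, pos = pos)
    wm <- rare_snp_windows(p, max_share = 3, window = 10000,
                           chrom_length = 50000)
    for (j in 1:n_stock) {
      for (w in 1:5) {
        bf <- sum(m[, j] & rowSums(m) <= 3 &
                    pos > (w - 1) * 10000 & pos <= w * 10000)
        expect_identical(unname(wm$counts[w, j]), as.integer(bf))
      }
    }
    # conservation: column sums equal per-stock rare-SNP counts
    expect_identical(unname(colSums(wm$counts)),
                     unname(colSums(m & rowSums(m) <= 3)))
  }
})

test_that("window counts are monotone in max_share and zero when all shared", {
  m <- matrix(TRUE, 30, 6, dimnames = list(NULL, sprintf("s%02d", 1:6)))
  p <- panel_from_matrix(m)
  wm <- rare_snp_windows(p, max_share = 5, window = 1000)
  expect_true(all(wm$counts == 0L))
  set.seed(303)
  m2 <- matrix(runif(300) < 0.5, 50, 6,
               dimnames = list(NULL, sprintf("s%02d", 1:6)))
  m2[rowSums(m2) == 0, 1] <- TRUE
  p2 <- panel_from_matrix(m2)
  prev <- rare_snp_windows(p2, max_share = 0, window = 1000)$counts
  for (ms in 1:6) {
    cur <- rare_snp_windows(p2, max_share = ms, window = 1000)$counts
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("seven unique SNPs in one window light up exactly one cell", {
  m <- matrix(TRUE, 27, 6, dimnames = list(NULL, sprintf("s%02d", 1:6)))
  m[1:7, -1] <- FALSE          # 7 SNPs unique to stock 1
  pos <- c(seq(15001L, 15601L, by = 100L), sort(sample.int(9000, 20)) + 20000L)
  p <- panel_from_matrix(m, pos = pos)
  wm <- rare_snp_windows(p, max_share = 5, window = 10000,
                         chrom_length = 30000)
  expect_identical(unname(wm$counts[2, 1]), 7L)
  expect_identical(sum(wm$counts), 7L)
})

# a small simulated panel with one SCO and one DCO stock, memoised
tract_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 311, ref_length = 1e6, n_stocks = 8,
                        sco_stocks = 2L, sco_points = 120000L,
                        dco_specs = list(list(stocks = 5L,
                                              interval = c(300000L, 400000L))))
      panel <- derive_panel(cfg)
      vcfs <- panel_vcfs(panel, tempfile(), cfg)
      pm <- load_panel(vcfs)
      wm <- rare_snp_windows(pm, max_share = 3, window = 10000,
                             chrom_length = cfg$ref_length)
      cache <<- list(cfg = cfg, panel = panel, pm = pm, wm = wm)
    }
    cache
  }
})

test_that("simulated SCO and DCO tracts are recovered with covering CIs", {
  fx <- tract_fixture()
  tr <- call_tracts(fx$wm, fx$pm, breakpoints = fx$panel$truth$breakpoints)
  truth <- fx$panel$truth$tracts
  expect_identical(nrow(tr), 2L)
  sco_t <- truth[truth$type == "SCO", ]
  sco_c <- tr[tr$type == "SCO", ]
  expect_identical(sco_c$stock, sco_t$stock)
  # the proximal boundary CI contains the true crossover point
  expect_lte(sco_c$ci_end_lo, sco_t$end)
  expect_gte(sco_c$ci_end_hi, sco_t$end)
  dco_t <- truth[truth$type == "DCO", ]
  dco_c <- tr[tr$type == "DCO", ]
  expect_identical(dco_c$stock, dco_t$stock)
  expect_lte(dco_c$ci_start_lo, dco_t$start)
  expect_gte(dco_c$ci_start_hi, dco_t$start)
  expect_lte(dco_c$ci_end_lo, dco_t$end)
  expect_gte(dco_c$ci_end_hi, dco_t$end)
})

test_that("tracts are unclassified without breakpoints, typed with them", {
  fx <- tract_fixture()
  tr0 <- call_tracts(fx$wm, fx$pm, breakpoints = NULL)
  expect_true(all(tr0$type == "unclassified"))
  tr <- call_tracts(fx$wm, fx$pm, breakpoints = fx$panel$truth$breakpoints)
  expect_setequal(tr$type, c("SCO", "DCO"))
  expect_true(all(tr$dist_start_bp >= 0))
})

test_that("a panel with no rare SNPs yields zero tracts", {
  m <- matrix(TRUE, 40, 6, dimnames = list(NULL, sprintf("s%02d", 1:6)))
  p <- panel_from_matrix(m)
  wm <- rare_snp_windows(p, max_share = 3, window = 1000)
  tr <- call_tracts(wm, p, breakpoints = c(2000L))
  expect_identical(nrow(tr), 0L)
})

test_that("tracts from a shared donor event are flagged as common origin", {
  cfg <- sim_config(seed = 312, ref_length = 1e6, n_stocks = 6,
                    sco_rate = 0,
                    dco_specs = list(
                      list(stocks = c(2L, 3L), interval = c(300000L, 400000L),
                           donor = "shared"),
                      list(stocks = 5L, interval = c(600000L, 680000L))))
  panel <- derive_panel(cfg)
  pm <- load_panel(panel_vcfs(panel, tempfile(), cfg))
  # max_share well below the baseline sharing count (4, after two stocks
  # lose the interval) so sporadic QUAL dropout cannot mimic rarity
  wm <- rare_snp_windows(pm, max_share = 2, window = 10000,
                         chrom_length = cfg$ref_length)
  tr <- call_tracts(wm, pm, breakpoints = panel$truth$breakpoints)
  rel <- shared_tracts(tr, pm)
  flagged <- rel[rel$likely_common_origin, ]
  expect_identical(nrow(flagged), 1L)
  expect_setequal(c(flagged$stock_a, flagged$stock_b), c("s02", "s03"))
  expect_gt(flagged$identity, 0.95)
  # the independent-donor stock is not flagged against anyone
  expect_false(any(rel$likely_common_origin &
                     (rel$stock_a == "s05" | rel$stock_b == "s05")))
})
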