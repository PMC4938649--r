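# Independent oracles and tiny fixture builders shared across test files.

# random DNA string of length n
toy_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# base-counting oracle for the junction delta: join the prefix ending at
# `five` to the suffix starting at `three` on a toy sequence and measure
# the length change
oracle_delta <- function(five, three, len = max(five, three) + 20L) {
  s <- toy_seq(len, seed = 42)
  derived <- paste0(substr(s, 1, five), substr(s, three, len))
  nchar(derived) - len
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# string-construction oracle for a 2-cut inversion applied to sequence s
oracle_inversion <- function(s, f1, t1, f2, t2) {
  paste0(substr(s, 1, f1), rc(substr(s, t1, f2)),
         substr(s, t2, nchar(s)))
}

# string-construction oracle for a 3-cut rearrangement (both internal
# segments inverted in place)
oracle_three_break <- function(s, f1, t1, f2, t2, f3, t3) {
  paste0(substr(s, 1, f1), rc(substr(s, t1, f2)), rc(substr(s, t2, f3)),
         substr(s, t3, nchar(s)))
}

# hand-built pair of primary alignment records for classifier tests
make_pair <- function(pos1, strand1, pos2, strand2, rl = 150L,
                      clip1 = 0L, supp1 = FALSE, qname = "p1",
                      library = "pe") {
  cigar1 <- if (clip1 > 0) paste0(rl - clip1, "M", clip1, "S") else
    paste0(rl, "M")
  base <- data.frame(
    frag = 1L, mate = c(1L, 2L), ds = NA_integer_, de = NA_integer_,
    orient = NA_character_, pos = c(pos1, pos2),
    ref_end = c(pos1 + rl - 1L - clip1, pos2 + rl - 1L),
    strand = c(strand1, strand2), cigar = c(cigar1, paste0(rl, "M")),
    clip_lead = 0L, clip_trail = c(clip1, 0L), supp = FALSE,
    pnext = c(pos2, pos1), tlen = 0L,
    flag = c(64L, 128L) + 1L, qname = qname, rname = "chrT", mapq = 60L,
    rnext = "=", seq = "*", qual = "*", rg = "s01", library = library,
    stringsAsFactors = FALSE)
  if (supp1) {
    suppl <- base[1, ]
    suppl$supp <- TRUE
    suppl$flag <- suppl$flag + 2048L
    suppl$pos <- pos1 + 5000L
    suppl$ref_end <- suppl$pos + clip1 - 1L
    suppl$cigar <- paste0(clip1, "M", rl - clip1, "S")
    suppl$clip_lead <- 0L
    suppl$clip_trail <- rl - clip1
    base <- rbind(base, suppl)
  }
  base
}

# write a tiny VCF with explicit records; rec is a data.frame with
# pos/ref/alt/qual columns
write_tiny_vcf <- function(rec, path, chrom = "chrT", sample = "s") {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=1000000>", chrom),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample))
  if (nrow(rec)) {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT\t0/1",
                              chrom, rec$pos, rec$ref, rec$alt,
                              format(rec$qual)))
  }
  writeLines(lines, path)
  path
}

# small simulated inversion data set shared by caller tests (memoised)
caller_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 71, ref_length = 6e5,
                        karyotype = list(rearrangement(
                          "inv", list(c(150000L, 150001L),
                                      c(400000L, 400001L)))))
      map <- apply_karyotype(balancer_map(cfg$chrom, cfg$ref_length),
                             cfg$karyotype)
      mp <- simulate_read_pairs(map, cfg, "mp", coverage = 30, seed = 72)
      cache <<- list(cfg = cfg, map = map, mp = mp)
    }
    cache
  }
})
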