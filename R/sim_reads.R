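#' Simulate aligned read pairs from a derived chromosome
#'
#' Draws sequencing fragments uniformly from the derived (balancer)
#' chromosome and places each read on the reference analytically through
#' the segment map — an alignment emulation that produces exactly the
#' split/discordant signatures a read aligner would report at rearrangement
#' junctions, without running one:
#'
#' * reads wholly inside one segment become plain aligned records (strand
#'   follows the segment orientation);
#' * reads crossing a junction are split into a primary alignment (the
#'   longest piece) plus supplementary alignments with soft-clips whose
#'   CIGARs are consistent with the junction;
#' * pairs straddling a junction without a read crossing it become
#'   orientation- or insert-size-discordant on the reference.
#'
#' Records carry read group, mapping quality and proper-pair flags.
#' With `coverage` low enough that zero fragments are drawn an empty record
#' set is returned (with a message), not an error.
#'
#' @param map A [balancer_map()] describing the derived chromosome.
#' @param config A [sim_config()] supplying read length, insert models and
#'   error rate.
#' @param library `"pe"` (paired-end, Gaussian insert) or `"mp"`
#'   (mate-pair, uniform large insert).
#' @param coverage Fold coverage for this library (default from config).
#' @param refseq Reference sequence; when supplied, records carry real
#'   sequence (with substitution errors at `config$base_error`), otherwise
#'   SEQ is `*`.
#' @param stock Stock id, written as the read group.
#' @param seed RNG seed.
#' @return A data.frame of SAM-style records (one row per alignment record,
#'   including supplementaries) with columns `qname, flag, rname, pos,
#'   mapq, cigar, rnext, pnext, tlen, seq, qual, rg, library` plus helper
#'   columns `strand, ref_end, clip_lead, clip_trail, supp, mate, frag`.
#' @export
simulate_read_pairs <- function(map, config, library = c("pe", "mp"),
                                coverage = config$coverage, refseq = NULL,
                                stock = "s01", seed = config$seed) {
  library <- match.arg(library)
  stopifnot(inherits(map, "balancer_map"), coverage >= 0)
  rl <- config$read_length
  L <- derived_length(map)
  n_frag <- round(coverage * L / (2 * rl))
  if (n_frag < 1) {
    message("coverage too low: zero fragments drawn")
    return(empty_records())
  }

  with_seed(seed, {
    fl <- if (library == "pe") {
      pmax(2L * rl, as.integer(round(stats::rnorm(n_frag, config$pe_insert_mean,
                                                  config$pe_insert_sd))))
    } else {
      r <- config$mp_insert_range
      r[1] + as.integer(floor(stats::runif(n_frag) * (r[2] - r[1] + 1L)))
    }
    fl <- pmin(fl, L)
    fs <- 1L + as.integer(floor(stats::runif(n_frag) * (L - fl + 1)))

    # per-read derived intervals; mate-pair orientation is a library
    # parameter ("fr" default, "rf" optional)
    r1o <- "+"; r2o <- "-"
    if (library == "mp" && config$mp_orientation == "rf") { r1o <- "-"; r2o <- "+" }
    reads <- data.frame(
      frag = rep(seq_len(n_frag), 2L),
      mate = rep(1:2, each = n_frag),
      ds = c(fs, fs + fl - rl),
      de = c(fs + rl - 1L, fs + fl - 1L),
      orient = rep(c(r1o, r2o), each = n_frag),
      stringsAsFactors = FALSE
    )

    segs <- map$segments
    dst <- seg_dstarts(map)
    den <- dst + (segs$ref_end - segs$ref_start)
    idx <- findInterval(reads$ds, dst)
    single <- reads$de <= den[idx]

    rec <- within(reads[single, , drop = FALSE], {
      segi <- idx[single]
      off1 <- ds - dst[segi]
      off2 <- de - dst[segi]
      plus <- segs$strand[segi] == "+"
      pos <- ifelse(plus, segs$ref_start[segi] + off1, segs$ref_end[segi] - off2)
      ref_end <- pos + (de - ds)
      strand <- ifelse(plus, orient, flip_strand(orient))
      cigar <- paste0(de - ds + 1L, "M")
      clip_lead <- 0L; clip_trail <- 0L; supp <- FALSE
    })
    rec <- rec[, c("frag", "mate", "ds", "de", "orient", "pos", "ref_end",
                   "strand", "cigar", "clip_lead", "clip_trail", "supp")]

    # junction-crossing reads: split into one record per segment piece
    split_rows <- which(!single)
    split_recs <- lapply(split_rows, function(r) {
      ds <- reads$ds[r]; de <- reads$de[r]; orient <- reads$orient[r]
      pieces <- derived_slice(map, ds, de)
      plen <- pieces$ref_end - pieces$ref_start + 1L
      o2 <- cumsum(plen)          # 1-based offsets of pieces within the read,
      o1 <- o2 - plen + 1L        # in derived order
      n <- length(plen); RL <- de - ds + 1L
      a <- if (orient == "+") o1 else RL - o2 + 1L   # sequenced-order coords
      b <- if (orient == "+") o2 else RL - o1 + 1L
      strand <- if (orient == "+") pieces$strand else flip_strand(pieces$strand)
      lead <- ifelse(strand == "+", a - 1L, RL - b)
      trail <- ifelse(strand == "+", RL - b, a - 1L)
      data.frame(frag = reads$frag[r], mate = reads$mate[r], ds = ds, de = de,
                 orient = orient, pos = pieces$ref_start,
                 ref_end = pieces$ref_end, strand = strand,
                 cigar = paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                                plen, "M",
                                ifelse(trail > 0, paste0(trail, "S"), "")),
                 clip_lead = lead, clip_trail = trail,
                 supp = seq_len(n) != which.max(plen),
                 stringsAsFactors = FALSE)
    })
    if (length(split_recs)) rec <- rbind(rec, do.call(rbind, split_recs))

    # mate fields from each fragment's primary records
    prim <- rec[!rec$supp, ]
    key <- prim$frag * 2L + prim$mate  # frag*2+1 / frag*2+2
    ppos <- integer(2L * n_frag + 2L); pend <- ppos; pstr <- character(2L * n_frag + 2L)
    ppos[key] <- prim$pos; pend[key] <- prim$ref_end; pstr[key] <- prim$strand
    mkey <- rec$frag * 2L + (3L - rec$mate)
    skey <- rec$frag * 2L + rec$mate
    rec$pnext <- ppos[mkey]
    mate_strand <- pstr[mkey]
    lo <- pmin(ppos[skey], ppos[mkey])
    hi <- pmax(pend[skey], pend[mkey])
    span <- hi - lo + 1L
    leftmost <- ppos[skey] < ppos[mkey] |
      (ppos[skey] == ppos[mkey] & rec$mate == 1L)
    rec$tlen <- ifelse(leftmost, span, -span)

    # proper pair: both mates unsplit, FR orientation on the reference
    nsupp <- tabulate(rec$frag[rec$supp], nbins = n_frag)
    frag_split <- nsupp > 0L
    fr_ok <- ifelse(leftmost, pstr[skey] == "+" & mate_strand == "-",
                    pstr[skey] == "-" & mate_strand == "+")
    proper <- !frag_split[rec$frag] & fr_ok & span <= 2L * max(fl)

    rec$flag <- 1L +
      ifelse(proper & !rec$supp, 2L, 0L) +
      ifelse(rec$strand == "-", 16L, 0L) +
      ifelse(mate_strand == "-", 32L, 0L) +
      ifelse(rec$mate == 1L, 64L, 128L) +
      ifelse(rec$supp, 2048L, 0L)

    rec$qname <- sprintf("%s_%s_f%07d", stock, library, rec$frag)
    rec$rname <- map$chrom
    rec$mapq <- 60L
    rec$rnext <- "="

    if (!is.null(refseq)) {
      dseq <- derived_seq(map, refseq)
      raw <- Biostrings::extractAt(dseq, IRanges::IRanges(rec$ds, rec$de))
      flipme <- xor(rec$orient == "-", rec$strand == "-")
      if (any(flipme)) raw[flipme] <- Biostrings::reverseComplement(raw[flipme])
      rec$seq <- as.character(raw)
      if (config$base_error > 0) {
        rec$seq <- add_substitutions(rec$seq, config$base_error)
      }
      rec$qual <- strrep("I", nchar(rec$seq))
    } else {
      rec$seq <- "*"
      rec$qual <- "*"
    }
    rec$rg <- stock
    rec$library <- library
    rec <- rec[order(rec$pos, rec$qname), ]
    rownames(rec) <- NULL
    rec
  })
}

empty_records <- function() {
  data.frame(frag = integer(), mate = integer(), ds = integer(),
             de = integer(), orient = character(), pos = integer(),
             ref_end = integer(), strand = character(), cigar = character(),
             clip_lead = integer(), clip_trail = integer(), supp = logical(),
             pnext = integer(), tlen = integer(), flag = integer(),
             qname = character(), rname = character(), mapq = integer(),
             rnext = character(), seq = character(), qual = character(),
             rg = character(), library = character(), stringsAsFactors = FALSE)
}

# substitution-only sequencing error, drawn independently per record
add_substitutions <- function(seqs, rate) {
  w <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), w, rate)
  for (i in which(n_err > 0)) {
    at <- sample.int(w[i], n_err[i])
    for (p in at) {
      substr(seqs[i], p, p) <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  seqs
}

#' Write simulated records as plain-text SAM
#'
#' @param records Record data.frame from [simulate_read_pairs()] (several
#'   libraries/stocks may be row-bound).
#' @param path Output SAM path.
#' @param chrom,ref_length Sequence dictionary entry for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, chrom, ref_length) {
  rgs <- unique(records$rg)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(ref_length)),
              sprintf("@RG\tID:%s\tSM:%s", rgs, rgs))
  records <- records[order(records$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tRG:Z:%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, records$rg)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into the record layout used by the caller
#'
#' SAM text is converted through [Rsamtools::asBam()]; BAM is read
#' directly. Helper columns (strand, clips, reference end) are derived from
#' flags and CIGARs.
#'
#' @param path SAM or BAM file.
#' @return A record data.frame compatible with [classify_pairs()].
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mpos",
             "isize", "seq", "qual"),
    tag = "RG")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  cig <- x$cigar
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  first_op <- vapply(ops, function(o) if (length(o)) o[1] else "", character(1))
  last_op <- vapply(ops, function(o) if (length(o)) o[length(o)] else "", character(1))
  first_len <- vapply(lens, function(l) if (length(l)) l[1] else 0L, integer(1))
  last_len <- vapply(lens, function(l) if (length(l)) l[length(l)] else 0L, integer(1))
  data.frame(
    frag = NA_integer_, mate = ifelse(bitwAnd(x$flag, 64L) > 0, 1L, 2L),
    ds = NA_integer_, de = NA_integer_, orient = NA_character_,
    pos = x$pos,
    ref_end = x$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(cig) - 1L,
    strand = ifelse(bitwAnd(x$flag, 16L) > 0, "-", "+"),
    cigar = cig,
    clip_lead = ifelse(first_op == "S", first_len, 0L),
    clip_trail = ifelse(last_op == "S", last_len, 0L),
    supp = bitwAnd(x$flag, 2048L) > 0,
    pnext = x$mpos, tlen = x$isize, flag = x$flag, qname = x$qname,
    rname = as.character(x$rname), mapq = x$mapq, rnext = "=",
    seq = as.character(x$seq), qual = as.character(x$qual),
    rg = if (!is.null(x$tag$RG)) x$tag$RG else NA_character_,
    library = NA_character_, stringsAsFactors = FALSE)
}
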