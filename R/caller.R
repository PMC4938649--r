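#' Classify read pairs as concordant, discordant or split
#'
#' A pair is *split* if either of its reads has a supplementary placement
#' together with a soft-clip of at least `min_clip` bases (split takes
#' precedence over discordant); *discordant* if the mates violate the
#' expected relative orientation or the inferred insert size falls outside
#' `insert_bounds`; otherwise *concordant*. Pairs with an unmapped or
#' missing mate are classified *unusable* and counted separately.
#'
#' @param records Record data.frame ([simulate_read_pairs()] or
#'   [read_sam()]); multiple libraries may be mixed — classification is per
#'   pair.
#' @param insert_bounds Numeric `c(lo, hi)`; `NULL` estimates
#'   mean +/- 3 SD from the orientation-concordant pairs
#'   ([estimate_insert_bounds()]).
#' @param expected_orientation `"fr"` (innie, the usual paired-end
#'   expectation) or `"rf"`.
#' @param min_clip Minimum soft-clip length for split evidence (bp).
#' @return A data.frame with one row per pair: `qname, class, pos1, end1,
#'   strand1, pos2, end2, strand2, insert, library`.
#' @export
classify_pairs <- function(records, insert_bounds = NULL,
                           expected_orientation = "fr", min_clip = 20L) {
  expected_orientation <- match.arg(expected_orientation, c("fr", "rf"))
  prim <- records[!records$supp & bitwAnd(records$flag, 4L) == 0L, , drop = FALSE]
  r1 <- prim[prim$mate == 1L, ]
  r2 <- prim[prim$mate == 2L, ]
  m <- match(r1$qname, r2$qname)
  paired <- !is.na(m)
  pairs <- data.frame(
    qname = r1$qname[paired],
    pos1 = r1$pos[paired], end1 = r1$ref_end[paired],
    strand1 = r1$strand[paired],
    pos2 = r2$pos[m[paired]], end2 = r2$ref_end[m[paired]],
    strand2 = r2$strand[m[paired]],
    library = r1$library[paired],
    stringsAsFactors = FALSE)
  pairs$insert <- pmax(pairs$end1, pairs$end2) - pmin(pairs$pos1, pairs$pos2) + 1L

  # orientation check relative to the library expectation
  left1 <- pairs$pos1 <= pairs$pos2
  left_strand <- ifelse(left1, pairs$strand1, pairs$strand2)
  right_strand <- ifelse(left1, pairs$strand2, pairs$strand1)
  orient_ok <- if (expected_orientation == "fr") {
    left_strand == "+" & right_strand == "-"
  } else {
    left_strand == "-" & right_strand == "+"
  }

  if (is.null(insert_bounds)) {
    insert_bounds <- estimate_insert_bounds(pairs$insert[orient_ok])
  }
  insert_ok <- pairs$insert >= insert_bounds[1] & pairs$insert <= insert_bounds[2]

  # split evidence: a supplementary placement whose primary carries a
  # soft-clip of at least min_clip (i.e. the smaller aligned piece is big
  # enough to be believed)
  supp_q <- unique(records$qname[records$supp])
  clip_q <- unique(records$qname[!records$supp &
                                   pmax(records$clip_lead,
                                        records$clip_trail) >= min_clip])
  split_q <- intersect(supp_q, clip_q)

  pairs$class <- ifelse(pairs$qname %in% split_q, "split",
                        ifelse(!orient_ok | !insert_ok, "discordant",
                               "concordant"))

  # reads whose mate never mapped
  orphans <- union(setdiff(r1$qname, r2$qname), setdiff(r2$qname, r1$qname))
  unmapped_q <- unique(records$qname[bitwAnd(records$flag, 4L) > 0L])
  bad <- union(orphans, unmapped_q)
  if (length(bad)) {
    extra <- data.frame(qname = bad, pos1 = NA_integer_, end1 = NA_integer_,
                        strand1 = NA_character_, pos2 = NA_integer_,
                        end2 = NA_integer_, strand2 = NA_character_,
                        library = NA_character_, insert = NA_integer_,
                        class = "unusable", stringsAsFactors = FALSE)
    pairs <- rbind(pairs[!pairs$qname %in% bad, ], extra)
  }
  attr(pairs, "insert_bounds") <- insert_bounds
  pairs
}

#' Empirical insert-size bounds
#'
#' Mean plus/minus `n_sd` standard deviations of the concordant-orientation
#' insert distribution; the default discordance cutoff when none is given.
#'
#' @param inserts Insert sizes of orientation-concordant pairs.
#' @param n_sd Number of standard deviations (default 3).
#' @return `c(lo, hi)`.
#' @export
estimate_insert_bounds <- function(inserts, n_sd = 3) {
  inserts <- inserts[is.finite(inserts)]
  if (!length(inserts)) return(c(0, Inf))
  m <- mean(inserts); s <- stats::sd(inserts)
  if (!is.finite(s)) s <- 0
  c(max(0, m - n_sd * s), m + n_sd * s)
}

#' Breakpoint evidence events from classified pairs
#'
#' Each split or discordant pair contributes one event per anchored side:
#' for split pairs, every aligned record (primary and supplementary) is an
#' anchor and carries its soft-clip position evidence; for discordant
#' pairs, each mate's primary alignment is an anchor. The event position is
#' the leftmost aligned reference base of the anchoring record. Clip
#' evidence is reported as `clip_high` (alignment soft-clipped at its
#' reference-high end, at coordinate `ref_end` — a candidate last-retained
#' 5' base) or `clip_low` (clipped at its low end, at `pos` — a candidate
#' first-retained 3' base).
#'
#' @param records Record data.frame.
#' @param pairs Output of [classify_pairs()].
#' @param min_clip Minimum soft-clip length counted as clip evidence.
#' @return A data.frame with columns `qname, type, pos, strand, clip_high,
#'   clip_low, library`.
#' @export
breakpoint_events <- function(records, pairs, min_clip = 20L) {
  split_q <- pairs$qname[pairs$class == "split"]
  disc_q <- pairs$qname[pairs$class == "discordant"]
  sr <- records[records$qname %in% split_q & bitwAnd(records$flag, 4L) == 0L, ]
  ev_split <- data.frame(
    qname = sr$qname, type = rep("split", nrow(sr)), pos = sr$pos,
    strand = sr$strand,
    clip_high = ifelse(sr$clip_trail >= min_clip, sr$ref_end, NA_integer_),
    clip_low = ifelse(sr$clip_lead >= min_clip, sr$pos, NA_integer_),
    library = sr$library, stringsAsFactors = FALSE, row.names = NULL)
  dr <- records[records$qname %in% disc_q & !records$supp, ]
  ev_disc <- data.frame(
    qname = dr$qname, type = rep("discordant", nrow(dr)), pos = dr$pos,
    strand = dr$strand,
    clip_high = rep(NA_integer_, nrow(dr)),
    clip_low = rep(NA_integer_, nrow(dr)),
    library = dr$library, stringsAsFactors = FALSE)
  ev <- rbind(ev_split, ev_disc)
  ev <- ev[order(ev$pos), ]
  rownames(ev) <- NULL
  ev
}

#' Remove events anchored in masked intervals
#'
#' @param events Event data.frame ([breakpoint_events()]).
#' @param mask Repeat/low-complexity mask: a [GenomicRanges::GRanges], a
#'   data.frame with `start`/`end` (1-based inclusive), or a BED file path
#'   (0-based half-open, read with [rtracklayer::import]).
#' @return Filtered events; the number removed is recorded in the
#'   `n_masked` attribute and reported with a message.
#' @export
mask_filter <- function(events, mask) {
  if (is.null(mask)) return(events)
  iv <- mask_intervals(mask)
  if (!nrow(iv) || !nrow(events)) {
    attr(events, "n_masked") <- 0L
    return(events)
  }
  hits <- IRanges::overlapsAny(IRanges::IRanges(events$pos, events$pos),
                               IRanges::IRanges(iv$start, iv$end))
  out <- events[!hits, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(hits)
  message(sum(hits), " events removed by mask")
  out
}

# normalise a mask argument to a 1-based inclusive interval data.frame
mask_intervals <- function(mask) {
  if (is.character(mask)) mask <- rtracklayer::import(mask)
  if (methods::is(mask, "GRanges")) {
    return(data.frame(start = BiocGenerics::start(mask),
                      end = BiocGenerics::end(mask)))
  }
  stopifnot(is.data.frame(mask), all(c("start", "end") %in% names(mask)))
  mask[, c("start", "end")]
}

#' Scan anchored events in fixed windows
#'
#' Tiles the chromosome in fixed, non-overlapping windows starting at
#' position 1 and counts split and discordant events per window by anchor
#' position. A window is a candidate iff its combined support is *strictly
#' greater* than `min_support` (the "more than 10 split or discordant read
#' pairs" rule, with both the window size and the threshold configurable).
#'
#' @param events Event data.frame.
#' @param window_size Window size in bp (default 1000).
#' @param min_support Support threshold; candidates require
#'   `support > min_support` (default 10).
#' @param chrom Chromosome name for the output (default from events if
#'   absent, `"chr"`).
#' @return Candidate windows: `chrom, start, end, n_split, n_discordant,
#'   support` (1-based inclusive coordinates).
#' @export
window_scan <- function(events, window_size = 1000L, min_support = 10L,
                        chrom = "chr") {
  if (!nrow(events)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_split = integer(), n_discordant = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  window_size <- as.integer(window_size)
  win <- (events$pos - 1L) %/% window_size
  n_split <- tapply(events$type == "split", win, sum)
  n_disc <- tapply(events$type == "discordant", win, sum)
  idx <- as.integer(names(n_split))
  out <- data.frame(chrom = chrom, start = idx * window_size + 1L,
                    end = (idx + 1L) * window_size,
                    n_split = as.integer(n_split),
                    n_discordant = as.integer(n_disc),
                    stringsAsFactors = FALSE)
  out$support <- out$n_split + out$n_discordant
  out <- out[out$support > min_support, , drop = FALSE]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Merge candidate windows into candidate regions
#'
#' Adjacent candidate windows (allowing up to `max_gap` empty windows
#' between them) are merged into one candidate region, so that the two
#' clip clusters of a junction with a sizeable deletion fall in the same
#' region.
#'
#' @param windows Output of [window_scan()].
#' @param window_size Window size used in the scan.
#' @param max_gap Maximum number of non-candidate windows bridged.
#' @return Regions: `region, chrom, start, end, n_windows, support`.
#' @export
candidate_regions <- function(windows, window_size = 1000L, max_gap = 2L) {
  if (!nrow(windows)) {
    return(data.frame(region = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  gap <- c(0L, diff(windows$start))
  new_region <- gap > (max_gap + 1L) * window_size
  rid <- cumsum(c(TRUE, new_region[-1]))
  data.frame(
    region = unique(rid),
    chrom = windows$chrom[!duplicated(rid)],
    start = as.integer(tapply(windows$start, rid, min)),
    end = as.integer(tapply(windows$end, rid, max)),
    n_windows = as.integer(tapply(windows$start, rid, length)),
    support = as.integer(tapply(windows$support, rid, sum)),
    stringsAsFactors = FALSE)
}

# assign event positions to candidate regions (NA when outside all)
region_of <- function(pos, regions) {
  idx <- findInterval(pos, regions$start)
  ok <- idx >= 1 & idx <= nrow(regions) & pos <= regions$end[pmax(idx, 1L)]
  ifelse(ok, regions$region[pmax(idx, 1L)], NA_integer_)
}

#' Link candidate regions through discordant mate pairs
#'
#' Two candidate regions are linked when at least `min_link` discordant
#' pairs have one mate anchored in each; links are stratified by the mate
#' strand pattern, so the distinct junctions of an inversion (which produce
#' +/+ and -/- discordant pairs) appear as separate links. The output is a
#' BEDPE-style table; candidate regions participating in no link are
#' reported one-sided by [call_breakpoints()].
#'
#' @param regions Output of [candidate_regions()].
#' @param events Event data.frame.
#' @param min_link Minimum discordant pairs per link.
#' @return Links: `chrom_a, start_a, end_a, chrom_b, start_b, end_b,
#'   region_a, region_b, strand_a, strand_b, n_pairs`.
#' @export
pair_junctions <- function(regions, events, min_link = 3L) {
  empty <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      region_a = integer(), region_b = integer(),
                      strand_a = character(), strand_b = character(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
  de <- events[events$type == "discordant", , drop = FALSE]
  if (!nrow(de) || !nrow(regions)) return(empty)
  de$region <- region_of(de$pos, regions)
  de <- de[!is.na(de$region), ]
  de <- de[order(de$qname, de$pos), ]
  # keep pairs with both mates in (different) regions
  cnt <- table(de$qname)
  both <- names(cnt)[cnt == 2L]
  de <- de[de$qname %in% both, ]
  if (!nrow(de)) return(empty)
  first <- de[!duplicated(de$qname), ]
  second <- de[duplicated(de$qname), ]
  second <- second[match(first$qname, second$qname), ]
  diffreg <- first$region != second$region
  first <- first[diffreg, ]; second <- second[diffreg, ]
  if (!nrow(first)) return(empty)
  key <- paste(first$region, second$region, first$strand, second$strand,
               sep = "|")
  tab <- table(key)
  tab <- tab[tab >= min_link]
  if (!length(tab)) return(empty)
  parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  ra <- as.integer(parts[, 1]); rb <- as.integer(parts[, 2])
  ia <- match(ra, regions$region); ib <- match(rb, regions$region)
  data.frame(chrom_a = regions$chrom[ia], start_a = regions$start[ia],
             end_a = regions$end[ia], chrom_b = regions$chrom[ib],
             start_b = regions$start[ib], end_b = regions$end[ib],
             region_a = ra, region_b = rb,
             strand_a = parts[, 3], strand_b = parts[, 4],
             n_pairs = as.integer(tab), stringsAsFactors = FALSE)
}

#' Refine a candidate region to a base-pair breakpoint call
#'
#' Takes the soft-clip consensus on each side of the junction: the modal
#' reference-high clip position is the 5' retained base, the modal
#' reference-low clip position the 3' retained base; the junction delta
#' follows from [junction_delta()]. Ties in the consensus break toward the
#' smaller coordinate and are flagged ambiguous with the competing mode
#' reported. With no usable split reads the call falls back to window-level
#' resolution at the region midpoint, with no delta. When the reference
#' sequence is supplied, the microhomology at the junction (identical bases
#' immediately flanking both retained ends) is reported.
#'
#' @param region One row of [candidate_regions()].
#' @param events Event data.frame (the whole set; the region's events are
#'   selected internally).
#' @param refseq Optional reference [Biostrings::DNAString] for
#'   microhomology.
#' @return One-row data.frame: `chrom, region, five_prime, three_prime,
#'   delta, resolution, n_split, n_discordant, microhomology, ambiguous,
#'   alt_five_prime, alt_three_prime`.
#' @export
refine_breakpoint <- function(region, events, refseq = NULL) {
  ev <- events[events$pos >= region$start & events$pos <= region$end |
                 (!is.na(events$clip_high) & events$clip_high >= region$start &
                    events$clip_high <= region$end), , drop = FALSE]
  highs <- ev$clip_high[!is.na(ev$clip_high)]
  lows <- ev$clip_low[!is.na(ev$clip_low)]
  n_split <- length(unique(ev$qname[ev$type == "split"]))
  n_disc <- length(unique(ev$qname[ev$type == "discordant"]))
  mode2 <- function(x) {
    if (!length(x)) return(list(val = NA_integer_, alt = NA_integer_))
    tab <- sort(table(x), decreasing = TRUE)
    vals <- as.integer(names(tab))
    if (length(tab) > 1 && tab[2] == tab[1]) {
      tied <- sort(vals[tab == tab[1]])
      list(val = tied[1], alt = tied[2])
    } else list(val = vals[1], alt = NA_integer_)
  }
  h <- mode2(highs); l <- mode2(lows)
  if (!is.na(h$val) && !is.na(l$val)) {
    five <- h$val; three <- l$val
    out <- data.frame(chrom = region$chrom, region = region$region,
                      five_prime = five, three_prime = three,
                      delta = junction_delta(five, three),
                      resolution = "bp", n_split = n_split,
                      n_discordant = n_disc,
                      microhomology = if (!is.null(refseq))
                        microhomology(refseq, five, three) else NA_integer_,
                      ambiguous = !is.na(h$alt) || !is.na(l$alt),
                      alt_five_prime = h$alt, alt_three_prime = l$alt,
                      stringsAsFactors = FALSE)
  } else {
    mid <- as.integer((region$start + region$end) %/% 2L)
    out <- data.frame(chrom = region$chrom, region = region$region,
                      five_prime = mid, three_prime = mid,
                      delta = NA_integer_, resolution = "window",
                      n_split = n_split, n_discordant = n_disc,
                      microhomology = NA_integer_, ambiguous = FALSE,
                      alt_five_prime = NA_integer_,
                      alt_three_prime = NA_integer_, stringsAsFactors = FALSE)
  }
  out
}

# identical bases immediately flanking both retained junction ends
microhomology <- function(refseq, five, three, max_check = 50L) {
  refseq <- Biostrings::DNAString(refseq)
  k <- 0L
  while (k < max_check && five - k >= 1L && three - 1L - k >= 1L &&
         as.character(refseq[five - k]) ==
         as.character(refseq[three - 1L - k])) {
    k <- k + 1L
  }
  k
}

#' Call inversion breakpoints from aligned read-pair records
#'
#' The full caller: classify pairs (per library), collect anchored events,
#' apply the repeat mask and optional prior regions, scan 1-kb windows with
#' the more-than-`min_support` rule, merge candidate windows into regions,
#' refine each region to a base-pair junction call by soft-clip consensus,
#' and link regions through discordant mates.
#'
#' @param records Record data.frame or a SAM/BAM path.
#' @param mask Optional repeat mask (see [mask_filter()]).
#' @param priors Optional prior-regions restriction (same formats as
#'   `mask`): only events anchored inside a prior region are considered;
#'   absent the file, the whole chromosome is scanned.
#' @param window_size,min_support Window-scan parameters ("1-kb windows,
#'   more than 10 split or discordant read pairs" by default).
#' @param min_clip Minimum soft-clip length for split evidence.
#' @param min_link Minimum discordant pairs linking two regions.
#' @param max_gap Maximum empty windows bridged when merging regions.
#' @param insert_bounds Optional fixed insert bounds (otherwise estimated
#'   per library).
#' @param refseq Optional reference sequence for microhomology.
#' @return A list of class `breakpoint_calls`: `junctions` (one row per
#'   called junction), `windows`, `regions`, `links`, `pairs`, `events`,
#'   and `params`.
#' @export
call_breakpoints <- function(records, mask = NULL, priors = NULL,
                             window_size = 1000L, min_support = 10L,
                             min_clip = 20L, min_link = 3L, max_gap = 2L,
                             insert_bounds = NULL, refseq = NULL) {
  if (is.character(records)) records <- read_sam(records)
  chrom <- if (nrow(records)) records$rname[1] else "chr"

  # classification pooled across libraries, insert bounds per library
  libs <- unique(records$library)
  pairs <- do.call(rbind, lapply(libs, function(lb) {
    sel <- if (is.na(lb)) is.na(records$library) else
      !is.na(records$library) & records$library == lb
    classify_pairs(records[sel, , drop = FALSE],
                   insert_bounds = insert_bounds, min_clip = min_clip)
  }))

  events <- breakpoint_events(records, pairs, min_clip = min_clip)
  if (!is.null(mask)) events <- mask_filter(events, mask)
  if (!is.null(priors)) {
    iv <- mask_intervals(priors)
    keep <- IRanges::overlapsAny(IRanges::IRanges(events$pos, events$pos),
                                 IRanges::IRanges(iv$start, iv$end))
    events <- events[keep, , drop = FALSE]
  }

  windows <- window_scan(events, window_size = window_size,
                         min_support = min_support, chrom = chrom)
  regions <- candidate_regions(windows, window_size = window_size,
                               max_gap = max_gap)
  junctions <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    refine_breakpoint(regions[i, ], events, refseq = refseq)
  }))
  if (is.null(junctions)) {
    junctions <- data.frame(chrom = character(), region = integer(),
                            five_prime = integer(), three_prime = integer(),
                            delta = integer(), resolution = character(),
                            n_split = integer(), n_discordant = integer(),
                            microhomology = integer(), ambiguous = logical(),
                            alt_five_prime = integer(),
                            alt_three_prime = integer(),
                            stringsAsFactors = FALSE)
  }
  links <- pair_junctions(regions, events, min_link = min_link)
  structure(list(junctions = junctions, windows = windows, regions = regions,
                 links = links, pairs = pairs, events = events,
                 params = list(window_size = window_size,
                               min_support = min_support,
                               min_clip = min_clip, min_link = min_link,
                               max_gap = max_gap)),
            class = "breakpoint_calls")
}

#' @export
print.breakpoint_calls <- function(x, ...) {
  cat("breakpoint_calls:", nrow(x$junctions), "junctions from",
      nrow(x$regions), "candidate regions,", nrow(x$links), "links\n")
  if (nrow(x$junctions)) print(x$junctions, row.names = FALSE)
  invisible(x)
}

#' Export called junctions
#'
#' `"tsv"` mirrors the published junction-table schema; `"bedpe"` writes
#' the region links as paired intervals (0-based half-open); `"vcf"` writes
#' BND-style breakend records.
#'
#' @param calls A `breakpoint_calls` object.
#' @param path Output path.
#' @param format One of `"tsv"`, `"bedpe"`, `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(calls, path, format = c("tsv", "bedpe", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls$junctions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "bedpe") {
    lk <- calls$links
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tlink%d\t%d\t%s\t%s",
                     lk$chrom_a, lk$start_a - 1L, lk$end_a,
                     lk$chrom_b, lk$start_b - 1L, lk$end_b,
                     seq_len(nrow(lk)), lk$n_pairs, lk$strand_a, lk$strand_b)
    writeLines(lines, path)
  } else {
    jx <- calls$junctions
    lines <- c("##fileformat=VCFv4.2",
               "##ALT=<ID=BND,Description=\"Breakend\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=DELTA,Number=1,Type=Integer,Description=\"Junction delta\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    if (nrow(jx)) {
      lines <- c(lines, sprintf(
        "%s\t%d\tbnd%d\tN\tN[%s:%d[\t.\t.\tSVTYPE=BND;DELTA=%s",
        jx$chrom, jx$five_prime, seq_len(nrow(jx)), jx$chrom,
        jx$three_prime, ifelse(is.na(jx$delta), ".", jx$delta)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
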