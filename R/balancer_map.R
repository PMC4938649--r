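#' Segment map of a rearranged (balancer) chromosome
#'
#' A `balancer_map` describes a derived chromosome as an ordered list of
#' reference segments, each carried in `+` or `-` orientation, together with
#' the junctions created between consecutive segments. Segments tile the
#' derived chromosome with no gaps; the derived length equals the reference
#' length plus the sum of the signed junction deltas (bases deleted at a cut
#' are absent from every segment, duplicated bases appear in two segments).
#'
#' All coordinates are 1-based inclusive. BED interchange converts to
#' 0-based half-open at the I/O boundary only.
#'
#' @param chrom Chromosome name.
#' @param ref_length Reference chromosome length in bp.
#' @return A `balancer_map` object representing the identity map.
#' @export
balancer_map <- function(chrom, ref_length) {
  ref_length <- as.integer(ref_length)
  stopifnot(ref_length >= 1)
  structure(list(
    chrom = chrom,
    ref_length = ref_length,
    segments = data.frame(ref_start = 1L, ref_end = ref_length,
                          strand = "+", stringsAsFactors = FALSE),
    junctions = empty_junctions()
  ), class = "balancer_map")
}

empty_junctions <- function() {
  data.frame(event = character(), chrom = character(),
             five_prime = integer(), three_prime = integer(),
             delta = integer(), stringsAsFactors = FALSE)
}

#' @export
print.balancer_map <- function(x, ...) {
  cat("balancer_map:", x$chrom, "\n")
  cat("  reference length:", x$ref_length, "bp; derived length:",
      derived_length(x), "bp\n")
  cat("  segments:", nrow(x$segments), " junctions:", nrow(x$junctions), "\n")
  if (nrow(x$junctions)) print(x$junctions, row.names = FALSE)
  invisible(x)
}

#' Derived chromosome length of a balancer map
#' @param map A `balancer_map`.
#' @return Integer length in bp.
#' @export
derived_length <- function(map) {
  sum(map$segments$ref_end - map$segments$ref_start + 1L)
}

# cumulative derived start of each segment
seg_dstarts <- function(map) {
  len <- map$segments$ref_end - map$segments$ref_start + 1L
  cumsum(c(1L, len))[seq_along(len)]
}

# internal: segments covering derived interval [a, b], clipped
derived_slice <- function(map, a, b) {
  stopifnot(a >= 1, b >= a, b <= derived_length(map))
  segs <- map$segments
  ds <- seg_dstarts(map)
  de <- ds + (segs$ref_end - segs$ref_start)
  keep <- which(de >= a & ds <= b)
  out <- segs[keep, , drop = FALSE]
  for (i in seq_along(keep)) {
    k <- keep[i]
    lo <- max(a, ds[k]) - ds[k]   # 0-based offsets into the segment
    hi <- min(b, de[k]) - ds[k]
    if (segs$strand[k] == "+") {
      out$ref_start[i] <- segs$ref_start[k] + lo
      out$ref_end[i] <- segs$ref_start[k] + hi
    } else {
      out$ref_start[i] <- segs$ref_end[k] - hi
      out$ref_end[i] <- segs$ref_end[k] - lo
    }
  }
  rownames(out) <- NULL
  out
}

# internal: reverse a segment slice (flip order and orientation)
rev_slice <- function(segs) {
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  rownames(segs) <- NULL
  segs
}

#' Describe a rearrangement event
#'
#' A rearrangement is a set of cuts on the current derived chromosome. Each
#' cut is a `(five_prime, three_prime)` coordinate pair in the derived
#' frame: the last retained base before the cut and the first retained base
#' after it, so that each cut can carry a local deletion
#' (`three_prime > five_prime + 1`) or duplication
#' (`three_prime <= five_prime`); see [junction_delta()].
#'
#' A 2-cut event inverts the interval between the cuts. A 3-cut event
#' inverts each of the two internal segments in place (the A-B'-C'-D
#' pattern), creating three novel junctions — the configuration observed for
#' three-breakpoint rearrangements such as In(3R)Hu, whose two internal
#' segments are both inverted.
#'
#' @param name Event label (e.g. an inversion name).
#' @param cuts List of 2 or 3 numeric pairs `c(five_prime, three_prime)`,
#'   ordered along the chromosome.
#' @param type `"inversion"` (2 cuts) or `"three_break"` (3 cuts); inferred
#'   from `length(cuts)` when omitted.
#' @return A `rearrangement` object.
#' @export
rearrangement <- function(name, cuts, type = NULL) {
  if (is.null(type)) type <- if (length(cuts) == 3) "three_break" else "inversion"
  n <- switch(type, inversion = 2L, three_break = 3L,
              stop("unknown rearrangement type: ", type))
  if (length(cuts) != n) {
    stop("invalid event: ", type, " requires ", n, " cuts")
  }
  cuts <- lapply(cuts, function(ct) {
    ct <- as.integer(ct)
    if (length(ct) != 2 || any(ct < 1)) {
      stop("invalid event: each cut is c(five_prime, three_prime), both >= 1")
    }
    ct
  })
  fives <- vapply(cuts, `[`, integer(1), 1L)
  if (is.unsorted(fives, strictly = TRUE)) {
    stop("invalid event: cuts must be ordered along the chromosome")
  }
  structure(list(name = name, type = type, cuts = cuts,
                 n_breakpoints = n), class = "rearrangement")
}

#' @export
print.rearrangement <- function(x, ...) {
  cat("rearrangement", x$name, "(", x$type, "):\n")
  for (ct in x$cuts) {
    cat(sprintf("  cut %d|%d  delta %+d\n", ct[1], ct[2],
                junction_delta(ct[1], ct[2])))
  }
  invisible(x)
}

# record a junction in reference coordinates for a derived-frame cut
cut_junction <- function(map, event_name, five_d, three_d) {
  f <- lift_to_reference(map, five_d)
  t <- lift_to_reference(map, three_d)
  data.frame(event = event_name, chrom = map$chrom,
             five_prime = f$ref, three_prime = t$ref,
             delta = junction_delta(five_d, three_d),
             stringsAsFactors = FALSE)
}

#' Apply a rearrangement to a balancer map
#'
#' Cuts are expressed in the current derived frame, so events superimposed
#' sequentially (the way balancer histories are built) compose naturally.
#' The input map is unchanged; a new map is returned with the interval(s)
#' between cuts reversed and the new junctions recorded in reference
#' coordinates.
#'
#' @param map A `balancer_map`.
#' @param event A [rearrangement()].
#' @return A new `balancer_map`.
#' @export
apply_rearrangement <- function(map, event) {
  stopifnot(inherits(map, "balancer_map"), inherits(event, "rearrangement"))
  L <- derived_length(map)
  cuts <- event$cuts
  ok <- all(vapply(cuts, function(ct) all(ct >= 1 & ct <= L), logical(1)))
  if (!ok) stop("invalid event: cut coordinate out of bounds [1, ", L, "]")

  if (event$type == "inversion") {
    f1 <- cuts[[1]][1]; t1 <- cuts[[1]][2]
    f2 <- cuts[[2]][1]; t2 <- cuts[[2]][2]
    if (t1 > f2 || f1 >= f2) stop("invalid event: cuts unordered within the event")
    jx <- rbind(cut_junction(map, event$name, f1, t1),
                cut_junction(map, event$name, f2, t2))
    segs <- rbind(derived_slice(map, 1L, f1),
                  rev_slice(derived_slice(map, t1, f2)),
                  derived_slice(map, t2, L))
  } else {
    f1 <- cuts[[1]][1]; t1 <- cuts[[1]][2]
    f2 <- cuts[[2]][1]; t2 <- cuts[[2]][2]
    f3 <- cuts[[3]][1]; t3 <- cuts[[3]][2]
    if (t1 > f2 || t2 > f3) stop("invalid event: cuts unordered within the event")
    jx <- rbind(cut_junction(map, event$name, f1, t1),
                cut_junction(map, event$name, f2, t2),
                cut_junction(map, event$name, f3, t3))
    segs <- rbind(derived_slice(map, 1L, f1),
                  rev_slice(derived_slice(map, t1, f2)),
                  rev_slice(derived_slice(map, t2, f3)),
                  derived_slice(map, t3, L))
  }
  out <- map
  out$segments <- segs
  rownames(out$segments) <- NULL
  out$junctions <- rbind(map$junctions, jx)
  out
}

#' Apply an ordered karyotype (list of rearrangements)
#'
#' @param map A `balancer_map` (usually the identity map).
#' @param karyotype List of [rearrangement()] objects, applied in order.
#' @return The resulting `balancer_map`.
#' @export
apply_karyotype <- function(map, karyotype) {
  for (ev in karyotype) map <- apply_rearrangement(map, ev)
  map
}

#' Lift derived coordinates to the reference
#'
#' Maps positions on the derived (balancer) chromosome to the underlying
#' reference base and reports whether the containing segment is inverted.
#' Positions inside duplicated bases map to the duplicated reference base;
#' reference bases deleted at a junction are unreachable.
#'
#' @param map A `balancer_map`.
#' @param pos Vector of 1-based derived coordinates.
#' @return A data.frame with columns `ref` (1-based reference coordinate)
#'   and `orientation` (`"+"` or `"-"`).
#' @export
lift_to_reference <- function(map, pos) {
  pos <- as.integer(pos)
  L <- derived_length(map)
  if (any(is.na(pos)) || any(pos < 1) || any(pos > L)) {
    stop("invalid coordinate: derived position out of range [1, ", L, "]")
  }
  segs <- map$segments
  ds <- seg_dstarts(map)
  idx <- findInterval(pos, ds)
  off <- pos - ds[idx]
  plus <- segs$strand[idx] == "+"
  ref <- ifelse(plus, segs$ref_start[idx] + off, segs$ref_end[idx] - off)
  data.frame(ref = as.integer(ref),
             orientation = ifelse(plus, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Lift reference coordinates to the derived chromosome
#'
#' Inverse of [lift_to_reference()] on non-duplicated bases. Duplicated
#' reference bases map to their first (leftmost derived) occurrence; deleted
#' reference bases return `NA`.
#'
#' @param map A `balancer_map`.
#' @param refpos Vector of 1-based reference coordinates.
#' @return Integer vector of derived coordinates (`NA` where deleted).
#' @export
lift_to_derived <- function(map, refpos) {
  refpos <- as.integer(refpos)
  if (any(is.na(refpos)) || any(refpos < 1) || any(refpos > map$ref_length)) {
    stop("invalid coordinate: reference position out of range")
  }
  segs <- map$segments
  ds <- seg_dstarts(map)
  out <- rep(NA_integer_, length(refpos))
  for (k in seq_len(nrow(segs))) {
    hit <- is.na(out) & refpos >= segs$ref_start[k] & refpos <= segs$ref_end[k]
    if (!any(hit)) next
    if (segs$strand[k] == "+") {
      out[hit] <- ds[k] + (refpos[hit] - segs$ref_start[k])
    } else {
      out[hit] <- ds[k] + (segs$ref_end[k] - refpos[hit])
    }
  }
  out
}

#' Construct the derived chromosome sequence
#'
#' Concatenates the reference segments of the map in derived order, taking
#' the reverse complement of inverted segments.
#'
#' @param map A `balancer_map`.
#' @param refseq Reference sequence as a [Biostrings::DNAString] (or
#'   anything coercible).
#' @return A [Biostrings::DNAString] of length `derived_length(map)`.
#' @export
derived_seq <- function(map, refseq) {
  refseq <- Biostrings::DNAString(refseq)
  stopifnot(length(refseq) == map$ref_length)
  pieces <- Biostrings::DNAStringSet(lapply(seq_len(nrow(map$segments)), function(k) {
    s <- Biostrings::subseq(refseq, map$segments$ref_start[k],
                            map$segments$ref_end[k])
    if (map$segments$strand[k] == "-") Biostrings::reverseComplement(s) else s
  }))
  unlist(pieces)
}

#' Junction table of a balancer map
#'
#' One row per cut, mirroring the published table schema: event, chromosome,
#' 5' break, 3' break, signed delta.
#'
#' @param map A `balancer_map`.
#' @return A data.frame.
#' @export
junction_table <- function(map) {
  map$junctions
}

#' Write or read a karyotype configuration
#'
#' The karyotype file is a plain-text (YAML) description of a derived
#' chromosome: chromosome name, reference length, and the rearrangements in
#' application order, each with its cut coordinate pairs.
#'
#' @param karyotype List of [rearrangement()] objects.
#' @param chrom,ref_length Chromosome name and reference length recorded in
#'   the file.
#' @param path File path.
#' @return `read_karyotype` returns a list with elements `chrom`,
#'   `ref_length` and `events` (a list of [rearrangement()]).
#' @export
write_karyotype <- function(karyotype, chrom, ref_length, path) {
  cfg <- list(
    chrom = chrom,
    ref_length = as.integer(ref_length),
    events = lapply(karyotype, function(ev) {
      list(name = ev$name, type = ev$type,
           cuts = lapply(ev$cuts, as.integer))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$chrom), !is.null(cfg$ref_length))
  events <- lapply(cfg$events, function(ev) {
    rearrangement(ev$name, ev$cuts, type = ev$type)
  })
  list(chrom = cfg$chrom, ref_length = as.integer(cfg$ref_length),
       events = events)
}
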