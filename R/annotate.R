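#' Load gene models from GFF3
#'
#' Reads a GFF3 file (via [rtracklayer::import]) into the simple gene-model
#' tables used by the annotator: genes, transcripts (isoforms), exons and
#' CDS intervals, linked by ID/Parent.
#'
#' @param path GFF3 file.
#' @return A `gene_models` list: `genes` (id, name, chrom, start, end,
#'   strand), `transcripts` (id, gene, start, end, strand), `exons` and
#'   `cds` (tx, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) p[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  name <- if ("Name" %in% names(md)) as.character(md$Name) else id
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = typ, id = id, name = name, parent = parent,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", c("id", "name", "chrom", "start", "end", "strand")]
  tx <- df[df$type %in% c("mRNA", "transcript", "ncRNA"), ]
  transcripts <- data.frame(id = tx$id, gene = tx$parent, start = tx$start,
                            end = tx$end, strand = tx$strand,
                            stringsAsFactors = FALSE)
  exons <- df[df$type == "exon", c("parent", "start", "end")]
  names(exons)[1] <- "tx"
  cds <- df[df$type == "CDS", c("parent", "start", "end")]
  names(cds)[1] <- "tx"
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds), class = "gene_models")
}

# exon/intron index of a coordinate within one transcript, numbered along
# the transcript (strand-aware, 1-based)
feature_index <- function(exons, strand, pos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  order_idx <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  for (j in seq_len(n)) {
    k <- order_idx[j]
    if (pos >= exons$start[k] && pos <= exons$end[k]) {
      return(list(feature = "exon", index = j))
    }
  }
  if (n > 1) {
    for (j in seq_len(n - 1)) {
      # intron j lies between transcript-order exons j and j+1
      k1 <- order_idx[j]; k2 <- order_idx[j + 1]
      a <- if (strand == "-") exons$end[k2] + 1L else exons$end[k1] + 1L
      b <- if (strand == "-") exons$start[k1] - 1L else exons$start[k2] - 1L
      if (pos >= a && pos <= b) return(list(feature = "intron", index = j))
    }
  }
  list(feature = NA_character_, index = NA_integer_)
}

#' Annotate breakpoints against gene models
#'
#' Labels each breakpoint coordinate with the gene whose span contains it.
#' A coordinate strictly inside a gene span "bisects" the gene; exactly at
#' a span edge it is reported as `"boundary"`; outside all genes it is
#' `"Intergenic"`. For bisected genes, the number and ids of isoforms whose
#' span contains the breakpoint are reported, with the containing
#' exon/intron index per isoform (transcript-order numbering). Genes whose
#' whole span falls inside a junction's deleted interval are reported as
#' `"deleted"`. Overlapping genes that all contain the breakpoint are all
#' reported, sorted by name.
#'
#' @param junctions Data.frame with `chrom`, `five_prime`, `three_prime`
#'   (e.g. [junction_table()] or [call_breakpoints()] junctions).
#' @param models A `gene_models` object.
#' @return A data.frame, one row per junction-gene relation (or one
#'   Intergenic row): `chrom, five_prime, three_prime, gene, relation,
#'   n_isoforms_affected, isoforms, features`.
#' @export
intersect_breakpoints <- function(junctions, models) {
  stopifnot(inherits(models, "gene_models"))
  out <- list()
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    coords <- sort(unique(c(jx$five_prime, jx$three_prime)))
    g <- models$genes[models$genes$chrom == jx$chrom, , drop = FALSE]
    rows <- list()
    # genes wholly removed by the junction's deletion
    if (jx$three_prime > jx$five_prime + 1L) {
      del <- g[g$start > jx$five_prime & g$end < jx$three_prime, , drop = FALSE]
      for (k in seq_len(nrow(del))) {
        rows[[length(rows) + 1L]] <- list(gene = del$name[k],
                                          relation = "deleted",
                                          n_iso = NA_integer_, iso = "",
                                          feat = "")
      }
    }
    for (pos in coords) {
      inside <- g$start < pos & pos < g$end
      edge <- g$start == pos | g$end == pos
      hit <- g[inside | edge, , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        if (any(vapply(rows, function(r) identical(r$gene, hit$name[k]) &&
                         r$relation != "deleted", logical(1)))) next
        relation <- if (hit$start[k] < pos && pos < hit$end[k]) "bisected"
                    else "boundary"
        tx <- models$transcripts[models$transcripts$gene == hit$id[k] &
                                   models$transcripts$start <= pos &
                                   models$transcripts$end >= pos, ,
                                 drop = FALSE]
        feats <- character(0)
        for (t in seq_len(nrow(tx))) {
          ex <- models$exons[models$exons$tx == tx$id[t], , drop = FALSE]
          fi <- feature_index(ex, tx$strand[t], pos)
          feats <- c(feats, paste0(tx$id[t], ":", fi$feature, fi$index))
        }
        rows[[length(rows) + 1L]] <- list(gene = hit$name[k],
                                          relation = relation,
                                          n_iso = nrow(tx),
                                          iso = paste(tx$id, collapse = ","),
                                          feat = paste(feats, collapse = ","))
      }
    }
    if (!length(rows)) {
      rows[[1]] <- list(gene = "Intergenic", relation = "intergenic",
                        n_iso = NA_integer_, iso = "", feat = "")
    }
    ord <- order(vapply(rows, `[[`, character(1), "gene"))
    for (r in rows[ord]) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = jx$chrom, five_prime = jx$five_prime,
        three_prime = jx$three_prime, gene = r$gene, relation = r$relation,
        n_isoforms_affected = r$n_iso, isoforms = r$iso, features = r$feat,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), five_prime = integer(),
                      three_prime = integer(), gene = character(),
                      relation = character(), n_isoforms_affected = integer(),
                      isoforms = character(), features = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Classify a deletion against coding sequence
#'
#' Computes the deleted coding length `L` (overlap of the interval with the
#' CDS intervals) and classifies the deletion as in-frame iff
#' `L mod 3 == 0`, reporting the codon count `L / 3` for in-frame
#' deletions. An interval with no CDS overlap is `"noncoding"` (no framing
#' call). Coordinates are 1-based inclusive, so the interval length itself
#' is `end - start + 1`.
#'
#' @param start,end Deletion interval (1-based inclusive).
#' @param cds Data.frame of CDS intervals with `start`/`end` columns (e.g.
#'   the `cds` table of a `gene_models`, possibly filtered to one
#'   transcript).
#' @return A one-row data.frame: `start, end, length, cds_removed, class,
#'   codons`.
#' @export
classify_deletion <- function(start, end, cds) {
  stopifnot(end >= start)
  L <- 0L
  for (k in seq_len(nrow(cds))) {
    L <- L + max(0L, min(end, cds$end[k]) - max(start, cds$start[k]) + 1L)
  }
  cls <- if (L == 0L) "noncoding" else if (L %% 3L == 0L) "in-frame" else
    "frameshift"
  data.frame(start = start, end = end, length = end - start + 1L,
             cds_removed = L, class = cls,
             codons = if (cls == "in-frame") L %/% 3L else NA_integer_,
             stringsAsFactors = FALSE)
}
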