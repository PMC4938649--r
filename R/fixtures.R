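#' Build toy gene models around junction coordinates
#'
#' Constructs a small annotation set for a simulated chromosome: a
#' single-isoform gene deliberately spanning the first junction (so the
#' annotator reports it bisected), a four-isoform gene whose isoforms all
#' span the second junction inside their fifth intron (mimicking a
#' breakpoint that hits every isoform of a multi-isoform tumour-suppressor
#' locus), and an intergenic control region. Exons are 100 bp with 200-bp
#' introns; every CDS length is a multiple of 3.
#'
#' @param junctions Junction table (`five_prime` used as anchor
#'   coordinates; at least 2 rows).
#' @param chrom Chromosome name.
#' @return A list: `models` (a `gene_models` object) and `gr` (a
#'   [GenomicRanges::GRanges] ready for GFF3 export).
#' @export
make_toy_genes <- function(junctions, chrom = "chrS") {
  stopifnot(nrow(junctions) >= 2)
  feats <- list()
  add <- function(type, start, end, id, parent = NA, name = NA,
                  strand = "+") {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = as.integer(start), end = as.integer(end),
      id = id, parent = parent, name = name, strand = strand,
      stringsAsFactors = FALSE)
  }

  # gene A: one isoform, 3 exons, spans junction 1
  j1 <- junctions$five_prime[1]
  a0 <- j1 - 450L
  add("gene", a0, a0 + 1000L, "geneA", name = "bisectA")
  add("mRNA", a0, a0 + 1000L, "geneA.t1", parent = "geneA")
  for (e in 0:2) {
    es <- a0 + e * 300L
    add("exon", es, es + 99L, paste0("geneA.t1.e", e + 1), parent = "geneA.t1")
    add("CDS", es, es + 98L, paste0("geneA.t1.c", e + 1), parent = "geneA.t1")
  }

  # gene B: four isoforms, 7 exons each, junction 2 in intron 5 of all
  j2 <- junctions$five_prime[2]
  # exon k occupies [b0 + (k-1)*300, +99]; intron 5 is (b0+4*300+100, b0+5*300)
  b0 <- j2 - 4L * 300L - 150L   # junction falls 50 bp into intron 5
  for (t in 1:4) {
    off <- (t - 1L) * 10L       # slight per-isoform 5' offsets
    add("mRNA", b0 + off, b0 + 6L * 300L + 99L, paste0("geneB.t", t),
        parent = "geneB")
    for (e in 0:6) {
      es <- b0 + e * 300L + if (e == 0) off else 0L
      ee <- b0 + e * 300L + 99L
      add("exon", es, ee, paste0("geneB.t", t, ".e", e + 1),
          parent = paste0("geneB.t", t))
    }
  }
  add("gene", b0, b0 + 6L * 300L + 99L, "geneB", name = "multi5")

  df <- do.call(rbind, feats)
  df <- df[order(df$start, df$type != "gene"), ]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "balancerseq"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Name <- df$name
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)

  genes <- df[df$type == "gene", ]
  tx <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", c("parent", "start", "end")]
  names(exons)[1] <- "tx"
  cds <- df[df$type == "CDS", c("parent", "start", "end")]
  names(cds)[1] <- "tx"
  models <- structure(list(
    genes = data.frame(id = genes$id,
                       name = ifelse(is.na(genes$name), genes$id, genes$name),
                       chrom = chrom, start = genes$start, end = genes$end,
                       strand = genes$strand, stringsAsFactors = FALSE),
    transcripts = data.frame(id = tx$id, gene = tx$parent, start = tx$start,
                             end = tx$end, strand = tx$strand,
                             stringsAsFactors = FALSE),
    exons = exons, cds = cds), class = "gene_models")
  list(models = models, gr = gr)
}

#' Emit simulation fixture files
#'
#' Writes, in standard plain-text formats, the side inputs the real
#' analysis consumes plus the simulation truth: a repeat-mask BED (0-based
#' half-open; empty when no intervals are configured), toy gene models as
#' GFF3 ([make_toy_genes()], one gene deliberately spanning a junction),
#' and the truth tables (junctions, crossover tracts) as TSV.
#'
#' @param panel Result of [derive_panel()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used.
#' @param mask_intervals Optional data.frame of 1-based inclusive mask
#'   intervals (`start`, `end`); `NULL` writes an empty BED.
#' @return Named list of file paths: `mask`, `genes`, `truth_junctions`,
#'   `truth_tracts`.
#' @export
emit_fixtures <- function(panel, dir, config, mask_intervals = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mask = file.path(dir, "mask.bed"),
                genes = file.path(dir, "genes.gff3"),
                truth_junctions = file.path(dir, "truth_junctions.tsv"),
                truth_tracts = file.path(dir, "truth_tracts.tsv"))
  if (is.null(mask_intervals) || !nrow(mask_intervals)) {
    writeLines(character(0), paths$mask)
  } else {
    gr <- GenomicRanges::GRanges(config$chrom,
                                 IRanges::IRanges(mask_intervals$start,
                                                  mask_intervals$end))
    rtracklayer::export(gr, paths$mask, format = "BED")
  }
  toy <- make_toy_genes(panel$truth$junctions, config$chrom)
  rtracklayer::export(toy$gr, paths$genes, format = "GFF3")
  utils::write.table(panel$truth$junctions, paths$truth_junctions,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$tracts, paths$truth_tracts,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
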