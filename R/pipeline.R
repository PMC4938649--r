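#' Pipeline configuration
#'
#' Collects the stage parameters of the full analysis (simulate, call
#' breakpoints, call tracts, annotate, report) in one object that
#' round-trips through a plain-text YAML file, so a whole run is
#' reproducible from the config and seed alone.
#'
#' @param outdir Output directory.
#' @param sim A [sim_config()] (its seed drives every stage).
#' @param stages Character vector of stages to run, in order; a prefix of
#'   `c("simulate", "callbp", "tracts", "annotate", "report")`.
#' @param window_size,min_support,min_clip,min_link,max_gap Breakpoint
#'   caller parameters (see [call_breakpoints()]).
#' @param qual_min,max_share,tract_window,min_windows,tract_max_gap SNP
#'   panel and tract-calling parameters (see [load_panel()],
#'   [rare_snp_windows()], [call_tracts()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, sim = sim_config(),
                            stages = c("simulate", "callbp", "tracts",
                                       "annotate", "report"),
                            window_size = 1000L, min_support = 10L,
                            min_clip = 20L, min_link = 3L, max_gap = 2L,
                            qual_min = 200, max_share = 5L,
                            tract_window = 10000L, min_windows = 3L,
                            tract_max_gap = 2L) {
  allowed <- c("simulate", "callbp", "tracts", "annotate", "report")
  stopifnot(all(stages %in% allowed),
            window_size >= 100, min_support >= 0, qual_min >= 0,
            max_share >= 0, tract_window >= 100)
  structure(list(outdir = outdir, sim = sim, stages = stages,
                 window_size = as.integer(window_size),
                 min_support = as.integer(min_support),
                 min_clip = as.integer(min_clip),
                 min_link = as.integer(min_link),
                 max_gap = as.integer(max_gap), qual_min = qual_min,
                 max_share = as.integer(max_share),
                 tract_window = as.integer(tract_window),
                 min_windows = as.integer(min_windows),
                 tract_max_gap = as.integer(tract_max_gap)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$karyotype <- lapply(x$sim$karyotype, function(ev) {
    list(name = ev$name, type = ev$type, cuts = lapply(ev$cuts, as.integer))
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  karyotype <- lapply(sim$karyotype, function(ev) {
    rearrangement(ev$name, ev$cuts, type = ev$type)
  })
  simc <- sim_config(seed = sim$seed, chrom = sim$chrom,
                     ref_length = sim$ref_length, karyotype = karyotype,
                     snp_density = sim$snp_density,
                     donor_snp_density = sim$donor_snp_density,
                     n_stocks = sim$n_stocks, sco_rate = sim$sco_rate,
                     sco_stocks = unlist(sim$sco_stocks),
                     sco_points = unlist(sim$sco_points),
                     sco_exclusion = sim$sco_exclusion,
                     dco_specs = lapply(sim$dco_specs, function(sp) {
                       sp$stocks <- unlist(sp$stocks)
                       sp$interval <- unlist(sp$interval)
                       sp
                     }),
                     read_length = sim$read_length,
                     pe_insert_mean = sim$pe_insert_mean,
                     pe_insert_sd = sim$pe_insert_sd,
                     mp_insert_range = unlist(sim$mp_insert_range),
                     mp_orientation = sim$mp_orientation,
                     coverage = sim$coverage, base_error = sim$base_error,
                     qual_meanlog = sim$qual_meanlog,
                     qual_sdlog = sim$qual_sdlog,
                     indel_fraction = sim$indel_fraction)
  pipeline_config(outdir = x$outdir, sim = simc, stages = unlist(x$stages),
                  window_size = x$window_size, min_support = x$min_support,
                  min_clip = x$min_clip, min_link = x$min_link,
                  max_gap = x$max_gap, qual_min = x$qual_min,
                  max_share = x$max_share, tract_window = x$tract_window,
                  min_windows = x$min_windows,
                  tract_max_gap = x$tract_max_gap)
}

#' Run the full synthetic-analysis pipeline
#'
#' Stages run in order: *simulate* (reference FASTA, panel VCFs, aligned
#' PE+MP SAM for the first stock, mask/gene-model/truth fixtures), *callbp*
#' (breakpoint calling on the SAM), *tracts* (panel load, rare-SNP windows,
#' tract and relatedness calls, using the called breakpoints), *annotate*
#' (called junctions against the toy gene models), *report* (summary tables
#' plus truth-comparison recall/precision when truth files exist). Each
#' output records the package version and a parameter fingerprint. A stage
#' failure raises an error naming the stage; outputs of completed stages
#' are preserved.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the per-stage outputs and, after the
#'   report stage, `metrics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list(
    ref = file.path(config$outdir, "reference.fa"),
    sam = file.path(config$outdir, "reads.sam"),
    vcf_dir = file.path(config$outdir, "vcf"),
    junctions = file.path(config$outdir, "junctions.tsv"),
    bedpe = file.path(config$outdir, "links.bedpe"),
    bnd = file.path(config$outdir, "junctions.vcf"),
    heatmap = file.path(config$outdir, "heatmap.tsv"),
    tracts = file.path(config$outdir, "tracts.tsv"),
    related = file.path(config$outdir, "relatedness.tsv"),
    annot = file.path(config$outdir, "annotation.tsv"),
    report = file.path(config$outdir, "report.txt"),
    metrics = file.path(config$outdir, "metrics.tsv"))

  sim <- config$sim
  if ("simulate" %in% config$stages) {
    out$sim <- stage("simulate", {
      panel <- derive_panel(sim)
      ref <- Biostrings::DNAStringSet(panel$reference)
      names(ref) <- sim$chrom
      Biostrings::writeXStringSet(ref, paths$ref)
      pe <- simulate_read_pairs(panel$map, sim, "pe",
                                coverage = sim$coverage / 2,
                                stock = "s01", seed = sim$seed + 31L)
      mp <- simulate_read_pairs(panel$map, sim, "mp",
                                coverage = sim$coverage / 2,
                                stock = "s01", seed = sim$seed + 32L)
      write_sam(rbind(pe, mp), paths$sam, sim$chrom, sim$ref_length)
      vcfs <- panel_vcfs(panel, paths$vcf_dir, sim)
      fixtures <- emit_fixtures(panel, config$outdir, sim)
      list(panel = panel, vcfs = vcfs, fixtures = fixtures)
    })
  }
  if ("callbp" %in% config$stages) {
    out$calls <- stage("callbp", {
      calls <- call_breakpoints(paths$sam,
                                mask = out$sim$fixtures$mask,
                                window_size = config$window_size,
                                min_support = config$min_support,
                                min_clip = config$min_clip,
                                min_link = config$min_link,
                                max_gap = config$max_gap)
      write_junctions(calls, paths$junctions, "tsv")
      write_junctions(calls, paths$bedpe, "bedpe")
      write_junctions(calls, paths$bnd, "vcf")
      calls
    })
  }
  if ("tracts" %in% config$stages) {
    out$tracts <- stage("tracts", {
      panel_m <- load_panel(out$sim$vcfs, qual_min = config$qual_min)
      wm <- rare_snp_windows(panel_m, max_share = config$max_share,
                             window = config$tract_window,
                             chrom_length = sim$ref_length)
      write_window_matrix(wm, paths$heatmap)
      bps <- if (!is.null(out$calls) && nrow(out$calls$junctions)) {
        out$calls$junctions$five_prime
      } else NULL
      tr <- call_tracts(wm, panel_m, breakpoints = bps,
                        min_windows = config$min_windows,
                        max_gap = config$tract_max_gap)
      write_tracts(tr, paths$tracts)
      rel <- shared_tracts(tr, panel_m)
      utils::write.table(rel, paths$related, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(panel = panel_m, windows = wm, tracts = tr, related = rel)
    })
  }
  if ("annotate" %in% config$stages) {
    out$annot <- stage("annotate", {
      models <- read_gene_models(out$sim$fixtures$genes)
      ann <- intersect_breakpoints(out$calls$junctions, models)
      utils::write.table(ann, paths$annot, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      ann
    })
  }
  if ("report" %in% config$stages) {
    out$metrics <- stage("report", {
      truth <- out$sim$panel$truth
      m <- list()
      if (!is.null(out$calls)) {
        cj <- out$calls$junctions
        tj <- truth$junctions
        hit <- vapply(seq_len(nrow(tj)), function(i) {
          any(abs(cj$five_prime - tj$five_prime[i]) <= 1 &
                abs(cj$three_prime - tj$three_prime[i]) <= 1)
        }, logical(1))
        fp <- vapply(seq_len(nrow(cj)), function(i) {
          !any(abs(cj$five_prime[i] - tj$five_prime) <= 1 &
                 abs(cj$three_prime[i] - tj$three_prime) <= 1)
        }, logical(1))
        m$junction_recall <- mean(hit)
        m$junction_precision <- if (nrow(cj)) 1 - mean(fp) else NA_real_
      }
      if (!is.null(out$tracts)) {
        tt <- truth$tracts
        ct <- out$tracts$tracts
        if (nrow(tt)) {
          trec <- vapply(seq_len(nrow(tt)), function(i) {
            any(ct$stock == tt$stock[i] & ct$start <= tt$end[i] &
                  ct$end >= tt$start[i])
          }, logical(1))
          m$tract_recall <- mean(trec)
        }
        if (nrow(ct)) {
          tprec <- vapply(seq_len(nrow(ct)), function(i) {
            any(tt$stock == ct$stock[i] & tt$start <= ct$end[i] &
                  tt$end >= ct$start[i])
          }, logical(1))
          m$tract_precision <- mean(tprec)
        }
      }
      mdf <- data.frame(metric = names(m), value = unlist(m),
                        stringsAsFactors = FALSE)
      utils::write.table(mdf, paths$metrics, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      ver <- as.character(utils::packageVersion("balancerseq"))
      hash <- param_hash(yaml::as.yaml(list(
        seed = sim$seed, ref_length = sim$ref_length,
        n_stocks = sim$n_stocks, window_size = config$window_size,
        min_support = config$min_support, max_share = config$max_share)))
      rep_lines <- c(
        sprintf("balancerseq %s  parameter-hash %s  seed %d", ver, hash,
                sim$seed),
        sprintf("stages: %s", paste(config$stages, collapse = " -> ")),
        "",
        if (!is.null(out$calls))
          sprintf("junctions called: %d (recall %.3f, precision %.3f)",
                  nrow(out$calls$junctions), m$junction_recall,
                  m$junction_precision),
        if (!is.null(out$tracts))
          sprintf("tracts called: %d (recall %.3f, precision %.3f)",
                  nrow(out$tracts$tracts), m$tract_recall %||% NA,
                  m$tract_precision %||% NA))
      writeLines(rep_lines, paths$report)
      m
    })
  }
  out$paths <- paths
  invisible(out)
}
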