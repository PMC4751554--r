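# One-command orchestration: simulate -> depth -> junctions -> reconstruct
# -> classify -> in silico PCR, with persisted intermediates and a
# machine-readable report.

#' Assemble a validated pipeline configuration
#'
#' All parameters default to the package's standard study conditions: a
#' 5 Mb reference carrying the full-size default rearrangement, 30x
#' paired-end 2x100 coverage of both samples, 10 kb depth windows with a
#' 10 kb -> 1 kb -> 200 bp refinement schedule, split-read calling with
#' minimum clip 15 and minimum support 3.
#'
#' @param ... Overrides for any of the defaults (see the returned list for
#'   the full set of names).
#' @param file Optional YAML file whose entries override the defaults
#'   (command-line overrides in `...` still win).
#' @return Named list of class `chromo_config`.
#' @export
chromo_config <- function(..., file = NULL) {
  cfg <- list(
    length = 5e6, scale = 1, gc_fraction = 0.36, triplicated = "28kb",
    coverage = 30, read_len = 100, insert_mean = 300, insert_sd = 50,
    error_rate = 0.005, seed = 1,
    window = 10000, refine_schedule = c(10000, 1000, 200), min_mapq = 1,
    smoothing_halfwidth = 2, min_segment = 3,
    min_clip = 15, min_support = 3, consensus_flank = 50,
    search_radius = 500, tolerance = 400, refine_below = 10000,
    min_direct = 500, max_walks = 1000,
    mh_min = 2, feature_frac = 0.5, min_alternations = 2,
    run_pcr = TRUE, write_reads = FALSE, chrom = "chrS")
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$length >= 1, cfg$coverage > 0, cfg$read_len < cfg$insert_mean,
            cfg$window >= 100, cfg$min_clip >= 10, cfg$min_support >= 1)
  structure(cfg, class = "chromo_config")
}

msg <- function(log, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(line)
}

#' Run the full CGR discovery pipeline
#'
#' Executes every stage in order on a freshly simulated scenario: genome
#' simulation with truth alignments, windowed depth-ratio segmentation with
#' multi-resolution boundary refinement, split-read junction calling with
#' consensus and signature analysis, segment-graph reconstruction with
#' derivative-walk enumeration and classification, and junction-primer
#' design with the derivative-only amplification check.  Intermediates are
#' persisted in their standard formats when `outdir` is given.
#'
#' @param config A `chromo_config` (or arguments for one via `...`).
#' @param outdir Output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param ... Shorthand config overrides when `config` is missing.
#' @return A `run_report` list: per-stage summaries plus the full
#'   intermediate objects in `$objects`.
#' @export
run_all <- function(config = chromo_config(...), outdir = NULL, ...) {
  t_start <- Sys.time()
  log <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(outdir, "run.log")
    cat("", file = log)
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  }

  ## stage 1: simulate
  msg(log, "simulate: reference %g bp, scale %g, seed %d",
      config$length, config$scale, config$seed)
  scen <- cgr_scenario(config$length, config$scale, config$gc_fraction,
                       config$seed, config$triplicated)
  mut_reads <- simulate_reads(scen$derivative, config$coverage,
                              config$read_len, config$insert_mean,
                              config$insert_sd, config$error_rate,
                              seed = config$seed + 1, sample_name = "mutant")
  ctl_reads <- simulate_reads(scen$reference, config$coverage,
                              config$read_len, config$insert_mean,
                              config$insert_sd, config$error_rate,
                              seed = config$seed + 2, sample_name = "control")
  test <- emit_truth_alignments(mut_reads, scen$derivative, config$chrom)
  control <- emit_truth_alignments(ctl_reads, scen$reference, config$chrom)
  msg(log, "simulate: %d + %d read pairs",
      length(mut_reads$r1), length(ctl_reads$r1))

  ## stage 2: depth
  wt <- window_counts(test, config$window, min_mapq = config$min_mapq)
  wc <- window_counts(control, config$window, min_mapq = config$min_mapq)
  track <- depth_ratio(wt, wc)
  segments <- call_cn_segments(track, config$smoothing_halfwidth,
                               config$min_segment)
  refined <- segments
  bounds <- segments$end[-nrow(segments)]
  dirs <- sign(diff(segments$state))
  keep <- dirs != 0
  for (i in which(keep)) {
    r <- tryCatch(
      refine_breakpoint(test, control, bounds[i], config$refine_schedule,
                        direction = dirs[i], min_mapq = config$min_mapq),
      error = function(e) NULL)
    if (!is.null(r)) {
      refined$end[refined$end == bounds[i]] <- r$boundary
      refined$start[refined$start == bounds[i]] <- r$boundary
    } else {
      msg(log, "depth: boundary %g not refined (no transition)", bounds[i])
    }
  }
  attr(refined, "baseline") <- attr(segments, "baseline")
  msg(log, "depth: %d segments (baseline %.3f)", nrow(segments),
      attr(segments, "baseline"))

  ## stage 3: junctions
  clusters <- collect_clip_clusters(test, config$min_clip)
  ctl_clusters <- collect_clip_clusters(control, config$min_clip)
  junctions <- call_junctions(clusters, scen$reference, config$min_support,
                              ctl_clusters)
  signatures <- NULL
  if (nrow(junctions)) {
    signatures <- withCallingHandlers(
      do.call(rbind, lapply(seq_len(nrow(junctions)), function(k) {
        cons <- junction_consensus(junctions[k, ], clusters,
                                   config$consensus_flank)
        junction_signature(junctions[k, ], cons, scen$reference,
                           config$search_radius)
      })),
      warning = function(w) {
        msg(log, "junctions: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  msg(log, "junctions: %d called, %d orphan clusters", nrow(junctions),
      nrow(attr(junctions, "orphans")))

  ## stage 4: reconstruct + classify
  graph <- build_segment_graph(refined, junctions, config$tolerance,
                               test = test, control = control,
                               refine_below = config$refine_below,
                               min_direct = config$min_direct)
  walks <- enumerate_derivatives(graph, config$max_walks)
  classification <- classify_cgr(graph, signatures, config$mh_min,
                                 config$feature_frac, config$min_alternations)
  msg(log, "reconstruct: %d walks, label %s", length(walks),
      classification$label)

  ## stage 5: in silico PCR
  primers <- NULL
  if (isTRUE(config$run_pcr) && nrow(junctions)) {
    primers <- do.call(rbind, lapply(seq_len(nrow(junctions)), function(k) {
      pp <- tryCatch(design_junction_primers(junctions[k, ], scen$reference,
                                             scen$derivative),
                     error = function(e) NULL)
      if (is.null(pp)) {
        return(data.frame(name = junctions$name[k], forward = NA, reverse = NA,
                          product_size = NA, derivative_products = NA,
                          reference_products = NA))
      }
      pp$derivative_products <- nrow(predict_products(
        pp$forward, pp$reverse, scen$derivative$sequence))
      pp$reference_products <- nrow(predict_products(
        pp$forward, pp$reverse, scen$reference$sequence))
      pp
    }))
    msg(log, "pcr: %d/%d junction primer pairs designed",
        sum(!is.na(primers$forward)), nrow(junctions))
  }

  ## summaries
  span <- if (nrow(junctions)) {
    max(c(junctions$coord_a, junctions$coord_b)) -
      min(c(junctions$coord_a, junctions$coord_b))
  } else NA_real_
  st2 <- sort(segments$end[segments$state == 2] -
                segments$start[segments$state == 2], decreasing = TRUE)
  gseg <- graph$segments
  report <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("chromoscout")),
      error = function(e) "dev"),
    seed = config$seed,
    config = unclass(config),
    n_read_pairs = c(test = length(mut_reads$r1), control = length(ctl_reads$r1)),
    depth = list(
      n_segments = nrow(segments),
      baseline = attr(segments, "baseline"),
      n_state2 = sum(segments$state == 2),
      n_state3 = sum(segments$state == 3),
      state2_lengths = st2,
      state3_length = sum(segments$end[segments$state == 3] -
                            segments$start[segments$state == 3])),
    junctions = list(
      n = nrow(junctions),
      span = span,
      table = if (nrow(junctions))
        cbind(junctions[, c("name", "coord_a", "orient_a", "coord_b",
                            "orient_b", "support")],
              signatures[, c("microhomology_len", "microhomology_seq",
                             "insertion_len", "templated")])
      else NULL),
    reconstruction = list(
      n_segments = nrow(gseg),
      duplicated_segments = sum(gseg$copy == 2),
      triplicated_segments = sum(gseg$copy == 3),
      deleted_segments = sum(gseg$copy == 0),
      inconsistencies = graph$inconsistencies,
      n_walks = length(walks),
      walks_truncated = isTRUE(attr(walks, "truncated")),
      first_walk = if (length(walks)) paste(walks[[1]], collapse = " ") else NA),
    classification = list(label = classification$label,
                          evidence = classification$evidence),
    pcr = if (!is.null(primers)) primers else NULL,
    wall_clock_sec = as.numeric(Sys.time() - t_start, units = "secs"))

  objects <- list(scenario = scen, test = test, control = control,
                  track = track, segments = segments, refined = refined,
                  clusters = clusters, junctions = junctions,
                  signatures = signatures, graph = graph, walks = walks,
                  classification = classification, primers = primers)

  if (!is.null(outdir)) {
    ch <- config$chrom
    write_fasta(stats::setNames(scen$reference$sequence, ch),
                file.path(outdir, "reference.fasta"))
    write_fasta(stats::setNames(scen$derivative$sequence, "derivative"),
                file.path(outdir, "derivative.fasta"))
    write_bedpe(scen$derivative$truth$junctions,
                file.path(outdir, "truth_junctions.bedpe"), ch)
    write_bed_segments(scen$derivative$truth$copy_profile,
                       file.path(outdir, "truth_copy.bed"), ch)
    write_bedgraph(track, file.path(outdir, "ratio.bedgraph"), ch)
    write_bed_segments(refined, file.path(outdir, "segments.bed"), ch)
    if (nrow(junctions)) {
      write_bedpe(junctions, file.path(outdir, "junctions.bedpe"), ch)
      write_vcf_bnd(junctions, signatures, scen$reference,
                    file.path(outdir, "junctions.vcf"), ch)
      utils::write.table(signatures, file.path(outdir, "signatures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_graph_tsv(graph, file.path(outdir, "graph"))
    writeLines(vapply(walks, paste, character(1), collapse = " "),
               file.path(outdir, "walks.txt"))
    jsonlite::write_json(list(label = classification$label,
                              evidence = classification$evidence),
                         file.path(outdir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(primers)) {
      utils::write.table(primers, file.path(outdir, "primers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (isTRUE(config$write_reads)) {
      write_fastq(mut_reads, file.path(outdir, "mutant"))
      write_fastq(ctl_reads, file.path(outdir, "control"))
      write_sam(test, file.path(outdir, "mutant.sam"))
      write_sam(control, file.path(outdir, "control.sam"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
    msg(log, "done in %.1f s; outputs in %s", report$wall_clock_sec, outdir)
  }

  structure(c(report, list(objects = objects)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  junctions: %d (span %s bp)\n", x$junctions$n,
              format(x$junctions$span, big.mark = ",")))
  cat(sprintf("  segments: %d duplicated, %d triplicated, %d deleted\n",
              x$reconstruction$duplicated_segments,
              x$reconstruction$triplicated_segments,
              x$reconstruction$deleted_segments))
  cat(sprintf("  classification: %s\n", x$classification$label))
  invisible(x)
}
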