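# End-to-end orchestration: QC -> background -> segmentation ->
# classification -> promoter profiles -> specific NDRs -> element summaries,
# with a serialized run manifest. All thresholds default to the standard
# analysis parameters.

#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage threshold with its standard default: depth filter 3;
#' NDR windows 100/20 at `-log10 p > 5`, minimum 140 bp; nucleosome windows
#' 40/20 at `-log10 p > 3`, minimum 60 bp; proximal cutoff 2 kb; specific-NDR
#' retention at `r > 0.6`, `p < 0.1`; QC retention at efficiency >= 0.90 and
#' conversion > 0.98.
#'
#' @param out_dir output directory.
#' @param min_depth per-site depth filter.
#' @param ndr,nucleosome lists of segmentation parameters
#'   (`window, step, score_cut, min_len, merge_gap`).
#' @param proximal_cutoff TSS distance separating proximal from distal NDRs.
#' @param r_threshold,p_threshold specific-NDR retention thresholds.
#' @param efficiency_min,conversion_min QC retention thresholds.
#' @param lambda_chrom spike-in contig name.
#' @param invert_directions see [call_ndrs()].
#' @param seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       min_depth = 3L,
                       ndr = list(window = 100L, step = 20L, score_cut = 5,
                                  min_len = 140L, merge_gap = 0L),
                       nucleosome = list(window = 40L, step = 20L,
                                         score_cut = 3, min_len = 60L,
                                         merge_gap = 0L),
                       proximal_cutoff = 2000L,
                       r_threshold = 0.6, p_threshold = 0.1,
                       efficiency_min = 0.90, conversion_min = 0.98,
                       lambda_chrom = "lambda",
                       invert_directions = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full NOMe-seq analysis pipeline
#'
#' Applies the spike-in retention rule, calls NDRs and nucleosomes per
#' retained sample, classifies NDRs against the TSS catalog, summarises
#' promoters, builds the cross-sample NDR signal and distance matrices,
#' calls cell-type-specific proximal NDRs when expression and group labels
#' are available, summarises annotation classes, and writes every product
#' plus a JSON manifest (parameters, stages, file checksums) under
#' `config$out_dir`. Re-running on an existing output directory requires
#' `force = TRUE` and reproduces identical files for identical inputs.
#'
#' @param samples named list of `nome_calls` (each containing its spike-in
#'   contig when QC is to be enforced; samples without spike-in sites are
#'   retained with a logged notice).
#' @param config a [run_config()].
#' @param tss optional TSS catalog (`gene_id, chrom, pos`).
#' @param expression optional gene x sample matrix for specific-NDR calling.
#' @param groups optional named character vector sample -> group.
#' @param annotation optional element annotation
#'   (`chrom, start, end, class_label`).
#' @param force overwrite an existing output directory.
#' @param verbose log stage progress via `message()`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(samples, config, tss = NULL, expression = NULL,
                         groups = NULL, annotation = NULL, force = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("`samples` must be a named list")
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (verbose) message("[nomeseqr] ", ...)
  stages <- character()
  run_stage <- function(name, expr) {
    log("stage: ", name)
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  qc <- run_stage("qc", {
    rbindlist(lapply(names(samples), function(nm) {
      s <- samples[[nm]]
      has_lambda <- s$sites[chrom %in% config$lambda_chrom, .N] > 0L
      if (!has_lambda) {
        log("  sample ", nm, ": no spike-in sites, retained without QC")
        return(data.table(sample_id = nm, mcvipi_efficiency = NA_real_,
                          conversion_rate = NA_real_, n_gch_obs = 0L,
                          n_non_gch_obs = 0L, pass = TRUE,
                          reason = "no spike-in"))
      }
      r <- qc_report(s, config$lambda_chrom, config$efficiency_min,
                     config$conversion_min)
      r$sample_id <- nm
      if (!r$pass) log("  sample ", nm, " excluded: ", r$reason)
      r
    }))
  })
  data.table::fwrite(qc, file.path(out, "qc.tsv"), sep = "\t", na = "NA")
  retained <- samples[qc$sample_id[qc$pass]]
  if (length(retained) == 0L) stop("no sample passed spike-in QC")

  seg <- run_stage("segmentation", {
    lapply(names(retained), function(nm) {
      s <- retained[[nm]]
      bg <- compute_background(s, config$min_depth, config$lambda_chrom)
      ndr <- do.call(call_ndrs, c(list(
        calls = s, background = bg, min_depth = config$min_depth,
        invert_directions = config$invert_directions,
        exclude_chroms = config$lambda_chrom), config$ndr))
      nuc <- do.call(call_nucleosomes, c(list(
        calls = s, background = bg, min_depth = config$min_depth,
        invert_directions = config$invert_directions,
        exclude_chroms = config$lambda_chrom), config$nucleosome))
      write_segments_bed(ndr, file.path(out, paste0(nm, ".ndr.bed")))
      write_segments_bed(nuc, file.path(out, paste0(nm, ".nucleosome.bed")))
      list(background = bg, ndr = ndr, nucleosome = nuc)
    })
  })
  names(seg) <- names(retained)

  union_ndr <- run_stage("union", union_segments(lapply(seg, `[[`, "ndr")))
  classified <- NULL
  if (!is.null(tss) && nrow(union_ndr)) {
    classified <- run_stage("classification", {
      u <- copy(union_ndr)[, `:=`(seg_type = "NDR", score = NA_real_,
                                  n_windows = NA_integer_)]
      cl <- classify_ndrs(u, tss, config$proximal_cutoff)
      data.table::fwrite(cl, file.path(out, "ndr_classified.tsv"),
                         sep = "\t", na = "NA")
      cl
    })
    run_stage("promoters", {
      genes <- as.data.table(tss)[, .(gene_id, chrom, tss = pos)]
      for (nm in names(retained)) {
        ps <- promoter_summary(genes, retained[[nm]],
                               min_depth = config$min_depth)
        data.table::fwrite(ps, file.path(out,
                                         paste0(nm, ".promoters.tsv")),
                           sep = "\t", na = "NA")
      }
    })
  }

  if (nrow(union_ndr) && length(retained) >= 2L) {
    run_stage("signal-matrix", {
      m <- build_signal_matrix(union_ndr, retained,
                               min_depth = config$min_depth)
      write_signal_matrix(m, file.path(out, "ndr_signal_matrix.tsv"))
      d <- sample_distance_matrix(m)
      write_signal_matrix(d, file.path(out, "sample_distance_matrix.tsv"))
      if (!is.null(expression) && !is.null(groups) &&
          !is.null(classified)) {
        prox <- classified[proximity == "proximal"]
        if (nrow(prox)) {
          pm <- build_signal_matrix(prox, retained,
                                    min_depth = config$min_depth)
          calls <- call_specific_ndrs(pm, expression, groups,
                                      prox$nearest_tss,
                                      config$r_threshold,
                                      config$p_threshold)
          data.table::fwrite(calls, file.path(out, "specific_ndrs.tsv"),
                             sep = "\t", na = "NA")
        }
      }
    })
  }

  if (!is.null(annotation)) {
    run_stage("elements", {
      es <- rbindlist(lapply(names(retained), function(nm)
        data.table(sample_id = nm,
                   element_summaries(retained[[nm]], annotation,
                                     config$min_depth))))
      data.table::fwrite(es, file.path(out, "element_summary.tsv"),
                         sep = "\t", na = "NA")
    })
  }

  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(out), "manifest.json"))
    man <- list(
      package = "nomeseqr",
      version = as.character(utils::packageVersion("nomeseqr")),
      seed = config$seed,
      parameters = unclass(config)[setdiff(names(unclass(config)),
                                           "out_dir")],
      samples = names(samples),
      retained = names(retained),
      stages = stages,
      files = as.list(tools::md5sum(file.path(out, files))))
    names(man$files) <- files
    jsonlite::write_json(man, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  log("done: ", length(stages), " stages")
  invisible(manifest)
}
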