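# Accessibility and residual methylation over annotated elements, promoter
# CpG-density classes, and repeat families/subfamilies.

#' Pooled accessibility/methylation summary for one element class
#'
#' Pools GCH and WCG counts over all intervals of the class (a site covered
#' by several intervals contributes to each, which keeps class levels
#' additive over intervals) and reports the relative accessibility
#' enrichment `log2(class GCH level / genome GCH level)`.
#'
#' @param calls a `nome_calls` object.
#' @param intervals data.table/data.frame `chrom, start, end` (0-based
#'   half-open), at least one row.
#' @param label class label for the output row.
#' @param min_depth minimum per-site depth.
#' @param genome_gch genome GCH level to normalise against; computed from
#'   `calls` when `NULL`.
#' @return one-row data.table `class_label, gch_level, wcg_level,
#'   relative_enrichment, n_gch_sites, n_wcg_sites, n_intervals`.
#' @export
element_summary <- function(calls, intervals, label, min_depth = 3L,
                            genome_gch = NULL) {
  intervals <- as.data.table(intervals)
  if (nrow(intervals) == 0L)
    stop("`intervals` must contain at least one interval")
  if (is.null(genome_gch))
    genome_gch <- genome_mean_level(calls, "GCH", min_depth)
  reg <- intervals[, .(region_id = .I, chrom, start, end)]
  gch <- .pool_over_regions(.class_sites(calls, "GCH", min_depth), reg)
  wcg <- .pool_over_regions(.class_sites(calls, "WCG", min_depth), reg)
  g <- .pooled(gch[, .(meth = pooled_meth, unmeth = pooled_unmeth)])
  w <- .pooled(wcg[, .(meth = pooled_meth, unmeth = pooled_unmeth)])
  enr <- if (!is.na(g$level) && !is.na(genome_gch) && genome_gch > 0 &&
             g$level > 0) log2(g$level / genome_gch) else NA_real_
  data.table(class_label = label, gch_level = g$level, wcg_level = w$level,
             relative_enrichment = enr,
             n_gch_sites = sum(gch$n_sites), n_wcg_sites = sum(wcg$n_sites),
             n_intervals = nrow(intervals))
}

#' Summaries for every class of an annotation set
#'
#' @param calls a `nome_calls` object.
#' @param annotation data.table/data.frame `chrom, start, end, class_label`.
#' @param min_depth minimum per-site depth.
#' @return data.table with one [element_summary()] row per class.
#' @export
element_summaries <- function(calls, annotation, min_depth = 3L) {
  annotation <- as.data.table(annotation)
  if (nrow(annotation) == 0L) return(data.table())
  stopifnot("class_label" %in% names(annotation))
  genome_gch <- genome_mean_level(calls, "GCH", min_depth)
  rbindlist(lapply(split(annotation, by = "class_label"), function(a)
    element_summary(calls, a, a$class_label[1L], min_depth, genome_gch)))
}

#' Accessibility/methylation summary per repeat family and subfamily
#'
#' @param calls a `nome_calls` object.
#' @param repeats data.table/data.frame `chrom, start, end, family,
#'   subfamily` (RepeatMasker-style); missing labels group under
#'   `"unassigned"`.
#' @param min_depth minimum per-site depth.
#' @return data.table with `family, subfamily` plus the
#'   [element_summary()] columns, one row per subfamily.
#' @export
repeat_family_summary <- function(calls, repeats, min_depth = 3L) {
  repeats <- as.data.table(repeats)
  if (nrow(repeats) == 0L) return(data.table())
  if (!"family" %in% names(repeats)) repeats[, family := NA_character_]
  if (!"subfamily" %in% names(repeats)) repeats[, subfamily := NA_character_]
  repeats[is.na(family) | family == "", family := "unassigned"]
  repeats[is.na(subfamily) | subfamily == "", subfamily := "unassigned"]
  genome_gch <- genome_mean_level(calls, "GCH", min_depth)
  parts <- split(repeats, by = c("family", "subfamily"))
  rbindlist(lapply(parts, function(a) {
    s <- element_summary(calls, a, paste(a$family[1L], a$subfamily[1L],
                                         sep = "/"),
                         min_depth, genome_gch)
    data.table(family = a$family[1L], subfamily = a$subfamily[1L], s)
  }))
}

#' Classify promoters by CpG density (HCP / ICP / LCP)
#'
#' Over the window TSS +/- `flank` bp, computes the CpG observed/expected
#' ratio `n_CG * L / (n_C * n_G)` and the GC fraction; a promoter is HCP
#' when `o/e >= 0.75` and `GC >= 0.55`, LCP when `o/e < 0.48`, and ICP
#' otherwise (Weber-style convention). Windows with no C or no G are LCP.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param tss data.table/data.frame `gene_id, chrom, pos` (0-based TSS).
#' @param flank window half-width (default 500 bp); windows are clipped to
#'   the chromosome.
#' @param oe_high,gc_high,oe_low class thresholds.
#' @return data.table `gene_id, cpg_oe, gc_fraction, promoter_class`
#'   (factor HCP/ICP/LCP).
#' @export
classify_promoter_cpg <- function(genome, tss, flank = 500L,
                                  oe_high = 0.75, gc_high = 0.55,
                                  oe_low = 0.48) {
  seqs <- .as_seq_set(genome)
  tss <- as.data.table(tss)
  stopifnot(all(c("gene_id", "chrom", "pos") %in% names(tss)))
  if (!all(tss$chrom %in% names(seqs)))
    stop("TSS on chromosome absent from the genome")
  sl <- nchar(seqs)
  start1 <- pmax(1L, as.integer(tss$pos) - as.integer(flank) + 1L)
  end1 <- pmin(unname(sl[tss$chrom]), as.integer(tss$pos) + as.integer(flank))
  win <- substr(seqs[tss$chrom], start1, end1)
  ws <- Biostrings::DNAStringSet(win)
  n_cg <- Biostrings::vcountPattern("CG", ws)
  freq <- Biostrings::letterFrequency(ws, c("C", "G"))
  n_c <- freq[, "C"]; n_g <- freq[, "G"]
  len <- nchar(win)
  oe <- ifelse(n_c * n_g > 0, n_cg * len / (n_c * n_g), 0)
  gc <- (n_c + n_g) / len
  cls <- ifelse(n_c * n_g == 0, "LCP",
                ifelse(oe >= oe_high & gc >= gc_high, "HCP",
                       ifelse(oe < oe_low, "LCP", "ICP")))
  data.table(gene_id = tss$gene_id, cpg_oe = oe, gc_fraction = gc,
             promoter_class = factor(cls, levels = c("HCP", "ICP", "LCP")))
}
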