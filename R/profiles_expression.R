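# Metaprofiles around genomic anchors, expression stratification, and the
# promoter accessibility/methylation vs expression rank correlations.

#' Group genes by expression level
#'
#' Boundary-literal RPKM classes: `> 10` high, `(1, 10]` intermediate,
#' `(0.1, 1]` low, `<= 0.1` silenced.
#'
#' @param value non-negative RPKM/FPKM values.
#' @return ordered factor `silenced < low < intermediate < high`.
#' @export
expression_group <- function(value) {
  if (any(is.na(value)) || any(value < 0))
    stop("expression values must be non-negative and non-missing")
  cut(value, breaks = c(-Inf, 0.1, 1, 10, Inf),
      labels = c("silenced", "low", "intermediate", "high"),
      right = TRUE, ordered_result = TRUE)
}

#' Pooled methylation metaprofile around anchors
#'
#' Bins the flank `[-flank, +flank)` around each anchor into `bin`-bp bins
#' and pools methylated/unmethylated counts of qualifying sites across all
#' anchors per bin. With `strand_aware = TRUE`, offsets at minus-strand
#' anchors are mirrored so that positive offsets always point downstream.
#' Bins with no covered site report `level = NA`, not 0.
#'
#' @param calls a `nome_calls` object.
#' @param anchors data.table/data.frame with `chrom, pos` and optionally
#'   `strand` (`+`/`-`; assumed `+` when absent). E.g., TSSs, NDR centers,
#'   or exon boundaries.
#' @param context_class `"GCH"` or `"WCG"`.
#' @param flank half-width in bp; must be a positive multiple of `bin`.
#' @param bin bin width in bp.
#' @param strand_aware mirror minus-strand anchors.
#' @param min_depth minimum per-site depth.
#' @return data.table `bin_center, level, n_sites, pooled_meth,
#'   pooled_unmeth` covering every bin.
#' @export
metaprofile <- function(calls, anchors, context_class = "GCH",
                        flank = 1000L, bin = 20L, strand_aware = TRUE,
                        min_depth = 3L) {
  anchors <- as.data.table(anchors)
  if (nrow(anchors) == 0L) stop("`anchors` must be non-empty")
  stopifnot(all(c("chrom", "pos") %in% names(anchors)),
            flank > 0L, bin > 0L, flank %% bin == 0L)
  if (!"strand" %in% names(anchors)) anchors[, strand := "+"]
  n_bins <- 2L * flank %/% bin
  grid <- data.table(bin_idx = seq_len(n_bins) - 1L)
  grid[, bin_center := -flank + bin_idx * bin + bin / 2]
  sites <- .class_sites(calls, context_class, min_depth)
  if (nrow(sites) == 0L)
    return(grid[, .(bin_center, level = NA_real_, n_sites = 0L,
                    pooled_meth = 0L, pooled_unmeth = 0L)])
  a <- anchors[, .(anchor_id = .I, chrom, anchor_pos = pos, strand,
                   rstart = pos - flank, rend = pos + flank - 1L)]
  data.table::setkey(a, chrom, rstart, rend)
  q <- sites[, .(chrom, qstart = pos, qend = pos, meth, unmeth)]
  ov <- data.table::foverlaps(q, a, by.x = c("chrom", "qstart", "qend"),
                              nomatch = NULL)
  if (nrow(ov) == 0L)
    return(grid[, .(bin_center, level = NA_real_, n_sites = 0L,
                    pooled_meth = 0L, pooled_unmeth = 0L)])
  ov[, offset := qstart - anchor_pos]
  if (strand_aware)
    ov[strand == "-", offset := -offset - 1L]  # half-open mirror
  ov <- ov[offset >= -flank & offset < flank]
  ov[, bin_idx := (offset + flank) %/% bin]
  agg <- ov[, .(pooled_meth = sum(meth), pooled_unmeth = sum(unmeth),
                n_sites = .N), by = bin_idx]
  out <- agg[grid, on = "bin_idx"]
  out[is.na(n_sites), `:=`(n_sites = 0L, pooled_meth = 0L,
                           pooled_unmeth = 0L)]
  out[, level := site_level(pooled_meth, pooled_unmeth)]
  data.table::setorder(out, bin_idx)
  out[, .(bin_center, level, n_sites, pooled_meth, pooled_unmeth)]
}

#' Promoter accessibility and methylation summary per gene
#'
#' Promoter = TSS +/- `flank` bp (default 1 kb), clipped to chromosome
#' bounds when `seqlengths` is supplied; both the GCH (accessibility) and
#' WCG (endogenous methylation) pooled levels are returned.
#'
#' @param genes data.table/data.frame with `gene_id, chrom, tss` (0-based).
#' @param calls a `nome_calls` object.
#' @param flank promoter half-width in bp.
#' @param min_depth minimum per-site depth.
#' @param seqlengths optional named vector of chromosome lengths for
#'   clipping.
#' @return data.table `gene_id, chrom, start, end, gch_level, wcg_level,
#'   n_gch_sites, n_wcg_sites`.
#' @export
promoter_summary <- function(genes, calls, flank = 1000L, min_depth = 3L,
                             seqlengths = NULL) {
  genes <- as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  reg <- genes[, .(region_id = gene_id, chrom,
                   start = pmax(0L, as.integer(tss) - as.integer(flank)),
                   end = as.integer(tss) + as.integer(flank))]
  if (!is.null(seqlengths))
    reg[chrom %in% names(seqlengths),
        end := pmin(end, unname(seqlengths[chrom]))]
  gch <- region_levels(calls, reg, "GCH", min_depth)
  wcg <- region_levels(calls, reg, "WCG", min_depth)
  out <- gch[, .(gene_id = region_id, chrom, start, end,
                 gch_level = level, n_gch_sites = n_sites)]
  out[, `:=`(wcg_level = wcg$level[match(gene_id, wcg$region_id)],
             n_wcg_sites = wcg$n_sites[match(gene_id, wcg$region_id)])]
  out[]
}

# Spearman with mid-ranked ties and the asymptotic t approximation;
# NA (not an error) for constant or too-short input.
.spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Rank correlations between expression and promoter state
#'
#' Spearman correlation (mid-ranked ties, asymptotic t p-value) between the
#' expression vector and promoter accessibility (`r1`) and, when supplied,
#' between expression and promoter endogenous methylation (`r2`). Genes with
#' an undefined level are dropped pairwise per correlation; at least 5
#' complete pairs are required.
#'
#' @param expr expression values (RPKM scale), one per gene.
#' @param gch promoter GCH levels, same genes.
#' @param wcg optional promoter WCG levels, same genes.
#' @return list `r1, p1, n1` and (when `wcg` given) `r2, p2, n2`.
#' @export
expression_correlations <- function(expr, gch, wcg = NULL) {
  stopifnot(length(expr) == length(gch))
  s1 <- .spearman(expr, gch)
  if (s1$n < 5L)
    stop("fewer than 5 genes with paired expression and accessibility")
  out <- list(r1 = s1$r, p1 = s1$p, n1 = s1$n)
  if (!is.null(wcg)) {
    stopifnot(length(wcg) == length(expr))
    s2 <- .spearman(expr, wcg)
    if (s2$n < 5L)
      stop("fewer than 5 genes with paired expression and methylation")
    out <- c(out, list(r2 = s2$r, p2 = s2$p, n2 = s2$n))
  }
  out
}

#' Sliding-mean accessibility along the expression rank
#'
#' Orders genes by expression and returns the rolling mean of a promoter
#' signal over `window` consecutive genes stepped by `step` - the smoothed
#' presentation that accompanies the scalar rank correlations.
#'
#' @param expr expression values.
#' @param signal promoter signal, same genes.
#' @param window number of genes per rolling window.
#' @param step step between window starts, in genes.
#' @return data.table `rank_center, mean_expr, mean_signal`.
#' @export
expression_sliding_mean <- function(expr, signal, window = 100L, step = 1L) {
  ok <- stats::complete.cases(expr, signal)
  o <- order(expr[ok])
  e <- expr[ok][o]; s <- signal[ok][o]
  n <- length(e)
  if (n < window) stop("fewer genes than the window size")
  starts <- seq(1L, n - window + 1L, by = step)
  data.table(
    rank_center = starts + (window - 1) / 2,
    mean_expr = vapply(starts, function(i) mean(e[i:(i + window - 1L)]),
                       numeric(1)),
    mean_signal = vapply(starts, function(i) mean(s[i:(i + window - 1L)]),
                         numeric(1)))
}
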