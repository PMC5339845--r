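# Cell-type-specific proximal NDRs via the accessibility-expression rank
# correlation filter, and the cross-sample correlation/distance structure.

#' Accessibility signal matrix over NDRs across samples
#'
#' One row per NDR (union call set), one column per sample; entries are the
#' pooled GCH level over the NDR at the standard depth filter, `NA` when no
#' site qualifies in that sample.
#'
#' @param ndrs data.table/data.frame of intervals (`chrom, start, end`),
#'   e.g. a [union_segments()] result or a classified NDR table.
#' @param samples named list of `nome_calls` objects.
#' @param context_class signal to pool (default `"GCH"`; use `"WCG"` for the
#'   methylation companion matrix).
#' @param min_depth minimum per-site depth.
#' @return numeric matrix, rownames `chrom:start-end`, colnames sample
#'   names.
#' @export
build_signal_matrix <- function(ndrs, samples, context_class = "GCH",
                                min_depth = 3L) {
  ndrs <- as.data.table(ndrs)
  if (nrow(ndrs) == 0L) stop("`ndrs` must contain at least one interval")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("`samples` must be a named list of nome_calls")
  reg <- ndrs[, .(region_id = sprintf("%s:%d-%d", chrom, start, end),
                  chrom, start, end)]
  cols <- lapply(samples, function(s) {
    rl <- region_levels(s, reg, context_class, min_depth)
    rl$level[match(reg$region_id, rl$region_id)]
  })
  m <- do.call(cbind, cols)
  rownames(m) <- reg$region_id
  colnames(m) <- names(samples)
  m
}

#' Pairwise sample distances from NDR accessibility
#'
#' For each sample pair, Spearman correlation over the NDRs where both
#' entries are present (pairwise-complete, ranks computed within each pair's
#' shared rows); distance is `1 - r`. Pairs sharing fewer than `min_shared`
#' rows get `NA`. The result feeds standard `hclust`/`cmdscale` directly.
#'
#' @param signal_matrix a [build_signal_matrix()] result.
#' @param min_shared minimum shared rows per pair (default 3).
#' @return symmetric distance matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(signal_matrix, min_shared = 3L) {
  m <- as.matrix(signal_matrix)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  k <- ncol(m)
  d <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(d) <- 0
  for (i in seq_len(k - 1L)) {
    for (jj in (i + 1L):k) {
      ok <- stats::complete.cases(m[, i], m[, jj])
      if (sum(ok) < min_shared) next
      r <- suppressWarnings(stats::cor(m[ok, i], m[ok, jj],
                                       method = "spearman"))
      d[i, jj] <- d[jj, i] <- 1 - r
    }
  }
  d
}

#' Call cell-type-specific proximal NDRs
#'
#' For every NDR with a mapped gene, computes the Spearman correlation
#' between its accessibility across samples and the gene's expression
#' across the same samples; NDRs with `r > r_threshold` and
#' `p < p_threshold` (raw, uncorrected) are retained and assigned to the
#' sample group with the highest mean accessibility. NDRs with fewer than
#' `min_samples` paired observations, or with constant accessibility
#' (undefined correlation), are reported with class `"none"` and
#' `retained = FALSE`.
#'
#' @param signal_matrix NDR x sample accessibility matrix
#'   ([build_signal_matrix()]).
#' @param expression gene x sample expression matrix (RPKM scale); columns
#'   must cover the signal matrix's samples.
#' @param groups named character vector: sample -> group label (e.g.,
#'   `heart`, `fgc`, `soma`).
#' @param ndr_genes character vector, one gene id per signal-matrix row
#'   (e.g., the nearest TSS from [classify_ndrs()]); `NA` rows are skipped.
#' @param r_threshold,p_threshold retention thresholds (defaults 0.6 and
#'   0.1).
#' @param min_samples minimum paired samples per NDR (default 5).
#' @param wcg_matrix optional companion WCG matrix; adds the
#'   methylation-expression correlation as an annotation column.
#' @return data.table `ndr_id, gene, n_used, r_access_expr, p_access_expr,
#'   retained, class` (+ `r_meth_expr` when `wcg_matrix` given).
#' @export
call_specific_ndrs <- function(signal_matrix, expression, groups, ndr_genes,
                               r_threshold = 0.6, p_threshold = 0.1,
                               min_samples = 5L, wcg_matrix = NULL) {
  m <- as.matrix(signal_matrix)
  ex <- as.matrix(expression)
  stopifnot(length(ndr_genes) == nrow(m))
  if (!all(colnames(m) %in% colnames(ex)))
    stop("expression matrix must cover every sample of the signal matrix")
  if (!all(colnames(m) %in% names(groups)))
    stop("`groups` must label every sample of the signal matrix")
  ex <- ex[, colnames(m), drop = FALSE]
  grp <- groups[colnames(m)]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    gene <- ndr_genes[i]
    base <- data.table(ndr_id = rownames(m)[i], gene = gene,
                       n_used = 0L, r_access_expr = NA_real_,
                       p_access_expr = NA_real_, retained = FALSE,
                       class = "none")
    if (is.na(gene) || !gene %in% rownames(ex)) return(base)
    acc <- m[i, ]
    e <- ex[gene, ]
    ok <- stats::complete.cases(acc, e)
    if (sum(ok) < min_samples) return(base)
    s <- .spearman(acc[ok], e[ok])
    base[, `:=`(n_used = as.integer(sum(ok)), r_access_expr = s$r,
                p_access_expr = s$p)]
    if (!is.na(s$r) && s$r > r_threshold && !is.na(s$p) &&
        s$p < p_threshold) {
      gm <- tapply(acc[ok], grp[ok], mean, na.rm = TRUE)
      base[, `:=`(retained = TRUE, class = names(gm)[which.max(gm)])]
    }
    base
  })
  out <- rbindlist(rows)
  if (!is.null(wcg_matrix)) {
    w <- as.matrix(wcg_matrix)[, colnames(m), drop = FALSE]
    out[, r_meth_expr := vapply(seq_len(nrow(m)), function(i) {
      gene <- ndr_genes[i]
      if (is.na(gene) || !gene %in% rownames(ex)) return(NA_real_)
      .spearman(w[i, ], ex[gene, ])$r
    }, numeric(1))]
  }
  out[]
}

#' Write / read a signal matrix as TSV with NA tokens
#'
#' @param m matrix with row and column names.
#' @param path file path.
#' @return invisibly the path, or the matrix for the reader.
#' @export
write_signal_matrix <- function(m, path) {
  dt <- data.table(ndr_id = rownames(m), as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}
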