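# Lambda spike-in QC: M.CviPI efficiency and bisulfite conversion rate.
# Lambda phage DNA carries no endogenous methylation, so GCH methylation on
# the spike-in is purely enzymatic and non-GCH methylation is purely failed
# conversion.

#' M.CviPI in vitro methylation efficiency from the lambda spike-in
#'
#' Pooled GCH methylation level over the lambda contig. GCG/CCG sites never
#' reach this estimator (they are dropped at read time and filtered again
#' here).
#'
#' @param lambda_calls `nome_calls` containing the spike-in contig.
#' @param lambda_chrom name of the spike-in contig (default `"lambda"`).
#' @param min_depth minimum per-site depth (default 1; every observation of
#'   the unmethylated spike-in is informative).
#' @return list with `rate` (`NA` when no observation) and `n_obs`
#'   (pooled read count).
#' @export
mcvipi_efficiency <- function(lambda_calls, lambda_chrom = "lambda",
                              min_depth = 1L) {
  s <- .class_sites(lambda_calls, "GCH", min_depth)[chrom %in% lambda_chrom]
  p <- .pooled(s)
  list(rate = p$level, n_obs = p$meth + p$unmeth)
}

#' Bisulfite conversion rate from the lambda spike-in
#'
#' One minus the pooled methylation level at non-GCH lambda cytosines (WCG
#' and OTHER classes). GCH is excluded because it is enzymatically
#' methylated; everything else on lambda should read fully converted.
#'
#' @inheritParams mcvipi_efficiency
#' @return list with `rate` (`NA` when no observation) and `n_obs`.
#' @export
conversion_rate <- function(lambda_calls, lambda_chrom = "lambda",
                            min_depth = 1L) {
  s <- .class_sites(lambda_calls, c("WCG", "OTHER"),
                    min_depth)[chrom %in% lambda_chrom]
  p <- .pooled(s)
  list(rate = if (is.na(p$level)) NA_real_ else 1 - p$level,
       n_obs = p$meth + p$unmeth)
}

#' Sample retention rule
#'
#' A sample is retained when the in vitro methylation efficiency is at least
#' 90\% AND the bisulfite conversion rate is strictly higher than 98\%
#' (boundary-literal: efficiency exactly 0.90 passes, conversion exactly
#' 0.98 fails). An undefined rate fails with a reason.
#'
#' @param efficiency,conversion rates in `[0, 1]` (or `NA`).
#' @param efficiency_min,conversion_min thresholds (defaults 0.90 and 0.98).
#' @return list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
sample_qc <- function(efficiency, conversion, efficiency_min = 0.90,
                      conversion_min = 0.98) {
  if (is.na(efficiency))
    return(list(pass = FALSE, reason = "efficiency undefined"))
  if (is.na(conversion))
    return(list(pass = FALSE, reason = "conversion rate undefined"))
  if (efficiency < efficiency_min)
    return(list(pass = FALSE,
                reason = sprintf("efficiency %.3f < %.2f", efficiency,
                                 efficiency_min)))
  if (conversion <= conversion_min)
    return(list(pass = FALSE,
                reason = sprintf("conversion %.3f <= %.2f", conversion,
                                 conversion_min)))
  list(pass = TRUE, reason = NA_character_)
}

#' One-row QC report for a sample
#'
#' @inheritParams mcvipi_efficiency
#' @inheritParams sample_qc
#' @return data.table: `sample_id, mcvipi_efficiency, conversion_rate,
#'   n_gch_obs, n_non_gch_obs, pass, reason`.
#' @export
qc_report <- function(lambda_calls, lambda_chrom = "lambda",
                      efficiency_min = 0.90, conversion_min = 0.98) {
  eff <- mcvipi_efficiency(lambda_calls, lambda_chrom)
  conv <- conversion_rate(lambda_calls, lambda_chrom)
  qc <- sample_qc(eff$rate, conv$rate, efficiency_min, conversion_min)
  data.table(sample_id = lambda_calls$sample_id,
             mcvipi_efficiency = eff$rate, conversion_rate = conv$rate,
             n_gch_obs = eff$n_obs, n_non_gch_obs = conv$n_obs,
             pass = qc$pass, reason = qc$reason)
}
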