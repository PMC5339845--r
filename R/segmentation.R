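# Chi-squared sliding-window segmentation of GCH accessibility into
# nucleosome-depleted regions (NDRs) and positioned nucleosomes.
#
# The genome is tiled into sliding windows; per window, GCH read counts of
# sites passing the depth filter are pooled and tested in a 2x2 chi-squared
# (no continuity correction) against the genome-wide pooled GCH counts.
# Significant same-direction windows are merged (overlapping/book-ended) and
# merged segments below the minimum length are discarded. NDRs are
# methylated-GCH enriched (M.CviPI marks open chromatin), nucleosomes are
# unmethylated-GCH enriched; `invert_directions` swaps this orientation.

#' Genome-wide GCH background for the window test
#'
#' Pooled methylated/unmethylated GCH read totals over every site with depth
#' `>= min_depth`; these totals are the second row of the per-window 2x2
#' table. The whole covered genome is used (the tested window is not removed:
#' a window is vanishingly small relative to the genome).
#'
#' @param calls a `nome_calls` object.
#' @param min_depth minimum per-site depth (default 3).
#' @param exclude_chroms contigs excluded from the background (default the
#'   lambda spike-in).
#' @return object of class `genome_background`: list with `total_meth`,
#'   `total_unmeth`, `level`.
#' @export
compute_background <- function(calls, min_depth = 3L,
                               exclude_chroms = "lambda") {
  p <- .pooled(.class_sites(calls, "GCH", min_depth, exclude_chroms))
  if (p$meth + p$unmeth <= 0)
    stop("no GCH site passes the depth filter; cannot form a background")
  structure(list(total_meth = p$meth, total_unmeth = p$unmeth,
                 level = p$level, min_depth = min_depth),
            class = "genome_background")
}

#' @export
print.genome_background <- function(x, ...) {
  cat(sprintf("GCH genome background: level %.4f (%s meth / %s unmeth reads)\n",
              x$level, format(x$total_meth, big.mark = ","),
              format(x$total_unmeth, big.mark = ",")))
  invisible(x)
}

#' Windowed 2x2 chi-squared test against the genome background
#'
#' Pearson chi-squared without continuity correction on
#' `rbind(c(win_meth, win_unmeth), c(bg_meth, bg_unmeth))`, 1 df. The
#' statistic is 0 and p = 1 when the window proportion equals the background
#' or any margin is empty. Direction is `"open"` when the window's methylated
#' proportion exceeds the background (accessible chromatin), `"closed"` when
#' below, `"none"` at equality; windows with zero depth get `p = NA` and
#' direction `"none"` (skipped downstream). p-values are floored at 1e-300.
#'
#' @param win_meth,win_unmeth pooled window counts (vectorized).
#' @param bg_meth,bg_unmeth background totals (scalars or vectors).
#' @return data.table `statistic, p_value, direction`.
#' @export
window_chi2_test <- function(win_meth, win_unmeth, bg_meth, bg_unmeth) {
  a <- as.numeric(win_meth); b <- as.numeric(win_unmeth)
  c_ <- as.numeric(bg_meth); d <- as.numeric(bg_unmeth)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  stat <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p[stat == 0] <- 1
  p <- pmax(p, 1e-300)
  pw <- ifelse(r1 > 0, a / r1, NA_real_)
  pb <- ifelse(r2 > 0, c_ / r2, NA_real_)
  dir <- rep("none", length(stat))
  dir[!is.na(pw) & !is.na(pb) & pw > pb] <- "open"
  dir[!is.na(pw) & !is.na(pb) & pw < pb] <- "closed"
  p[is.na(pw)] <- NA_real_
  data.table(statistic = stat, p_value = p, direction = dir)
}

# window counts over sliding windows: start = j*step, width = window.
# Requires window to be a multiple of step; each site then falls in exactly
# window/step windows.
.window_counts <- function(sites, window, step) {
  stopifnot(window %% step == 0L, window > 0L, step > 0L)
  nrep <- window %/% step
  reps <- lapply(seq_len(nrep) - 1L, function(k)
    sites[, .(chrom, j = pos %/% step - k, meth, unmeth)])
  dt <- rbindlist(reps)[j >= 0L]
  agg <- dt[, .(meth = sum(meth), unmeth = sum(unmeth), n_sites = .N),
            by = .(chrom, j)]
  agg[, `:=`(start = j * step, end = j * step + window)]
  agg[]
}

# shared segment caller
.call_segments <- function(calls, background, target_direction, seg_type,
                           window, step, min_depth, score_cut, min_len,
                           merge_gap, exclude_chroms) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), seg_type = character(),
                      score = numeric(), n_windows = integer())
  sites <- .class_sites(calls, "GCH", min_depth, exclude_chroms)
  if (nrow(sites) == 0L) return(empty)
  win <- .window_counts(sites, window, step)
  test <- window_chi2_test(win$meth, win$unmeth,
                           background$total_meth, background$total_unmeth)
  win[, `:=`(p_value = test$p_value, direction = test$direction)]
  win[, score := -log10(p_value)]
  sig <- win[!is.na(p_value) & direction == target_direction &
               score > score_cut]
  if (nrow(sig) == 0L) return(empty)
  data.table::setorder(sig, chrom, start)
  sig[, grp := {
    prev_end <- data.table::shift(cummax(as.numeric(end)))
    cumsum(is.na(prev_end) | start > prev_end + merge_gap)
  }, by = chrom]
  seg <- sig[, .(start = min(start), end = max(end), score = max(score),
                 n_windows = .N), by = .(chrom, grp)]
  seg <- seg[end - start >= min_len]
  seg[, `:=`(grp = NULL, seg_type = seg_type)]
  data.table::setcolorder(seg, c("chrom", "start", "end", "seg_type",
                                 "score", "n_windows"))
  data.table::setorder(seg, chrom, start)
  seg[]
}

#' Call nucleosome-depleted regions
#'
#' 100-bp windows sliding by 20 bp; windows significantly enriched for
#' methylated (accessible) GCH versus the genome background at
#' `-log10(p) > score_cut` are merged and merged segments shorter than
#' `min_len` are discarded. Defaults are the standard NDR parameters
#' (100/20, cutoff 5, minimum 140 bp). Segment score is the maximum window
#' score.
#'
#' @param calls a `nome_calls` object.
#' @param background a [compute_background()] result for the same sample;
#'   computed on the fly when `NULL`.
#' @param window,step window width and slide step in bp; `window` must be a
#'   multiple of `step`.
#' @param min_depth minimum per-site depth for a GCH site to contribute.
#' @param score_cut significance cutoff on `-log10(p)` (strict inequality).
#' @param min_len minimum merged-segment length in bp.
#' @param merge_gap maximum gap (bp) between significant windows that still
#'   merges them; 0 = overlapping or book-ended only.
#' @param invert_directions swap the open/closed orientation (calls NDRs on
#'   unmethylated-enriched windows, matching a transposed reading of the
#'   enrichment direction).
#' @param exclude_chroms contigs excluded from calling.
#' @return data.table of segments: `chrom, start, end, seg_type, score,
#'   n_windows`.
#' @export
call_ndrs <- function(calls, background = NULL, window = 100L, step = 20L,
                      min_depth = 3L, score_cut = 5, min_len = 140L,
                      merge_gap = 0L, invert_directions = FALSE,
                      exclude_chroms = "lambda") {
  if (is.null(background))
    background <- compute_background(calls, min_depth, exclude_chroms)
  dir <- if (invert_directions) "closed" else "open"
  .call_segments(calls, background, dir, "NDR", window, step, min_depth,
                 score_cut, min_len, merge_gap, exclude_chroms)
}

#' Call positioned nucleosomes
#'
#' Same strategy as [call_ndrs()] with the nucleosome defaults: 40-bp
#' windows, 20-bp steps, `-log10(p) > 3`, minimum merged length 60 bp, and
#' the opposite (protection = unmethylated-GCH-enriched) direction.
#'
#' @inheritParams call_ndrs
#' @export
call_nucleosomes <- function(calls, background = NULL, window = 40L,
                             step = 20L, min_depth = 3L, score_cut = 3,
                             min_len = 60L, merge_gap = 0L,
                             invert_directions = FALSE,
                             exclude_chroms = "lambda") {
  if (is.null(background))
    background <- compute_background(calls, min_depth, exclude_chroms)
  dir <- if (invert_directions) "open" else "closed"
  .call_segments(calls, background, dir, "nucleosome", window, step,
                 min_depth, score_cut, min_len, merge_gap, exclude_chroms)
}

#' Classify NDRs as proximal or distal to transcription start sites
#'
#' Distance is measured from the segment center (integer midpoint) to the
#' nearest TSS; an NDR is distal when its center lies at least
#' `proximal_cutoff` bp (default 2 kb) from every TSS, proximal otherwise
#' (the 2,000-bp tie is distal, reading "at least 2 kb away" literally).
#' Segments on chromosomes without any TSS are distal with infinite distance.
#'
#' @param segments a segment table from [call_ndrs()].
#' @param tss data.table/data.frame with `gene_id, chrom, pos` (TSS
#'   coordinates, 0-based); must be non-empty.
#' @param proximal_cutoff distance threshold in bp.
#' @return the segment table with `center, nearest_tss, distance, proximity`
#'   columns added.
#' @export
classify_ndrs <- function(segments, tss, proximal_cutoff = 2000L) {
  tss <- as.data.table(tss)
  if (nrow(tss) == 0L) stop("`tss` must contain at least one TSS")
  stopifnot(all(c("gene_id", "chrom", "pos") %in% names(tss)))
  seg <- as.data.table(segments)
  out <- copy(seg)[, center := (start + end) %/% 2L]
  if (nrow(out) == 0L) {
    out[, `:=`(nearest_tss = character(), distance = numeric(),
               proximity = character())]
    return(out[])
  }
  t <- tss[, .(chrom, pos, tss_pos = pos, gene_id)]
  data.table::setkey(t, chrom, pos)
  nn <- t[out[, .(chrom, pos = center)], on = c("chrom", "pos"),
          roll = "nearest"]
  out[, `:=`(nearest_tss = nn$gene_id,
             distance = abs(as.numeric(out$center) -
                              as.numeric(nn$tss_pos)))]
  out[is.na(distance), distance := Inf]
  out[, proximity := ifelse(distance < proximal_cutoff, "proximal",
                            "distal")]
  out[]
}

#' Merge segment calls across samples into a union set
#'
#' @param segment_list list of segment tables (e.g., per-sample NDR calls).
#' @param merge_gap merge intervals closer than this many bp (default 0).
#' @return data.table `chrom, start, end` of merged intervals.
#' @export
union_segments <- function(segment_list, merge_gap = 0L) {
  all <- rbindlist(lapply(segment_list, function(s)
    as.data.table(s)[, .(chrom, start, end)]))
  if (nrow(all) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  data.table::setorder(all, chrom, start)
  all[, grp := {
    prev_end <- data.table::shift(cummax(as.numeric(end)))
    cumsum(is.na(prev_end) | start > prev_end + merge_gap)
  }, by = chrom]
  out <- all[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Write segments as BED6
#'
#' `name` is the segment type and `score` is `min(1000, round(10 * -log10
#' p))`, clipping to the BED score range.
#'
#' @param segments a segment table.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_segments_bed <- function(segments, path) {
  seg <- as.data.table(segments)
  bed <- seg[order(chrom, start),
             .(chrom, start, end, name = seg_type,
               score = pmin(1000L, as.integer(round(10 * score))),
               strand = ".")]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
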