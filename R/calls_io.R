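# Per-cytosine bisulfite call table I/O and methylation levels.

.new_nome_calls <- function(sites, sample_id, species = "human",
                            stage = NA_character_, cell_type = NA_character_,
                            sex = NA_character_, replicate = NA_character_) {
  sites <- as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "strand", "context", "meth", "unmeth")
                %in% names(sites)))
  if (nrow(sites) && (any(sites$meth < 0) || any(sites$unmeth < 0)))
    stop("read counts must be non-negative")
  if (!is.factor(sites$context))
    sites[, context := factor(as.character(context),
                              levels = .context_levels)]
  data.table::setkey(sites, chrom, pos)
  structure(list(sites = sites, sample_id = sample_id, species = species,
                 stage = stage, cell_type = cell_type, sex = sex,
                 replicate = replicate),
            class = "nome_calls")
}

#' @export
print.nome_calls <- function(x, ...) {
  cat("NOMe-seq calls for sample '", x$sample_id, "' (", x$species,
      if (!is.na(x$cell_type)) paste0(", ", x$cell_type), ")\n", sep = "")
  cat(" ", format(nrow(x$sites), big.mark = ","), "sites on",
      data.table::uniqueN(x$sites$chrom), "sequence(s)\n")
  if (nrow(x$sites)) print(x$sites[, .N, by = context])
  invisible(x)
}

#' Read a per-cytosine bisulfite call table
#'
#' Accepts two tab-separated dialects, auto-detected from column 3:
#' \describe{
#'   \item{cytosine report}{`chrom, position (1-based), strand (+/-),
#'     methylated count, unmethylated count[, context string]`}
#'   \item{coverage}{`chrom, start (1-based), end, level %, methylated count,
#'     unmethylated count` (strand recovered from the context index)}
#' }
#' Rows are matched to the context index; rows at GCG/CCG positions are
#' dropped (ambiguous/off-target signal), rows at positions absent from the
#' index are dropped with a message, and duplicate rows for one site are
#' summed with a warning (merged lanes).
#'
#' @param path file path.
#' @param context_index a [build_context_index()] result for the matching
#'   reference.
#' @param sample_id,species,stage,cell_type,sex,replicate sample metadata.
#' @return a `nome_calls` object.
#' @export
read_cytosine_report <- function(path, context_index,
                                 sample_id = basename(path),
                                 species = "human", stage = NA, cell_type = NA,
                                 sex = NA, replicate = NA) {
  stopifnot(inherits(context_index, "context_index"))
  empty <- context_index$sites[0L][, `:=`(meth = integer(),
                                          unmeth = integer())]
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(.new_nome_calls(empty, sample_id, species, stage, cell_type,
                           sex, replicate))
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1L))
  if (ncol(raw) < 5L)
    stop("call table must have at least 5 tab-separated columns")
  is_report <- is.character(raw[[3L]]) && all(raw[[3L]] %in% c("+", "-"))
  if (is_report) {
    dt <- data.table(chrom = raw[[1L]], pos = as.integer(raw[[2L]]) - 1L,
                     strand = raw[[3L]], meth = raw[[4L]], unmeth = raw[[5L]])
  } else {
    if (ncol(raw) < 6L)
      stop("coverage-format table must have 6 columns")
    dt <- data.table(chrom = raw[[1L]], pos = as.integer(raw[[2L]]) - 1L,
                     strand = NA_character_, meth = raw[[5L]],
                     unmeth = raw[[6L]])
  }
  bad <- which(is.na(dt$pos) | is.na(dt$meth) | is.na(dt$unmeth) |
                 dt$meth < 0 | dt$unmeth < 0)
  if (length(bad))
    stop("malformed call-table row(s), e.g. line ", bad[1L], " of ", path)
  sl <- context_index$seqlengths
  known <- dt$chrom %in% names(sl)
  if (any(known)) {
    off <- known & (dt$pos < 0L | dt$pos >= unname(sl[dt$chrom]))
    if (any(off))
      stop("coordinate off chromosome at line ", which(off)[1L], " of ", path)
  }
  # collapse duplicate site rows before joining
  if (is_report) {
    dup <- anyDuplicated(dt, by = c("chrom", "pos", "strand"))
  } else {
    dup <- anyDuplicated(dt, by = c("chrom", "pos"))
  }
  if (dup) {
    warning("duplicate rows for single sites in ", path, "; counts summed")
    byc <- if (is_report) c("chrom", "pos", "strand") else c("chrom", "pos")
    dt <- dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = byc]
    if (!is_report) dt[, strand := NA_character_]
  }
  idx <- context_index$sites
  if (is_report) {
    merged <- idx[dt, on = c("chrom", "pos", "strand"), nomatch = NA]
  } else {
    merged <- idx[dt, on = c("chrom", "pos"), nomatch = NA]
  }
  n_unmatched <- sum(is.na(merged$context))
  if (n_unmatched > 0L)
    message(n_unmatched,
            " row(s) not present in the context index were dropped")
  merged <- merged[!is.na(context)]
  n_excl <- merged[context %in% c("GCG", "CCG"), .N]
  if (n_excl > 0L)
    message(n_excl, " GCG/CCG row(s) excluded from analysis")
  merged <- merged[!context %in% c("GCG", "CCG")]
  .new_nome_calls(merged[, .(chrom, pos, strand, context, meth, unmeth)],
                  sample_id, species, stage, cell_type, sex, replicate)
}

#' Write calls in the cytosine-report dialect
#'
#' Emits `chrom, 1-based position, strand, methylated, unmethylated, context`,
#' the same dialect [read_cytosine_report()] reads.
#'
#' @param calls a `nome_calls` object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_cytosine_report <- function(calls, path) {
  stopifnot(inherits(calls, "nome_calls"))
  out <- calls$sites[order(chrom, pos, strand),
                     .(chrom, pos = pos + 1L, strand, meth, unmeth,
                       context = as.character(context))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Per-site methylation level
#'
#' `meth / (meth + unmeth)`; `NA` (undefined, not 0) at zero depth.
#'
#' @param meth,unmeth non-negative read counts (vectorized).
#' @return numeric vector of levels in `[0, 1]` or `NA`.
#' @export
site_level <- function(meth, unmeth) {
  d <- meth + unmeth
  ifelse(d > 0, meth / d, NA_real_)
}

#' Pooled methylation level over regions
#'
#' Counts of all sites of `context_class` with depth `>= min_depth` inside
#' each region are summed and the level computed from the pooled counts
#' (count-weighted, not a mean of per-site levels). Regions are 0-based,
#' half-open.
#'
#' @param calls a `nome_calls` object.
#' @param regions data.table/data.frame with `chrom, start, end` and
#'   optionally `region_id` (generated if absent).
#' @param context_class `"GCH"` (accessibility) or `"WCG"` (endogenous
#'   methylation); `"OTHER"` also allowed.
#' @param min_depth minimum per-site depth (default 3, the standard filter).
#' @return data.table with `region_id, chrom, start, end, context,
#'   pooled_meth, pooled_unmeth, n_sites, level` (`level` is `NA` when no
#'   site qualifies).
#' @export
region_levels <- function(calls, regions, context_class = "GCH",
                          min_depth = 3L) {
  regions <- as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(regions$end >= regions$start))
  if (!"region_id" %in% names(regions))
    regions[, region_id := sprintf("%s:%d-%d", chrom, start, end)]
  sites <- .class_sites(calls, context_class, min_depth)
  pooled <- .pool_over_regions(sites, regions)
  out <- pooled[regions[, .(region_id, chrom, start, end)],
                on = "region_id"]
  out[is.na(pooled_meth), `:=`(pooled_meth = 0L, pooled_unmeth = 0L,
                               n_sites = 0L)]
  out[, `:=`(context = context_class,
             level = site_level(pooled_meth, pooled_unmeth))]
  out[, .(region_id, chrom, start, end, context, pooled_meth,
          pooled_unmeth, n_sites, level)]
}

#' @rdname region_levels
#' @param chrom,start,end a single region (alternative scalar interface).
#' @export
region_level <- function(calls, chrom, start, end, context_class = "GCH",
                         min_depth = 3L) {
  region_levels(calls, data.table(chrom = chrom, start = as.integer(start),
                                  end = as.integer(end)),
                context_class, min_depth)
}

#' Genome-wide pooled methylation level
#'
#' Count-pooled level over every qualifying site of a context class; this is
#' the "average methylation" statistic used for stage comparisons (WCG) and
#' the GCH genome background of segmentation.
#'
#' @inheritParams region_levels
#' @param exclude_chroms chromosomes to leave out (default the lambda
#'   spike-in contig).
#' @return a single level in `[0, 1]`, or `NA` when no site qualifies.
#' @export
genome_mean_level <- function(calls, context_class = "WCG", min_depth = 3L,
                              exclude_chroms = "lambda") {
  .pooled(.class_sites(calls, context_class, min_depth,
                       exclude_chroms))$level
}

#' Write per-site levels as bedGraph
#'
#' @inheritParams region_levels
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(calls, path, context_class = "GCH",
                           min_depth = 3L) {
  s <- .class_sites(calls, context_class, min_depth)
  bg <- s[order(chrom, pos),
          .(chrom, start = pos, end = pos + 1L,
            value = round(site_level(meth, unmeth), 4L))]
  data.table::fwrite(bg, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Combine call sets (e.g., a genomic sample with its lambda spike-in)
#'
#' @param x,y `nome_calls` objects; metadata is taken from `x`.
#' @return a `nome_calls` object with the union of sites.
#' @export
combine_calls <- function(x, y) {
  stopifnot(inherits(x, "nome_calls"), inherits(y, "nome_calls"))
  .new_nome_calls(rbindlist(list(x$sites, y$sites)), x$sample_id, x$species,
                  x$stage, x$cell_type, x$sex, x$replicate)
}
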