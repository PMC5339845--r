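# Internal helpers shared across modules. Coordinates are 0-based, half-open
# everywhere inside the package; 1-based conversion happens only in readers
# and writers of 1-based text formats.

# Pool site counts over a set of regions. `sites` must have chrom/pos/meth/
# unmeth; `regions` must have region_id/chrom/start/end (0-based half-open).
# Sites falling in several (possibly overlapping) regions contribute to each,
# which makes class-level pooling additive over intervals.
.pool_over_regions <- function(sites, regions) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  empty <- data.table(region_id = regions$region_id[0],
                      pooled_meth = integer(), pooled_unmeth = integer(),
                      n_sites = integer())
  if (nrow(sites) == 0L || nrow(regions) == 0L) return(empty)
  q <- sites[, .(chrom, qstart = pos, qend = pos, meth, unmeth)]
  r <- regions[, .(region_id, chrom, rstart = start, rend = end - 1L)]
  data.table::setkey(r, chrom, rstart, rend)
  ov <- data.table::foverlaps(q, r, by.x = c("chrom", "qstart", "qend"),
                              nomatch = NULL)
  ov[, .(pooled_meth = sum(meth), pooled_unmeth = sum(unmeth),
         n_sites = .N), by = region_id]
}

# depth-filtered site table for one context class (or several)
.class_sites <- function(calls, context_class, min_depth,
                         exclude_chroms = NULL) {
  stopifnot(inherits(calls, "nome_calls"), min_depth >= 1L)
  s <- calls$sites[context %in% context_class &
                     (meth + unmeth) >= min_depth]
  if (!is.null(exclude_chroms)) s <- s[!chrom %in% exclude_chroms]
  s
}

# pooled level over a site table; list(meth, unmeth, n, level)
.pooled <- function(sites) {
  m <- sum(as.numeric(sites$meth))
  u <- sum(as.numeric(sites$unmeth))
  list(meth = m, unmeth = u, n = nrow(sites),
       level = if (m + u > 0) m / (m + u) else NA_real_)
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

# named character vector of sequences from DNAStringSet / character input
.as_seq_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else {
    stop("`genome` must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("genome sequences must be named by chromosome")
  seqs
}

.context_levels <- c("WCG", "GCH", "GCG", "CCG", "OTHER")
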