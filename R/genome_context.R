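#' Classify a cytosine's strand-local trinucleotide context
#'
#' NOMe-seq partitions cytosines by the trinucleotide read 5'->3' on the
#' strand carrying the cytosine: `WCG` (ACG/TCG) reports endogenous CpG
#' methylation, `GCH` (GCA/GCT/GCC) reports M.CviPI accessibility, `GCG` and
#' `CCG` are excluded (ambiguous endogenous/enzymatic signal and enzyme
#' off-target, respectively) and everything else - including any N flank - is
#' `OTHER`.
#'
#' @param preceding_base,base,following_base character vectors of single
#'   upper-case bases; `base` must be `"C"` everywhere (callers only pass
#'   cytosines).
#' @return factor with levels `WCG, GCH, GCG, CCG, OTHER`.
#' @examples
#' classify_cytosine_context(c("A", "G", "G", "A"), rep("C", 4),
#'                           c("G", "G", "A", "A"))
#' @export
classify_cytosine_context <- function(preceding_base, base, following_base) {
  n <- length(base)
  if (length(preceding_base) != n || length(following_base) != n)
    stop("flanking base vectors must match the length of `base`")
  if (any(base != "C"))
    stop("`base` must be 'C' at every position; got non-cytosine input")
  bad <- !(preceding_base %in% c("A", "C", "G", "T", "N")) |
    !(following_base %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop("flanking bases must be one of A, C, G, T, N")
  out <- rep("OTHER", n)
  out[preceding_base %in% c("A", "T") & following_base == "G"] <- "WCG"
  out[preceding_base == "G" & following_base %in% c("A", "T", "C")] <- "GCH"
  out[preceding_base == "G" & following_base == "G"] <- "GCG"
  out[preceding_base == "C" & following_base == "G"] <- "CCG"
  factor(out, levels = .context_levels)
}

#' Index every cytosine of a genome by NOMe-seq context class
#'
#' Scans both strands: a C on the plus strand is a plus-strand site, a G on
#' the plus strand is a minus-strand cytosine whose context is read 5'->3' on
#' the minus strand. Minus-strand sites are reported at the plus-strand
#' coordinate of the G; strands are never collapsed because GpC on one strand
#' is generally not GpC on the other. Sites at sequence edges or with N in the
#' trinucleotide classify as `OTHER`.
#'
#' @param genome a `Biostrings::DNAStringSet` or named character vector of
#'   upper-case sequences (alphabet A/C/G/T/N).
#' @return object of class `context_index`: list with `sites` (data.table
#'   `chrom`, `pos` 0-based, `strand`, `context`) and `seqlengths`.
#' @seealso [context_sites()], [write_context_bed()]
#' @export
build_context_index <- function(genome) {
  seqs <- .as_seq_set(genome)
  if (length(seqs) == 0L) stop("`genome` is empty")
  per_chrom <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n == 0L)
      return(data.table(chrom = character(), pos = integer(),
                        strand = character(), context = character()))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(ch %in% c("A", "C", "G", "T", "N")))
      stop("sequence '", nm, "' contains letters outside A/C/G/T/N")
    padded <- c("N", ch, "N")                  # padded[i + 1] == ch[i]
    ip <- which(ch == "C")                     # plus-strand cytosines
    im <- which(ch == "G")                     # minus-strand cytosines
    plus <- if (length(ip)) data.table(
      chrom = nm, pos = ip - 1L, strand = "+",
      context = as.character(
        classify_cytosine_context(padded[ip], rep("C", length(ip)),
                                  padded[ip + 2L]))
    ) else NULL
    minus <- if (length(im)) data.table(
      chrom = nm, pos = im - 1L, strand = "-",
      context = as.character(
        classify_cytosine_context(.complement(padded[im + 2L]),
                                  rep("C", length(im)),
                                  .complement(padded[im])))
    ) else NULL
    rbindlist(list(plus, minus))
  })
  sites <- rbindlist(per_chrom)
  if (nrow(sites)) {
    sites[, context := factor(context, levels = .context_levels)]
    data.table::setkey(sites, chrom, pos)
  } else {
    sites <- data.table(chrom = character(), pos = integer(),
                        strand = character(),
                        context = factor(character(),
                                         levels = .context_levels))
  }
  structure(list(sites = sites,
                 seqlengths = setNames(nchar(seqs), names(seqs))),
            class = "context_index")
}

#' @export
print.context_index <- function(x, ...) {
  cat("NOMe-seq context index:", length(x$seqlengths), "sequence(s),",
      format(sum(as.numeric(x$seqlengths)), big.mark = ","), "bp\n")
  print(x$sites[, .N, by = context])
  invisible(x)
}

#' Extract indexed cytosine sites
#'
#' @param index a [build_context_index()] result.
#' @param classes context classes to keep (default: the two analyzable ones).
#' @param chroms optional chromosome filter.
#' @return data.table `chrom, pos, strand, context`.
#' @export
context_sites <- function(index, classes = c("WCG", "GCH"), chroms = NULL) {
  stopifnot(inherits(index, "context_index"))
  s <- index$sites[context %in% classes]
  if (!is.null(chroms)) s <- s[chrom %in% chroms]
  s[]
}

#' Write context sites as BED6
#'
#' One 1-bp interval per site (`chrom, pos, pos + 1, class, 0, strand`),
#' 0-based half-open per the BED standard.
#'
#' @inheritParams context_sites
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_context_bed <- function(index, path, classes = c("WCG", "GCH")) {
  s <- context_sites(index, classes)
  bed <- s[order(chrom, pos),
           .(chrom, start = pos, end = pos + 1L,
             name = as.character(context), score = 0L, strand)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
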