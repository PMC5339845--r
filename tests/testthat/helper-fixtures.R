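library(data.table)

# build a nome_calls object from bare site rows
make_calls <- function(chrom, pos, strand, context, meth, unmeth,
                       sample_id = "toy", ...) {
  nomeseqr:::.new_nome_calls(
    data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
               context = context, meth = as.integer(meth),
               unmeth = as.integer(unmeth)),
    sample_id = sample_id, ...)
}

# independent 2x2 chi-squared oracle: expected counts from the margins,
# sum of (O - E)^2 / E, 1 df (no continuity correction)
chi2_oracle <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  if (any(e == 0)) return(list(stat = 0, p = 1))
  stat <- sum((o - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# reverse complement of a plain character sequence
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
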