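# Synthetic NOMe-seq generator. Produces a random genome with planted
# chromatin architecture (standalone NDRs, promoter NDRs with phased
# nucleosome arrays downstream of TSSs, labelled repeat compartments), then
# per-site binomial read counts under the NOMe chemistry:
#   GCH  P(read methylated) = open * efficiency
#                             + (1 - open * efficiency) * conversion_failure
#   WCG  P(read methylated) = wcg + (1 - wcg) * conversion_failure
# plus an unmethylated lambda spike-in, and an expression table coupled
# positively to promoter openness and negatively to promoter methylation.
# Every run is reproducible from the seed; the truth set is serializable.

#' Simulation configuration
#'
#' All planted levels and rates of the generator. The defaults are the
#' standard study conditions: 1 Mb genome, 200 standalone NDRs of 300 bp
#' with open probability 0.85 inside vs 0.15 outside, 147/53 bp phased
#' nucleosome arrays at protection 0.9 downstream of TSSs, M.CviPI
#' efficiency 0.93 and conversion failure 0.013 (i.e., 98.7% conversion),
#' endogenous WCG levels of 0.65 (soma) and 0.07 (FGC), and mean depth 20.
#'
#' @param seed base random seed; all derived seeds stay below 2^31.
#' @param genome_length,gc_fraction,chrom_name random genome parameters.
#' @param n_ndr,ndr_length standalone planted NDRs.
#' @param open_prob_ndr,open_prob_bg open probability inside planted NDRs /
#'   in unannotated background.
#' @param n_genes number of gene models; each gets a promoter NDR of
#'   `ndr_length` centred on its TSS and a phased array downstream.
#' @param promoter_open_range per-gene promoter open probabilities are drawn
#'   uniformly from this range (genes without a group assignment).
#' @param n_nucleosomes,nucleosome_length,linker_length,protection,linker_open
#'   phased-array geometry: number of nucleosomes, protected length, linker
#'   length, protection probability (protected open prob = 1 - protection),
#'   linker open probability.
#' @param efficiency,conversion_failure M.CviPI efficiency and bisulfite
#'   conversion-failure rate.
#' @param wcg_levels named endogenous WCG levels per cell type.
#' @param cell_type default cell type for single-sample simulation.
#' @param mean_depth,depth_dispersion negative-binomial coverage model
#'   (mean and size).
#' @param lambda_length,lambda_gc,lambda_chrom,spike_fraction lambda
#'   spike-in contig; `spike_fraction` scales its coverage relative to
#'   `mean_depth` (the spike fraction is a free parameter of the protocol).
#' @param promoter_wcg_sd per-gene jitter of the promoter methylation
#'   fraction.
#' @param expr_intercept,expr_access_coef,expr_meth_coef,expr_noise_sd
#'   expression coupling: `log10 RPKM = intercept + access_coef * open +
#'   meth_coef * promoter_wcg + noise`; `access_coef > 0`,
#'   `meth_coef < 0`.
#' @param n_specific_per_group,group_names,specific_open_high,specific_open_low
#'   cohort design: per group, this many genes whose promoter is open
#'   (`specific_open_high`) only in samples of that group and closed
#'   (`specific_open_low`) elsewhere.
#' @param repeat_classes data.frame describing repeat compartments
#'   (see [default_repeat_classes()]), or `NULL` for none.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6, gc_fraction = 0.40,
                       chrom_name = "chr1",
                       n_ndr = 200L, ndr_length = 300L,
                       open_prob_ndr = 0.85, open_prob_bg = 0.15,
                       n_genes = 0L, promoter_open_range = c(0.05, 0.95),
                       n_nucleosomes = 3L, nucleosome_length = 147L,
                       linker_length = 53L, protection = 0.90,
                       linker_open = 0.85,
                       efficiency = 0.93, conversion_failure = 0.013,
                       wcg_levels = c(soma = 0.65, fgc = 0.07,
                                      heart = 0.729, epiblast = 0.777),
                       cell_type = "soma",
                       mean_depth = 20, depth_dispersion = 8,
                       lambda_length = 48502L, lambda_gc = 0.50,
                       lambda_chrom = "lambda", spike_fraction = 0.05,
                       promoter_wcg_sd = 0.10,
                       expr_intercept = -2, expr_access_coef = 4,
                       expr_meth_coef = -2, expr_noise_sd = 0.3,
                       n_specific_per_group = 0L,
                       group_names = c("heart", "fgc", "soma"),
                       specific_open_high = 0.85,
                       specific_open_low = 0.15,
                       repeat_classes = NULL) {
  cfg <- as.list(environment())
  probs <- c(cfg$gc_fraction, cfg$open_prob_ndr, cfg$open_prob_bg,
             cfg$protection, cfg$linker_open, cfg$efficiency,
             cfg$conversion_failure, cfg$wcg_levels, cfg$lambda_gc,
             cfg$spike_fraction, cfg$promoter_open_range,
             cfg$specific_open_high, cfg$specific_open_low)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (!cfg$cell_type %in% names(cfg$wcg_levels))
    stop("cell_type must name an entry of wcg_levels")
  if (!is.null(cfg$repeat_classes))
    cfg$repeat_classes <- as.data.table(cfg$repeat_classes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Default repeat compartments for the generator
#'
#' Planted accessibility and residual-methylation levels reproducing the
#' qualitative germline repeat biology: SVA most open; L1 (young) less open
#' and more methylated than L2 (old); Alu (young) less open and more
#' methylated than MIR (old). The WCG levels are absolute residual levels,
#' i.e. the hypomethylated-germline regime.
#'
#' @return data.table `class_label, family, subfamily, n, length,
#'   open_prob, wcg_level`.
#' @export
default_repeat_classes <- function() {
  data.table(
    class_label = c("SVA", "LINE", "LINE", "SINE", "SINE", "LTR"),
    family = c("SVA", "LINE", "LINE", "SINE", "SINE", "LTR"),
    subfamily = c("SVA", "L1", "L2", "Alu", "MIR", "LTR"),
    n = c(60L, 60L, 60L, 60L, 60L, 60L),
    length = c(400L, 600L, 500L, 300L, 300L, 500L),
    open_prob = c(0.70, 0.10, 0.40, 0.15, 0.35, 0.20),
    wcg_level = c(0.20, 0.30, 0.10, 0.25, 0.12, 0.20))
}

# random i.i.d. sequence at a GC fraction
.random_sequence <- function(length, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# paint value over 0-based half-open intervals of a per-base vector
.paint <- function(v, start, end, value) {
  if (length(start) == 0L) return(v)
  value <- rep_len(value, length(start))
  s <- pmax(0L, as.integer(start)); e <- pmin(length(v), as.integer(end))
  for (i in seq_along(s)) if (e[i] > s[i]) v[(s[i] + 1L):e[i]] <- value[i]
  v
}

#' Simulate a reference genome with planted chromatin architecture
#'
#' Lays out genes, standalone NDRs and repeat intervals on non-overlapping
#' slots of a single random chromosome, builds the context index, and
#' records the truth set. Gene models carry a promoter NDR centred on the
#' TSS, `n_nucleosomes` phased nucleosomes downstream (mirrored for
#' minus-strand genes), a TES, and two exons.
#'
#' @param config a [sim_config()].
#' @return object of class `nome_simulation`: list with `genome` (named
#'   character), `context_index`, `genes`, `ndrs`, `nucleosomes`,
#'   `repeats`, `exons`, and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  half <- as.integer(config$ndr_length) %/% 2L
  period <- config$nucleosome_length + config$linker_length
  gene_extent <- half + config$n_nucleosomes * period + 500L
  reps <- if (is.null(config$repeat_classes)) {
    data.table(class_label = character(), family = character(),
               subfamily = character(), n = integer(), length = integer(),
               open_prob = numeric(), wcg_level = numeric())
  } else config$repeat_classes
  feat <- rbindlist(list(
    if (config$n_genes > 0L)
      data.table(kind = "gene", idx = seq_len(config$n_genes),
                 extent = gene_extent),
    if (config$n_ndr > 0L)
      data.table(kind = "ndr", idx = seq_len(config$n_ndr),
                 extent = half),
    if (nrow(reps))
      reps[, .(kind = "repeat", idx = seq_len(sum(n)),
               extent = as.integer(rep(length, n) %/% 2L),
               class_label = rep(class_label, n),
               family = rep(family, n), subfamily = rep(subfamily, n),
               open_prob = rep(open_prob, n),
               wcg_level = rep(wcg_level, n))]
  ), fill = TRUE)
  genes <- data.table(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      tes = integer(), group = character(),
                      open_prob = numeric(), wcg_eps = numeric())
  ndrs <- data.table(chrom = character(), start = integer(),
                     end = integer(), open_prob = numeric(),
                     kind = character(), gene_id = character())
  nucs <- data.table(chrom = character(), start = integer(),
                     end = integer(), gene_id = character(),
                     index = integer())
  repints <- data.table(chrom = character(), start = integer(),
                        end = integer(), class_label = character(),
                        family = character(), subfamily = character(),
                        open_prob = numeric(), wcg_level = numeric())
  exons <- data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer())
  if (nrow(feat)) {
    n_feat <- nrow(feat)
    slot <- L %/% n_feat
    margin <- 50L
    if (any(slot < 2L * feat$extent + 2L * margin))
      stop("genome_length too small for the requested features")
    feat <- feat[sample(n_feat)]
    play <- slot - 2L * feat$extent - 2L * margin
    feat[, center := as.integer((seq_len(n_feat) - 1L) * slot + margin +
                                  extent + floor(runif(n_feat) * play))]
    fg <- feat[kind == "gene"]
    if (nrow(fg)) {
      ng <- nrow(fg)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      sign <- ifelse(strand == "+", 1L, -1L)
      tss <- fg$center
      open <- runif(ng, config$promoter_open_range[1L],
                    config$promoter_open_range[2L])
      group <- rep("none", ng)
      nspec <- config$n_specific_per_group
      if (nspec > 0L) {
        need <- nspec * length(config$group_names)
        if (need > ng)
          stop("n_genes too small for the requested specific genes")
        group[seq_len(need)] <- rep(config$group_names, each = nspec)
        open[seq_len(need)] <- config$specific_open_low
      }
      tes <- tss + sign * (half + config$n_nucleosomes * period + 500L)
      genes <- data.table(
        gene_id = sprintf("gene%04d", seq_len(ng)),
        chrom = config$chrom_name, strand = strand, tss = tss, tes = tes,
        group = group, open_prob = open,
        wcg_eps = rnorm(ng, 0, config$promoter_wcg_sd))
      ndrs <- rbindlist(list(ndrs, data.table(
        chrom = config$chrom_name, start = tss - half, end = tss + half,
        open_prob = open, kind = "promoter", gene_id = genes$gene_id)))
      if (config$n_nucleosomes > 0L) {
        nucs <- rbindlist(list(nucs, rbindlist(lapply(
          seq_len(config$n_nucleosomes), function(k) {
            s_plus <- tss + half + (k - 1L) * period
            s_minus <- tss - half - (k - 1L) * period -
              config$nucleosome_length
            s <- ifelse(sign > 0, s_plus, s_minus)
            data.table(chrom = config$chrom_name, start = as.integer(s),
                       end = as.integer(s + config$nucleosome_length),
                       gene_id = genes$gene_id, index = k)
          }))))
      }
      exons <- rbindlist(list(exons, rbindlist(list(
        data.table(gene_id = genes$gene_id, chrom = config$chrom_name,
                   start = as.integer(pmin(tss, tss + sign * 150L)),
                   end = as.integer(pmax(tss, tss + sign * 150L))),
        data.table(gene_id = genes$gene_id, chrom = config$chrom_name,
                   start = as.integer(pmin(tes, tes - sign * 200L)),
                   end = as.integer(pmax(tes, tes - sign * 200L)))))))
    }
    fn <- feat[kind == "ndr"]
    if (nrow(fn))
      ndrs <- rbindlist(list(ndrs, data.table(
        chrom = config$chrom_name, start = fn$center - half,
        end = fn$center + half, open_prob = config$open_prob_ndr,
        kind = "standalone", gene_id = NA_character_)))
    fr <- feat[kind == "repeat"]
    if (nrow(fr))
      repints <- rbindlist(list(repints, fr[, .(
        chrom = config$chrom_name, start = center - extent,
        end = center + extent, class_label, family, subfamily,
        open_prob, wcg_level)]))
  }
  seq <- .random_sequence(L, config$gc_fraction)
  genome <- setNames(seq, config$chrom_name)
  structure(list(genome = genome,
                 context_index = build_context_index(genome),
                 genes = genes, ndrs = ndrs, nucleosomes = nucs,
                 repeats = repints, exons = exons, config = config),
            class = "nome_simulation")
}

#' @export
print.nome_simulation <- function(x, ...) {
  cat("Synthetic NOMe-seq genome:",
      format(nchar(x$genome[[1L]]), big.mark = ","), "bp;",
      nrow(x$genes), "genes,", nrow(x$ndrs), "planted NDRs,",
      nrow(x$nucleosomes), "planted nucleosomes,",
      nrow(x$repeats), "repeat intervals\n")
  invisible(x)
}

# per-gene promoter open probability for a sample of the given group
.gene_open <- function(sim, group = NULL) {
  g <- sim$genes
  cfg <- sim$config
  if (nrow(g) == 0L) return(numeric())
  open <- g$open_prob
  if (!is.null(group)) {
    open[g$group != "none"] <- ifelse(g$group[g$group != "none"] == group,
                                      cfg$specific_open_high,
                                      cfg$specific_open_low)
  }
  open
}

# per-base open-probability vector for one sample
.open_vector <- function(sim, gene_open) {
  cfg <- sim$config
  v <- rep(cfg$open_prob_bg, nchar(sim$genome[[1L]]))
  if (nrow(sim$repeats))
    v <- .paint(v, sim$repeats$start, sim$repeats$end,
                sim$repeats$open_prob)
  st <- sim$ndrs[kind == "standalone"]
  v <- .paint(v, st$start, st$end, st$open_prob)
  if (nrow(sim$genes)) {
    period <- cfg$nucleosome_length + cfg$linker_length
    half <- cfg$ndr_length %/% 2L
    sign <- ifelse(sim$genes$strand == "+", 1L, -1L)
    span <- cfg$n_nucleosomes * period
    a_start <- ifelse(sign > 0, sim$genes$tss + half,
                      sim$genes$tss - half - span)
    v <- .paint(v, a_start, a_start + span, cfg$linker_open)
    v <- .paint(v, sim$nucleosomes$start, sim$nucleosomes$end,
                1 - cfg$protection)
    pr <- sim$ndrs[kind == "promoter"]
    v <- .paint(v, pr$start, pr$end,
                gene_open[match(pr$gene_id, sim$genes$gene_id)])
  }
  v
}

# per-base endogenous WCG level vector
.wcg_vector <- function(sim, cell_type, gene_open) {
  cfg <- sim$config
  bg <- unname(cfg$wcg_levels[cell_type])
  v <- rep(bg, nchar(sim$genome[[1L]]))
  if (nrow(sim$repeats))
    v <- .paint(v, sim$repeats$start, sim$repeats$end,
                sim$repeats$wcg_level)
  if (nrow(sim$genes)) {
    frac <- pmin(1, pmax(0, 1 - gene_open + sim$genes$wcg_eps))
    v <- .paint(v, sim$genes$tss - 500L, sim$genes$tss + 500L, bg * frac)
  }
  v
}

#' Simulate one NOMe-seq sample from a planted genome
#'
#' Draws a negative-binomial depth per WCG/GCH site (zero-depth sites are
#' uncovered and dropped) and binomial methylated counts at the chemistry
#' probabilities given the planted per-base open probability and endogenous
#' methylation level. GCG/CCG sites are not emitted - they would be
#' excluded on input anyway.
#'
#' @param sim a [simulate_genome()] result.
#' @param cell_type entry of `config$wcg_levels` setting the endogenous
#'   methylation regime (default from the config).
#' @param group optional cohort group; group-specific genes are open only
#'   in samples of their own group.
#' @param sample_id sample name.
#' @param seed random seed (default derived from the config seed).
#' @return a `nome_calls` object.
#' @export
simulate_sample <- function(sim, cell_type = sim$config$cell_type,
                            group = NULL,
                            sample_id = paste0("sim_", cell_type),
                            seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "nome_simulation"))
  cfg <- sim$config
  if (!cell_type %in% names(cfg$wcg_levels))
    stop("unknown cell_type: ", cell_type)
  set.seed(as.integer(seed))
  gene_open <- .gene_open(sim, group)
  open <- .open_vector(sim, gene_open)
  wcg <- .wcg_vector(sim, cell_type, gene_open)
  sites <- sim$context_index$sites[context %in% c("WCG", "GCH")]
  n <- nrow(sites)
  depth <- stats::rnbinom(n, mu = cfg$mean_depth,
                          size = cfg$depth_dispersion)
  keep <- depth > 0L
  sites <- sites[keep]; depth <- depth[keep]
  m_enz <- open[sites$pos + 1L] * cfg$efficiency
  p <- ifelse(sites$context == "GCH",
              m_enz + (1 - m_enz) * cfg$conversion_failure,
              wcg[sites$pos + 1L] +
                (1 - wcg[sites$pos + 1L]) * cfg$conversion_failure)
  meth <- stats::rbinom(nrow(sites), depth, p)
  out <- sites[, .(chrom, pos, strand, context)]
  out[, `:=`(meth = meth, unmeth = depth - meth)]
  .new_nome_calls(out, sample_id, species = "synthetic",
                  cell_type = cell_type,
                  stage = if (is.null(group)) NA_character_ else group)
}

#' Simulate the unmethylated lambda spike-in
#'
#' Lambda carries no endogenous methylation, so GCH sites read methylated at
#' `efficiency + (1 - efficiency) * conversion_failure` and every other
#' cytosine at `conversion_failure`. Coverage is `mean_depth *
#' spike_fraction / 0.05` (the default spike fraction maps to the sample
#' depth). All context classes are emitted, including GCG/CCG, which the
#' QC estimators must exclude.
#'
#' @param config a [sim_config()].
#' @param sample_id sample name.
#' @param seed random seed (default derived from the config seed).
#' @return a `nome_calls` object on the lambda contig.
#' @export
simulate_lambda <- function(config, sample_id = "sim_lambda",
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  seq <- .random_sequence(as.integer(config$lambda_length),
                          config$lambda_gc)
  idx <- build_context_index(setNames(seq, config$lambda_chrom))
  sites <- idx$sites
  mu <- config$mean_depth * config$spike_fraction / 0.05
  depth <- stats::rnbinom(nrow(sites), mu = mu,
                          size = config$depth_dispersion)
  keep <- depth > 0L
  sites <- sites[keep]; depth <- depth[keep]
  p <- ifelse(sites$context == "GCH",
              config$efficiency +
                (1 - config$efficiency) * config$conversion_failure,
              config$conversion_failure)
  meth <- stats::rbinom(nrow(sites), depth, p)
  out <- sites[, .(chrom, pos, strand, context)]
  out[, `:=`(meth = meth, unmeth = depth - meth)]
  .new_nome_calls(out, sample_id, species = "lambda")
}

#' Simulate an expression table coupled to promoter state
#'
#' `log10 RPKM = intercept + access_coef * open + meth_coef * wcg + noise`
#' with positive accessibility coupling and negative methylation coupling;
#' `open` is the gene's promoter open probability in this sample and `wcg`
#' its planted promoter methylation level.
#'
#' @inheritParams simulate_sample
#' @param noise_sd log10-scale noise standard deviation (default from the
#'   config).
#' @return data.table `gene_id, rpkm`.
#' @export
simulate_expression <- function(sim, cell_type = sim$config$cell_type,
                                group = NULL,
                                noise_sd = sim$config$expr_noise_sd,
                                seed = sim$config$seed + 3L) {
  stopifnot(inherits(sim, "nome_simulation"))
  cfg <- sim$config
  if (nrow(sim$genes) == 0L)
    return(data.table(gene_id = character(), rpkm = numeric()))
  set.seed(as.integer(seed))
  open <- .gene_open(sim, group)
  bg <- unname(cfg$wcg_levels[cell_type])
  wcg <- bg * pmin(1, pmax(0, 1 - open + sim$genes$wcg_eps))
  x <- cfg$expr_intercept + cfg$expr_access_coef * open +
    cfg$expr_meth_coef * wcg + stats::rnorm(length(open), 0, noise_sd)
  data.table(gene_id = sim$genes$gene_id, rpkm = 10^x)
}

#' Simulate a multi-sample cohort with group-specific promoter NDRs
#'
#' Builds one genome (requires `n_specific_per_group > 0` for planted
#' specificity), then `n_per_group` replicate samples per group with
#' matched expression. Group names that match an entry of `wcg_levels` use
#' that endogenous regime; others fall back to the config cell type.
#'
#' @param config a [sim_config()] with `n_genes` and
#'   `n_specific_per_group` set.
#' @param n_per_group replicates per group.
#' @return list with `sim`, `samples` (named list of `nome_calls`),
#'   `expression` (gene x sample matrix), and `sample_sheet`
#'   (`sample_id, group, cell_type`).
#' @export
simulate_cohort <- function(config, n_per_group = 3L) {
  sim <- simulate_genome(config)
  cfg <- sim$config
  sheet <- data.table(
    group = rep(cfg$group_names, each = n_per_group),
    replicate = rep(seq_len(n_per_group), length(cfg$group_names)))
  sheet[, sample_id := sprintf("%s_rep%d", group, replicate)]
  sheet[, cell_type := ifelse(group %in% names(cfg$wcg_levels), group,
                              cfg$cell_type)]
  samples <- vector("list", nrow(sheet))
  exprs <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    samples[[i]] <- simulate_sample(
      sim, cell_type = sheet$cell_type[i], group = sheet$group[i],
      sample_id = sheet$sample_id[i], seed = cfg$seed + 100L + i)
    exprs[[i]] <- simulate_expression(
      sim, cell_type = sheet$cell_type[i], group = sheet$group[i],
      seed = cfg$seed + 500L + i)$rpkm
  }
  names(samples) <- sheet$sample_id
  expression <- do.call(cbind, exprs)
  rownames(expression) <- sim$genes$gene_id
  colnames(expression) <- sheet$sample_id
  list(sim = sim, samples = samples, expression = expression,
       sample_sheet = sheet[])
}

#' Serialize / restore the truth set
#'
#' Writes the planted intervals, gene models and generating parameters as
#' JSON so recovery tests can run against files rather than in-memory
#' objects.
#'
#' @param sim a [simulate_genome()] result.
#' @param path JSON file path.
#' @return invisibly the path; `read_truth()` returns the truth list with
#'   data.table components.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "nome_simulation"))
  truth <- list(genes = sim$genes, ndrs = sim$ndrs,
                nucleosomes = sim$nucleosomes, repeats = sim$repeats,
                exons = sim$exons,
                lambda = list(efficiency = sim$config$efficiency,
                              conversion_rate =
                                1 - sim$config$conversion_failure),
                config = unclass(sim$config))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("genes", "ndrs", "nucleosomes", "repeats", "exons"))
    truth[[nm]] <- as.data.table(truth[[nm]])
  truth
}

#' Write the simulated genome as FASTA
#'
#' @param sim a [simulate_genome()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_genome_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), path)
  invisible(path)
}
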