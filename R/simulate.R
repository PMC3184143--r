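## Synthetic-study generator. Emulates the statistical structure of a
## repressive-histone-mark ChIP-Seq study: a genome of known size, genes
## with log-scale expression, mark domains preferentially placed near
## low-expression genes, Poisson read pileups with fold enrichment over
## the domains, and K "virtual caller" peak sets with differing
## sensitivity, boundary jitter, merge distance and false-positive rate.

#' Virtual-caller profile
#'
#' Describes how a virtual peak caller distorts the true domain set: it
#' reports each true domain with probability `sensitivity`, jitters both
#' endpoints by a rounded Gaussian with SD `jitter_sd` bp, adds
#' Poisson-distributed false peaks at `fp_per_mb` per megabase (placed
#' uniformly outside true domains), and finally merges reported peaks whose
#' gap is smaller than `merge_gap` bp.
#'
#' @param name caller label.
#' @param sensitivity per-domain report probability in \[0, 1\].
#' @param fp_per_mb expected false peaks per Mb of genome.
#' @param jitter_sd boundary jitter SD in bp.
#' @param merge_gap merge distance in bp (0 = merge only overlapping peaks).
#' @export
caller_profile <- function(name, sensitivity, fp_per_mb = 0,
                           jitter_sd = 0, merge_gap = 0) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            fp_per_mb >= 0, jitter_sd >= 0, merge_gap >= 0)
  structure(list(name = as.character(name), sensitivity = sensitivity,
                 fp_per_mb = fp_per_mb, jitter_sd = jitter_sd,
                 merge_gap = merge_gap),
            class = "caller_profile")
}

#' Default virtual-caller profiles
#'
#' Four profiles spanning the qualitative behaviours seen among real peak
#' callers: a conservative high-resolution caller (`sharp`), a permissive
#' broad caller with many false positives (`broad`), a sensitive caller
#' without input correction (`nocontrol`), and a caller that aggressively
#' merges nearby peaks (`merged`).
#'
#' @return list of [caller_profile()] objects.
#' @export
default_caller_profiles <- function() {
  list(
    caller_profile("sharp", sensitivity = 0.55, fp_per_mb = 0.1,
                   jitter_sd = 50, merge_gap = 0),
    caller_profile("broad", sensitivity = 0.98, fp_per_mb = 5,
                   jitter_sd = 300, merge_gap = 2000),
    caller_profile("nocontrol", sensitivity = 0.85, fp_per_mb = 1,
                   jitter_sd = 100, merge_gap = 200),
    caller_profile("merged", sensitivity = 0.80, fp_per_mb = 0.2,
                   jitter_sd = 150, merge_gap = 1000)
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic study. The defaults define the study
#' conditions used throughout this package's analyses: 2,000 genes on an
#' 18 Mb three-chromosome genome, a quarter of genes carrying a true
#' repressive domain (placed within the body, upstream or downstream of the
#' gene, strand-relative), an 8-fold odds multiplier pushing marked genes
#' into the low-expression tail, and Poisson pileups with 8-fold enrichment
#' over a background of 2 reads/bp.
#'
#' @param seed integer seed; the seed fully determines the simulated study.
#' @param chrom_lengths named bp lengths; must be multiples of `bin_size`.
#' @param n_genes number of genes.
#' @param gene_length_range min/max gene length in bp.
#' @param mark_fraction fraction of genes carrying a true domain.
#' @param placement_mix named probabilities over `within`, `upstream`,
#'   `downstream`; must sum to 1.
#' @param repression_odds odds multiplier that a marked gene falls in the
#'   low-expression tail (1 = no planted association).
#' @param expression_logmean,expression_logsd log10-scale location and
#'   spread of raw expression values.
#' @param background_depth mean read depth per bp outside domains.
#' @param enrichment_fold depth multiplier over true domains (> 1).
#' @param domain_length_range min/max true-domain length in bp.
#' @param flank_window bp of flank on each side of a gene reserved for
#'   upstream/downstream domains; genes are spaced at least
#'   `2 * flank_window` apart so every domain maps to exactly one gene.
#' @param bin_size bp per pileup bin; depth is drawn once per bin.
#' @param caller_profiles list of [caller_profile()] objects.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr01 = 6e6, chr02 = 6e6, chr03 = 6e6),
                       n_genes = 2000L,
                       gene_length_range = c(1000, 3000),
                       mark_fraction = 0.25,
                       placement_mix = c(within = 0.5, upstream = 0.3,
                                         downstream = 0.2),
                       repression_odds = 8,
                       expression_logmean = 2,
                       expression_logsd = 1,
                       background_depth = 2,
                       enrichment_fold = 8,
                       domain_length_range = c(500, 2000),
                       flank_window = 2000,
                       bin_size = 10L,
                       caller_profiles = default_caller_profiles()) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (any(chrom_lengths %% bin_size != 0))
    stop("chrom_lengths must be multiples of bin_size")
  if (abs(sum(placement_mix) - 1) > 1e-8 || any(placement_mix < 0) ||
      !setequal(names(placement_mix), c("within", "upstream", "downstream")))
    stop("placement_mix must be named probabilities over within/upstream/downstream summing to 1")
  if (mark_fraction < 0 || mark_fraction > 1)
    stop("mark_fraction must be in [0, 1]")
  if (enrichment_fold <= 1) stop("enrichment_fold must be > 1")
  if (repression_odds <= 0) stop("repression_odds must be > 0")
  stopifnot(gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1],
            domain_length_range[1] > 0,
            domain_length_range[2] >= domain_length_range[1],
            background_depth > 0, flank_window >= 0, bin_size >= 1)
  if (domain_length_range[2] > flank_window)
    stop("domain_length_range max must not exceed flank_window, ",
         "else flank domains could spill past a gene's own windows")
  nm <- vapply(caller_profiles, function(p) p$name, "")
  if (anyDuplicated(nm)) stop("duplicate caller profile names")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 mark_fraction = mark_fraction,
                 placement_mix = placement_mix[c("within", "upstream", "downstream")],
                 repression_odds = repression_odds,
                 expression_logmean = expression_logmean,
                 expression_logsd = expression_logsd,
                 background_depth = background_depth,
                 enrichment_fold = enrichment_fold,
                 domain_length_range = domain_length_range,
                 flank_window = flank_window,
                 bin_size = as.integer(bin_size),
                 caller_profiles = caller_profiles),
            class = "sim_config")
}

# snap a coordinate down to the bin grid
snap <- function(x, bin) floor(x / bin) * bin

#' Simulate a complete synthetic ChIP-Seq study
#'
#' Generates, in this order (so that `tracks = FALSE` leaves everything else
#' on the same random stream): gene placements, true-domain assignment,
#' expression values with the planted repression association, virtual-caller
#' peak sets, and finally the ChIP/Input pileup tracks.
#'
#' Genes are placed non-overlapping with at least `2 * flank_window` spacing
#' so that every true domain lies in exactly one gene's body-or-flank and
#' the planted labels are unambiguous. A marked gene's domain is placed
#' inside its body (`within`), wholly inside its strand-relative upstream
#' window (`upstream`), or wholly inside its downstream window
#' (`downstream`). Marked genes are drawn into the low-expression tail
#' (bottom third of the log10-normal expression distribution) with odds
#' multiplied by `repression_odds`; with `repression_odds = 1` the marginal
#' expression distribution is exactly log10-normal and no association is
#' planted. ChIP depth is Poisson(`background_depth * enrichment_fold`)
#' per bin over domains and Poisson(`background_depth`) elsewhere; Input is
#' Poisson(`background_depth`) everywhere.
#'
#' @param config a [sim_config()].
#' @param tracks if `FALSE`, skip pileup generation (the expensive part);
#'   gene/domain/expression/caller output is identical either way.
#' @return list of class `chip_study` with elements `genome`, `genes`,
#'   `expression`, `truth` (list: `true_domains` peak collection,
#'   `gene_labels` data.frame), `chip`, `input` (pileup tracks or `NULL`),
#'   `callers` (named list of peak collections) and `config`.
#' @export
simulate_study <- function(config, tracks = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bin <- config$bin_size
  genome <- genome_spec(config$chrom_lengths)
  W <- config$flank_window

  ## --- gene placement -----------------------------------------------------
  lens <- snap(stats::runif(config$n_genes, config$gene_length_range[1],
                            config$gene_length_range[2]), bin)
  lens <- pmax(lens, bin)
  ## allocate genes to chromosomes proportionally to length
  n_chr <- length(config$chrom_lengths)
  alloc <- floor(config$n_genes * config$chrom_lengths / sum(config$chrom_lengths))
  rem <- config$n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  min_gap <- 2 * W
  margin <- W
  idx0 <- 0L
  rows <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    ng <- alloc[ci]
    if (ng == 0) next
    L <- config$chrom_lengths[ci]
    gl <- lens[idx0 + seq_len(ng)]
    slack <- L - 2 * margin - sum(gl) - (ng - 1) * min_gap
    if (slack < 0)
      stop("genome too small to place ", ng, " genes on ",
           names(config$chrom_lengths)[ci], " at the required spacing")
    w <- stats::runif(ng + 1)
    extra <- snap(slack * w / sum(w), bin)
    cursor <- margin + extra[1]
    starts <- numeric(ng)
    for (gi in seq_len(ng)) {
      starts[gi] <- cursor
      cursor <- cursor + gl[gi] + min_gap + extra[gi + 1]
    }
    rows[[ci]] <- data.frame(
      chrom = names(config$chrom_lengths)[ci],
      start = starts, end = starts + gl,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
    idx0 <- idx0 + ng
  }
  genes <- do.call(rbind, rows)
  genes <- cbind(gene_id = sprintf("g%05d", seq_len(nrow(genes))), genes,
                 stringsAsFactors = FALSE)

  ## --- true domains -------------------------------------------------------
  n_marked <- round(config$mark_fraction * config$n_genes)
  labels <- rep("none", nrow(genes))
  dom <- NULL
  if (n_marked > 0) {
    marked <- sort(sample.int(nrow(genes), n_marked))
    place <- sample(names(config$placement_mix), n_marked, replace = TRUE,
                    prob = config$placement_mix)
    dlen <- snap(stats::runif(n_marked, config$domain_length_range[1],
                              config$domain_length_range[2]), bin)
    dlen <- pmax(dlen, bin)
    g <- genes[marked, ]
    dstart <- numeric(n_marked)
    for (i in seq_len(n_marked)) {
      gs <- g$start[i]; ge <- g$end[i]; gl <- ge - gs
      if (place[i] == "within") {
        dl <- min(dlen[i], gl)
        dlen[i] <- dl
        dstart[i] <- gs + snap(stats::runif(1, 0, gl - dl), bin)
      } else {
        upstream_side <- (place[i] == "upstream") == (g$strand[i] == "+")
        dl <- dlen[i]
        off <- snap(stats::runif(1, 0, W - dl), bin)
        dstart[i] <- if (upstream_side) gs - W + off else ge + off
      }
    }
    labels[marked] <- place
    dom <- data.frame(chrom = g$chrom, start = dstart, end = dstart + dlen,
                      stringsAsFactors = FALSE)
  }
  true_domains <- peak_collection(
    if (is.null(dom)) data.frame(chrom = character(), start = numeric(),
                                 end = numeric()) else dom,
    program = "truth")
  gene_labels <- data.frame(gene_id = genes$gene_id, label = labels,
                            stringsAsFactors = FALSE)

  ## --- expression with planted repression ---------------------------------
  p0 <- 1 / 3 # baseline probability of the low-expression tail
  odds0 <- p0 / (1 - p0)
  odds_m <- config$repression_odds * odds0
  p_marked <- odds_m / (1 + odds_m)
  p_low <- ifelse(labels == "none", p0, p_marked)
  is_low <- stats::runif(nrow(genes)) < p_low
  u <- stats::runif(nrow(genes))
  q <- ifelse(is_low, u * p0, p0 + u * (1 - p0))
  logv <- stats::qnorm(q, config$expression_logmean, config$expression_logsd)
  expression <- stats::setNames(10^logv, genes$gene_id)

  ## --- virtual callers ----------------------------------------------------
  callers <- lapply(config$caller_profiles, function(pf)
    virtual_caller(pf, true_domains, genome))
  names(callers) <- vapply(config$caller_profiles, function(p) p$name, "")

  ## --- pileups ------------------------------------------------------------
  chip <- input <- NULL
  if (tracks) {
    chip <- simulate_pileup(genome, true_domains, bin,
                            config$background_depth,
                            config$enrichment_fold)
    input <- simulate_pileup(genome, true_domains, bin,
                             config$background_depth, 1)
  }

  structure(list(genome = genome, genes = genes, expression = expression,
                 truth = list(true_domains = true_domains,
                              gene_labels = gene_labels),
                 chip = chip, input = input, callers = callers,
                 config = config),
            class = "chip_study")
}

# One distorted caller output from the true domain set.
virtual_caller <- function(profile, true_domains, genome) {
  td <- true_domains$intervals
  nd <- nrow(td)
  out <- NULL
  if (nd > 0) {
    keep <- stats::runif(nd) < profile$sensitivity
    kept <- td[keep, , drop = FALSE]
    if (nrow(kept) > 0 && profile$jitter_sd > 0) {
      s <- kept$start + round(stats::rnorm(nrow(kept), 0, profile$jitter_sd))
      e <- kept$end + round(stats::rnorm(nrow(kept), 0, profile$jitter_sd))
      e <- pmax(e, s + 1)
      L <- genome$chrom_lengths[kept$chrom]
      e <- pmin(e, L)
      s <- pmax(0, pmin(s, e - 1))
      kept$start <- s; kept$end <- e
    }
    out <- kept
  }
  ## false peaks, uniform over the genome excluding true domains
  n_fp <- stats::rpois(1, profile$fp_per_mb * sum(genome$chrom_lengths) / 1e6)
  if (n_fp > 0) {
    fp <- place_false_peaks(n_fp, genome, td)
    out <- rbind(out, fp)
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  pc <- peak_collection(out, program = profile$name)
  merge_peaks(pc, profile$merge_gap)
}

place_false_peaks <- function(n, genome, true_dom) {
  probs <- genome$chrom_lengths / sum(genome$chrom_lengths)
  td_by_chrom <- split(true_dom, true_dom$chrom)
  res <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      ch <- sample(genome$chrom_names, 1, prob = probs)
      len <- round(stats::runif(1, 200, 1000))
      s <- floor(stats::runif(1, 0, genome$chrom_lengths[ch] - len))
      e <- s + len
      tdc <- td_by_chrom[[ch]]
      if (is.null(tdc) || !any(tdc$start < e & s < tdc$end)) break
    }
    res$chrom[i] <- ch; res$start[i] <- s; res$end[i] <- e
  }
  res
}

#' Merge peaks closer than a gap threshold
#'
#' Sorts the collection and merges any two consecutive peaks on the same
#' chromosome whose gap is strictly smaller than `merge_gap`. Overlapping
#' peaks are always merged; with `merge_gap = 0` only overlapping peaks are
#' merged (touching peaks are kept separate).
#'
#' @param x a [peak_collection()].
#' @param merge_gap bp threshold.
#' @return a [peak_collection()] with merged intervals.
#' @export
merge_peaks <- function(x, merge_gap = 0) {
  df <- x$intervals
  if (nrow(df) < 2) return(x)
  out <- df[1, , drop = FALSE]
  j <- 1L
  for (i in 2:nrow(df)) {
    if (df$chrom[i] == out$chrom[j] && df$start[i] - out$end[j] < merge_gap ||
        df$chrom[i] == out$chrom[j] && df$start[i] < out$end[j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      j <- j + 1L
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  peak_collection(out[, c("chrom", "start", "end")], program = x$program)
}

# Poisson pileup over binned genome; enriched bins are those overlapping a
# true domain (domains are snapped to the bin grid by construction).
simulate_pileup <- function(genome, domains, bin, background, fold) {
  rows <- vector("list", length(genome$chrom_names))
  for (ci in seq_along(genome$chrom_names)) {
    ch <- genome$chrom_names[ci]
    nb <- as.integer(genome$chrom_lengths[ci] / bin)
    lambda <- rep(background, nb)
    dd <- domains$intervals[domains$intervals$chrom == ch, , drop = FALSE]
    if (nrow(dd) && fold != 1) {
      for (i in seq_len(nrow(dd))) {
        b0 <- floor(dd$start[i] / bin) + 1L
        b1 <- ceiling(dd$end[i] / bin)
        lambda[b0:b1] <- background * fold
      }
    }
    depth <- stats::rpois(nb, lambda)
    r <- rle(depth)
    ends <- cumsum(r$lengths) * bin
    starts <- ends - r$lengths * bin
    rows[[ci]] <- data.frame(chrom = ch, start = starts, end = ends,
                             depth = r$values, stringsAsFactors = FALSE)
  }
  pileup_track(do.call(rbind, rows))
}

#' Generate a synthetic gene-to-term annotation map
#'
#' Assigns each gene 1 to `terms_per_gene` random background terms and, for
#' the genes in `signal_genes`, adds the planted term with probability
#' `signal_prob`; background genes receive the planted term with probability
#' `background_prob`. Uses the current RNG stream (seed upstream).
#'
#' @param gene_ids character vector of all genes (the background universe).
#' @param signal_genes genes enriched for the planted term.
#' @param n_terms number of background terms.
#' @param terms_per_gene max random terms per gene.
#' @param planted_term id of the planted term.
#' @param signal_prob,background_prob planted-term assignment probabilities.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
simulate_annotation <- function(gene_ids, signal_genes = character(),
                                n_terms = 50, terms_per_gene = 4,
                                planted_term = "T0001",
                                signal_prob = 0.5, background_prob = 0.02) {
  terms <- sprintf("B%04d", seq_len(n_terms))
  n_per <- sample.int(terms_per_gene, length(gene_ids), replace = TRUE)
  base <- data.frame(
    gene_id = rep(gene_ids, n_per),
    term_id = unlist(lapply(n_per, function(k) sample(terms, k))),
    stringsAsFactors = FALSE)
  p <- ifelse(gene_ids %in% signal_genes, signal_prob, background_prob)
  hit <- stats::runif(length(gene_ids)) < p
  planted <- data.frame(gene_id = gene_ids[hit],
                        term_id = rep(planted_term, sum(hit)),
                        stringsAsFactors = FALSE)
  ann <- rbind(base, planted)
  ann <- unique(ann[order(ann$gene_id, ann$term_id), ])
  rownames(ann) <- NULL
  ann
}

#' Write a simulated study bundle to a directory
#'
#' Emits `genome.tsv`, `genes.gff3`, `expression.tsv`, `truth.tsv`,
#' `truth_domains.bed`, `chip.bedGraph`/`input.bedGraph` (when tracks were
#' simulated), one `<caller>.bed` per virtual caller, and the configuration
#' as `config.yaml`. Re-reading with [read_study()] reproduces the bundle;
#' the same seed always produces byte-identical files.
#'
#' @param study a `chip_study` from [simulate_study()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir, force = FALSE) {
  stopifnot(inherits(study, "chip_study"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is non-empty (use force = TRUE): ",
         out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(chrom = study$genome$chrom_names,
                       length = format_bp(study$genome$chrom_lengths)),
            file.path(out_dir, "genome.tsv"))
  write_gff3_genes(study$genes, file.path(out_dir, "genes.gff3"))
  write_tsv(data.frame(gene_id = names(study$expression),
                       value = format(study$expression, digits = 15,
                                      scientific = FALSE, trim = TRUE)),
            file.path(out_dir, "expression.tsv"))
  write_tsv(study$truth$gene_labels, file.path(out_dir, "truth.tsv"))
  write_bed(study$truth$true_domains, file.path(out_dir, "truth_domains.bed"))
  if (!is.null(study$chip)) {
    write_bedgraph(study$chip, file.path(out_dir, "chip.bedGraph"))
    write_bedgraph(study$input, file.path(out_dir, "input.bedGraph"))
  }
  for (nm in names(study$callers))
    write_bed(study$callers[[nm]], file.path(out_dir, paste0(nm, ".bed")))
  cfg <- study$config
  cfg$caller_profiles <- lapply(cfg$caller_profiles, unclass)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir the bundle directory.
#' @return a list shaped like [simulate_study()]'s return value (the
#'   configuration is restored from `config.yaml`).
#' @export
read_study <- function(dir) {
  gen <- utils::read.delim(file.path(dir, "genome.tsv"),
                           colClasses = c("character", "numeric"))
  genome <- genome_spec(stats::setNames(gen$length, gen$chrom))
  genes <- read_gff3_genes(file.path(dir, "genes.gff3"))
  expression <- read_expression_table(file.path(dir, "expression.tsv"))
  gene_labels <- utils::read.delim(file.path(dir, "truth.tsv"),
                                   colClasses = "character")
  true_domains <- read_bed(file.path(dir, "truth_domains.bed"),
                           program = "truth")
  chip <- input <- NULL
  if (file.exists(file.path(dir, "chip.bedGraph"))) {
    chip <- read_bedgraph(file.path(dir, "chip.bedGraph"))
    input <- read_bedgraph(file.path(dir, "input.bedGraph"))
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  caller_names <- vapply(cfg$caller_profiles, function(p) p$name, "")
  callers <- lapply(caller_names, function(nm)
    read_bed(file.path(dir, paste0(nm, ".bed")), program = nm))
  names(callers) <- caller_names
  structure(list(genome = genome, genes = genes, expression = expression,
                 truth = list(true_domains = true_domains,
                              gene_labels = gene_labels),
                 chip = chip, input = input, callers = callers,
                 config = cfg),
            class = "chip_study")
}
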