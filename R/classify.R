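#' Classification configuration
#'
#' Windows and strandedness for peak-to-gene classification. The defaults
#' follow the common 2 kb promoter/terminator convention; an alternate
#' setting such as 1 kb upstream / 500 bp downstream is a one-argument
#' change. With `strand_aware = TRUE` (default) "upstream" means 5' of the
#' gene on its own strand; with `strand_aware = FALSE` upstream is simply
#' leftward in genome coordinates (sensitivity-analysis mode).
#'
#' @param upstream_window bp upstream of the TSS scanned for peaks.
#' @param downstream_window bp downstream of the gene end.
#' @param strand_aware whether windows follow gene strand.
#' @export
classify_config <- function(upstream_window = 2000, downstream_window = 2000,
                            strand_aware = TRUE) {
  stopifnot(upstream_window >= 0, downstream_window >= 0)
  structure(list(upstream_window = upstream_window,
                 downstream_window = downstream_window,
                 strand_aware = isTRUE(strand_aware)),
            class = "classify_config")
}

# windows in 0-based half-open coords; zero-width rows allowed (skipped by
# the overlap query since IRanges needs width >= 0 -> we filter).
gene_windows <- function(genes, cfg) {
  up <- cfg$upstream_window
  dn <- cfg$downstream_window
  plus <- if (cfg$strand_aware) genes$strand == "+" else rep(TRUE, nrow(genes))
  u_start <- ifelse(plus, genes$start - up, genes$end)
  u_end <- ifelse(plus, genes$start, genes$end + up)
  d_start <- ifelse(plus, genes$end, genes$start - dn)
  d_end <- ifelse(plus, genes$end + dn, genes$start)
  list(
    upstream = data.frame(chrom = genes$chrom,
                          start = pmax(0, u_start), end = pmax(0, u_end)),
    downstream = data.frame(chrom = genes$chrom,
                            start = pmax(0, d_start), end = pmax(0, d_end))
  )
}

# which genes' regions overlap any peak (>= 1 bp)
region_hits <- function(regions, peaks_gr) {
  ok <- regions$end > regions$start
  hits <- logical(nrow(regions))
  if (!any(ok)) return(hits)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom[ok],
    ranges = IRanges::IRanges(start = regions$start[ok] + 1L,
                              end = regions$end[ok]))
  ov <- GenomicRanges::countOverlaps(gr, peaks_gr, ignore.strand = TRUE) > 0
  hits[ok] <- ov
  hits
}

#' Classify genes by peak position
#'
#' Assigns every gene exactly one label with precedence
#' `within > upstream > downstream > none`: a gene is `within` if any peak
#' overlaps its body by at least 1 bp; otherwise `upstream` if any peak
#' overlaps the upstream window; otherwise `downstream` likewise; otherwise
#' `none`. For a `+` gene the upstream window is
#' `[start - W_up, start)` and the downstream window `[end, end + W_dn)`;
#' for a `-` gene the two are mirrored.
#'
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`) as from [read_gff3_genes()].
#' @param peaks a [peak_collection()].
#' @param cfg a [classify_config()].
#' @return data.frame with columns `gene_id`, `label`, `program`, plus an
#'   attribute `multi_label`: the number of genes that matched more than
#'   one category before precedence was applied.
#' @export
classify_genes <- function(genes, peaks, cfg = classify_config()) {
  stopifnot(is.data.frame(genes), inherits(peaks, "peak_collection"),
            inherits(cfg, "classify_config"))
  if (nrow(genes) == 0) stop("empty gene set")
  if (cfg$strand_aware &&
      (!"strand" %in% names(genes) || any(!genes$strand %in% c("+", "-"))))
    stop("strand-aware classification requires every gene to have strand +/-")
  peaks_gr <- if (n_peaks(peaks)) {
    GenomicRanges::reduce(as_granges(peaks), ignore.strand = TRUE)
  } else {
    GenomicRanges::GRanges()
  }
  body_hit <- region_hits(genes[, c("chrom", "start", "end")], peaks_gr)
  w <- gene_windows(genes, cfg)
  up_hit <- region_hits(w$upstream, peaks_gr)
  dn_hit <- region_hits(w$downstream, peaks_gr)
  label <- ifelse(body_hit, "within",
                  ifelse(up_hit, "upstream",
                         ifelse(dn_hit, "downstream", "none")))
  multi <- sum(body_hit + up_hit + dn_hit > 1)
  out <- data.frame(gene_id = genes$gene_id, label = label,
                    program = peaks$program, stringsAsFactors = FALSE)
  attr(out, "multi_label") <- multi
  out
}

#' Classify genes and report the label distribution
#'
#' @inheritParams classify_genes
#' @param universe optional character vector of gene ids to restrict the
#'   distribution to (e.g. genes present in the expression table); labels
#'   are still computed for all genes.
#' @return list with `labels` (as [classify_genes()]) and `distribution`
#'   (data.frame `label`, `count`, `percent` over the universe).
#' @export
classify_all <- function(genes, peaks, cfg = classify_config(),
                         universe = NULL) {
  labels <- classify_genes(genes, peaks, cfg)
  keep <- labels
  if (!is.null(universe)) keep <- labels[labels$gene_id %in% universe, ]
  lv <- c("within", "upstream", "downstream", "none")
  counts <- table(factor(keep$label, levels = lv))
  dist <- data.frame(label = lv, count = as.integer(counts),
                     percent = 100 * as.integer(counts) / nrow(keep),
                     stringsAsFactors = FALSE)
  list(labels = labels, distribution = dist)
}
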