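## Readers and writers for the plain-text formats the pipeline touches.
## One internal convention everywhere: 0-based half-open coordinates.
## GFF3 (1-based inclusive) is converted at the boundary and nowhere else.

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file of peaks
#'
#' Accepts 3+ column BED; columns beyond the first three are ignored except
#' column 5 which, when present and numeric, is kept as `score`. BED's
#' native 0-based half-open coordinates are preserved unchanged.
#'
#' @param path file path.
#' @param program label for the resulting collection; defaults to the file
#'   name without extension.
#' @return a [peak_collection()].
#' @export
read_bed <- function(path, program = sub("\\.bed$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(peak_collection(
      data.frame(chrom = character(), start = numeric(), end = numeric()),
      program = program))
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lnum[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lnum[bad[1]], " in ", path,
         ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at BED line ", lnum[bad[1]], " in ", path,
         ": start must satisfy 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 5)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    if (!anyNA(sc)) df$score <- sc
  }
  peak_collection(df, program = program)
}

#' Write a peak collection as 3-column BED
#'
#' @param x a [peak_collection()].
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  df <- x$intervals
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  if (nrow(df))
    writeLines(paste(df$chrom, format_bp(df$start), format_bp(df$end),
                     sep = "\t"), con, sep = "\n")
  invisible(path)
}

# bp coordinates can exceed .Machine$integer.max in principle; print without
# scientific notation.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read gene models from a GFF3 file
#'
#' Only rows with feature type `gene` are consumed; mRNA/exon/etc. rows are
#' ignored. GFF3's 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention, so a gene printed as
#' `start=1, end=10` becomes the interval `[0, 10)` of length 10. Strand is
#' mandatory: upstream/downstream windows are undefined without it.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (length(fields) && any(nf < 9))
    stop("malformed GFF3 line (fewer than 9 columns) in ", path)
  type <- vapply(fields, `[`, "", 3L)
  genes <- fields[type == "gene"]
  if (!length(genes)) {
    warning("no 'gene' feature rows found in ", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  chrom <- vapply(genes, `[`, "", 1L)
  start1 <- as.numeric(vapply(genes, `[`, "", 4L))
  end1 <- as.numeric(vapply(genes, `[`, "", 5L))
  strand <- vapply(genes, `[`, "", 7L)
  attrs <- vapply(genes, `[`, "", 9L)
  if (anyNA(start1) || anyNA(end1) || any(start1 < 1) || any(end1 < start1))
    stop("invalid gene coordinates in ", path)
  if (any(!strand %in% c("+", "-")))
    stop("gene without explicit strand (+/-) in ", path,
         ": upstream/downstream windows are undefined")
  m <- regmatches(attrs, regexpr("(^|;)ID=[^;]+", attrs))
  if (length(m) != length(attrs))
    stop("gene row without an ID attribute in ", path)
  gene_id <- sub("^;?ID=", "", m)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  df <- data.frame(gene_id = gene_id, chrom = chrom,
                   start = start1 - 1, end = end1, strand = strand,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open coordinates are
#' emitted as GFF3 1-based inclusive.
#'
#' @param genes data.frame as returned by [read_gff3_genes()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @export
write_gff3_genes <- function(genes, path, source = "peakcompare") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(genes))
    writeLines(paste(genes$chrom, source, "gene",
                     format_bp(genes$start + 1), format_bp(genes$end),
                     ".", genes$strand, ".",
                     paste0("ID=", genes$gene_id), sep = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' Pileup track (bedGraph semantics)
#'
#' A per-chromosome stepwise read-depth function: non-overlapping sorted
#' steps `(start, end, depth)` with implicit depth 0 between steps.
#' Construction canonicalizes the steps: they are sorted, overlapping steps
#' are an error, and adjacent steps with equal depth are merged. The track's
#' `total` is the summed signal `sum(depth * length)` divided by
#' `read_length` when one is supplied (i.e. an approximate read count).
#'
#' @param steps data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @param read_length optional read length in bp used to convert summed
#'   signal to a read count.
#' @return an object of class `pileup_track`.
#' @export
pileup_track <- function(steps, read_length = NULL) {
  stopifnot(is.data.frame(steps))
  need <- c("chrom", "start", "end", "depth")
  miss <- setdiff(need, names(steps))
  if (length(miss)) stop("steps missing column(s): ", paste(miss, collapse = ", "))
  steps$chrom <- as.character(steps$chrom)
  for (cc in c("start", "end", "depth")) steps[[cc]] <- as.numeric(steps[[cc]])
  if (nrow(steps)) {
    if (any(!is.finite(steps$start)) || any(!is.finite(steps$end)) ||
        any(!is.finite(steps$depth)))
      stop("non-numeric values in pileup steps")
    if (any(steps$start < 0 | steps$start >= steps$end))
      stop("invalid step (need 0 <= start < end)")
    if (any(steps$depth < 0)) stop("negative depth in pileup steps")
    o <- order(steps$chrom, steps$start)
    steps <- steps[o, , drop = FALSE]
    same <- steps$chrom[-1] == steps$chrom[-nrow(steps)]
    if (nrow(steps) > 1 && any(same & steps$start[-1] < steps$end[-nrow(steps)])) {
      i <- which(same & steps$start[-1] < steps$end[-nrow(steps)])[1]
      stop("overlapping pileup steps on ", steps$chrom[i], " at ",
           format_bp(steps$start[i + 1]), " < ", format_bp(steps$end[i]))
    }
    ## merge adjacent equal-depth steps
    if (nrow(steps) > 1) {
      joinable <- c(FALSE,
                    steps$chrom[-1] == steps$chrom[-nrow(steps)] &
                    steps$start[-1] == steps$end[-nrow(steps)] &
                    steps$depth[-1] == steps$depth[-nrow(steps)])
      if (any(joinable)) {
        firsts <- which(!joinable)
        lasts <- c(firsts[-1] - 1L, nrow(steps))
        steps <- data.frame(
          chrom = steps$chrom[firsts],
          start = steps$start[firsts],
          end = steps$end[lasts],
          depth = steps$depth[firsts],
          stringsAsFactors = FALSE)
      }
    }
    rownames(steps) <- NULL
  }
  signal <- sum(steps$depth * (steps$end - steps$start))
  total <- if (is.null(read_length)) signal else signal / read_length
  structure(list(steps = steps, total = total, signal = signal),
            class = "pileup_track")
}

#' @export
print.pileup_track <- function(x, ...) {
  cat("pileup_track:", nrow(x$steps), "step(s) on",
      length(unique(x$steps$chrom)), "chromosome(s); total =",
      format(x$total, big.mark = ","), "\n")
  invisible(x)
}

#' Read a bedGraph file into a pileup track
#'
#' @param path file path.
#' @param read_length optional read length passed to [pileup_track()].
#' @return a [pileup_track()].
#' @export
read_bedgraph <- function(path, read_length = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(pileup_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), depth = numeric()),
                        read_length = read_length))
  fields <- split_fields(lines)
  if (any(lengths(fields) < 4))
    stop("malformed bedGraph line (fewer than 4 columns) in ", path)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.numeric(vapply(fields, `[`, "", 2L)),
    end = as.numeric(vapply(fields, `[`, "", 3L)),
    depth = as.numeric(vapply(fields, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  pileup_track(df, read_length = read_length)
}

#' Write a pileup track as bedGraph
#'
#' Zero-depth steps are written explicitly so that a write/read round trip
#' reproduces the canonical track exactly.
#'
#' @param x a [pileup_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  df <- x$steps
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df))
    writeLines(paste(df$chrom, format_bp(df$start), format_bp(df$end),
                     format(df$depth, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a two-column expression table
#'
#' TSV of `gene_id <TAB> raw_value`, header row optional (detected by a
#' non-numeric second field on the first line). Values must be strictly
#' positive because downstream discretization works on log10 expression.
#'
#' @param path file path.
#' @return named numeric vector of raw expression values.
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty expression table: ", path)
  fields <- split_fields(lines)
  if (any(lengths(fields) < 2))
    stop("malformed expression table line (fewer than 2 columns) in ", path)
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) fields <- fields[-1] # header
  if (!length(fields)) stop("expression table has a header but no rows: ", path)
  ids <- vapply(fields, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1]
    stop("non-numeric expression value for gene ", ids[i], " in ", path)
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(vals <= 0)) {
    i <- which(vals <= 0)[1]
    stop("expression value <= 0 for gene ", ids[i],
         " (log10 transform undefined)")
  }
  stats::setNames(vals, ids)
}

# Internal: uniform TSV writer (LF, tabs, no quoting).
write_tsv <- function(df, path, col.names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names, eol = "\n")
  invisible(path)
}
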