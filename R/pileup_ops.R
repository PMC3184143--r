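#' Normalize ChIP and Input tracks to equal totals
#'
#' Scales the Input track's depths by `chip$total / input$total` so the two
#' tracks carry identical total signal over the genome; the ChIP track is
#' returned unchanged. This matches the display convention where track
#' heights are directly comparable between ChIP and control.
#'
#' @param chip,input [pileup_track()]s with strictly positive totals.
#' @return list with elements `chip` (unchanged) and `input` (scaled).
#' @export
normalize_tracks <- function(chip, input) {
  stopifnot(inherits(chip, "pileup_track"), inherits(input, "pileup_track"))
  if (chip$total <= 0 || input$total <= 0)
    stop("cannot normalize a track with zero total signal")
  ratio <- chip$total / input$total
  steps <- input$steps
  steps$depth <- steps$depth * ratio
  list(chip = chip, input = pileup_track(steps))
}

# Per-chromosome depth Rle with implicit zeros filled, padded to at least
# `min_len` bp per chromosome.
pileup_rle <- function(track, chroms = NULL, min_len = NULL) {
  st <- track$steps
  if (is.null(chroms)) chroms <- unique(st$chrom)
  out <- lapply(chroms, function(ch) {
    s <- st[st$chrom == ch, , drop = FALSE]
    L <- if (!is.null(min_len)) min_len[[ch]] else 0
    if (nrow(s)) L <- max(L, max(s$end))
    if (L == 0) return(S4Vectors::Rle(numeric(0)))
    if (!nrow(s)) return(S4Vectors::Rle(0, L))
    lens <- c(rbind(s$start - c(0, s$end[-nrow(s)]), s$end - s$start))
    vals <- c(rbind(0, s$depth))
    keep <- lens > 0
    r <- S4Vectors::Rle(vals[keep], lens[keep])
    if (length(r) < L) r <- c(r, S4Vectors::Rle(0, L - length(r)))
    r
  })
  names(out) <- chroms
  out
}

#' Peak height: max minus min depth within a peak
#'
#' Depth is read from the ChIP pileup over `[start, end)`. Positions not
#' covered by any step have implicit depth 0 and, by default, participate
#' in the minimum (`include_gaps = TRUE`); with `include_gaps = FALSE` the
#' minimum is taken over explicitly covered positions only (a peak with no
#' coverage at all then has height `NA`).
#'
#' @param peak one-row data.frame or list with `chrom`, `start`, `end`.
#' @param pileup a [pileup_track()].
#' @param include_gaps whether implicit zero-depth gaps count in the
#'   minimum.
#' @return numeric height (>= 0).
#' @export
peak_height <- function(peak, pileup, include_gaps = TRUE) {
  if (peak$end <= peak$start) stop("zero-length peak")
  st <- pileup$steps
  s <- st[st$chrom == peak$chrom & st$start < peak$end & st$end > peak$start,
          , drop = FALSE]
  if (!nrow(s)) {
    if (include_gaps) return(0)
    return(NA_real_)
  }
  covered <- sum(pmin(s$end, peak$end) - pmax(s$start, peak$start))
  depths <- s$depth
  mx <- max(depths)
  mn <- min(depths)
  if (include_gaps && covered < peak$end - peak$start) {
    mn <- min(mn, 0)
    mx <- max(mx, 0)
  }
  mx - mn
}

#' Mean peak height for one program
#'
#' The per-peak height (max depth minus min depth over the peak) averaged
#' over all peaks of the program.
#'
#' @param peaks a non-empty [peak_collection()].
#' @param pileup a [pileup_track()] (ChIP depths; heights use raw ChIP
#'   depth, not ChIP minus Input).
#' @param include_gaps see [peak_height()].
#' @return list of class `height_report` with `program`,
#'   `per_peak_heights`, `mean_height`.
#' @export
mean_peak_height <- function(peaks, pileup, include_gaps = TRUE) {
  if (n_peaks(peaks) == 0)
    stop("cannot compute mean height of an empty collection: ",
         peaks$program)
  df <- peaks$intervals
  if (include_gaps) {
    ## fast path: Views over zero-filled Rles
    lens <- tapply(df$end, df$chrom, max)
    rles <- pileup_rle(pileup, chroms = unique(df$chrom), min_len = lens)
    heights <- numeric(nrow(df))
    for (ch in unique(df$chrom)) {
      idx <- which(df$chrom == ch)
      v <- IRanges::Views(rles[[ch]], start = df$start[idx] + 1L,
                          end = df$end[idx])
      heights[idx] <- IRanges::viewMaxs(v) - IRanges::viewMins(v)
    }
  } else {
    heights <- vapply(seq_len(nrow(df)), function(i)
      peak_height(df[i, ], pileup, include_gaps = FALSE), 0)
  }
  structure(list(program = peaks$program, per_peak_heights = heights,
                 mean_height = mean(heights)),
            class = "height_report")
}

#' @export
print.height_report <- function(x, ...) {
  cat(sprintf("height_report '%s': %d peaks, mean height %.2f\n",
              x$program, length(x$per_peak_heights), x$mean_height))
  invisible(x)
}

#' Mean-height table across callers
#'
#' @param collections list of [peak_collection()]s.
#' @param pileup ChIP [pileup_track()].
#' @param include_gaps see [peak_height()].
#' @return data.frame with columns `program`, `mean_height` (2 decimals).
#' @export
height_table <- function(collections, pileup, include_gaps = TRUE) {
  rows <- lapply(collections, function(pc) {
    hr <- mean_peak_height(pc, pileup, include_gaps = include_gaps)
    data.frame(program = hr$program,
               mean_height = round(hr$mean_height, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
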