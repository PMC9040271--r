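# Localisation and Extraction: reduce peak tracks to per-gene, per-mark
# scalar enrichment features over symmetric TSS windows ("input-fields").
#
# The input-field of a gene spans l bp symmetrically around its TSS
# (l/2 upstream, l/2 downstream; default l = 10000), mimicking an expanded
# promoter. Localisation paints each position of the field with the
# signalValue of the peak covering it (0 where uncovered, per-position max
# where peaks overlap); Extraction collapses the field to one number, by
# default the maximum.

#' Canonical core histone marks
#'
#' The five core marks, in their conventional order: the promoter mark
#' H3K4me3, the regulative mark H3K4me1, the structural mark H3K36me3, and
#' the repressor marks H3K9me3 and H3K27me3. Feature-matrix columns default
#' to this order whenever all five are present.
#' @export
CORE_MARKS <- c("H3K4me3", "H3K4me1", "H3K36me3", "H3K9me3", "H3K27me3")

#' Build the input-field of a gene
#'
#' The field is the interval [tss - l/2, tss + l/2) on the gene's
#' chromosome. It is strand-independent (symmetric around the TSS) and its
#' position index runs in genomic coordinate order. Fields extending below
#' position 0 are clipped at 0 and flagged; the localised vector is still
#' length l, zero-padded over the clipped positions.
#'
#' @param gene one row of a gene annotation table (list or data.frame row
#'   with \code{gene_id}, \code{chrom}, \code{tss}).
#' @param l window length in bp; must be positive and even.
#' @return a list with \code{gene_id}, \code{chrom}, \code{origin} (nominal
#'   0-based start, may be negative), \code{start} (clipped), \code{end},
#'   \code{l}, \code{clipped}.
#' @export
build_input_field <- function(gene, l = 10000L) {
  if (length(l) != 1L || !is.finite(l) || l <= 0 || l %% 2 != 0) {
    stop("window length l must be a positive even number of bp")
  }
  origin <- gene$tss - l / 2
  clipped <- origin < 0
  if (clipped) {
    warning("input-field of gene ", gene$gene_id,
            " clipped at chromosome start; zero-padded to length ", l)
  }
  list(gene_id = gene$gene_id, chrom = gene$chrom,
       origin = origin, start = max(0, origin), end = origin + l,
       l = as.integer(l), clipped = clipped)
}

#' Localise peak enrichments onto an input-field
#'
#' Returns the length-l signal vector x over the field: position i
#' (0-based, genomic order) holds the signalValue of a peak covering
#' genomic position origin + i, 0.0 where no peak overlaps, and the
#' maximum signalValue where several peaks overlap. Peaks on other
#' chromosomes or outside the field contribute nothing.
#'
#' @param peaks a peaks \code{data.frame} (see [read_peaks()]).
#' @param field an input-field from [build_input_field()].
#' @return numeric vector of length \code{field$l} with attributes
#'   \code{"gene_id"} and \code{"n_peaks"} (number of distinct peaks
#'   overlapping the field, used by the \code{count} aggregator).
#' @export
localise <- function(peaks, field) {
  x <- numeric(field$l)
  ov <- which(peaks$chrom == field$chrom &
                peaks$start < field$end & peaks$end > field$start)
  for (j in ov) {
    i0 <- max(peaks$start[j], field$start) - field$origin
    i1 <- min(peaks$end[j], field$end) - field$origin
    idx <- (i0 + 1):i1   # field positions are 0-based; R vectors 1-based
    x[idx] <- pmax(x[idx], peaks$signal_value[j])
  }
  attr(x, "gene_id") <- field$gene_id
  attr(x, "n_peaks") <- length(ov)
  x
}

#' Collapse a localised signal to a scalar feature
#'
#' The default aggregator is the maximum enrichment over the field,
#' \eqn{\phi = \max_i x_i}. \code{mean}, \code{sum} and \code{count} are
#' provided as sensitivity alternatives; \code{count} is the number of
#' distinct peaks overlapping the field (taken from the signal's
#' \code{"n_peaks"} attribute).
#'
#' @param signal localised signal from [localise()].
#' @param aggregator one of \code{"max"}, \code{"mean"}, \code{"sum"},
#'   \code{"count"}.
#' @return a nonnegative scalar.
#' @export
extract_feature <- function(signal, aggregator = c("max", "mean", "sum", "count")) {
  aggregator <- match.arg(aggregator)
  switch(aggregator,
    max = if (length(signal)) max(signal) else 0,
    mean = mean(signal),
    sum = sum(signal),
    count = {
      n <- attr(signal, "n_peaks")
      if (is.null(n)) stop("'count' aggregator needs a signal from localise()")
      as.numeric(n)
    })
}

# Max enrichment / overlap count / per-position-max sum for one mark over
# all gene fields, via an interval index (never materialises n x l vectors).
# origins may be negative for clipped fields; peak coordinates are clipped
# to [max(0, origin), origin + l).
.featurise_track <- function(peaks, chrom, origin, l, aggregator) {
  n <- length(origin)
  out <- numeric(n)
  if (nrow(peaks) == 0L) return(out)
  fstart <- pmax(0, origin)
  fend <- origin + l
  # GRanges are 1-based closed: [start+1, end]
  fields_gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = fstart + 1, end = fend))
  peaks_gr <- GenomicRanges::GRanges(peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hits <- GenomicRanges::findOverlaps(fields_gr, peaks_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q) == 0L) return(out)
  if (aggregator == "max") {
    agg <- tapply(peaks$signal_value[s], q, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  } else if (aggregator == "count") {
    agg <- table(q)
    out[as.integer(names(agg))] <- as.numeric(agg)
  } else {  # sum / mean of the per-position max signal
    for (g in unique(q)) {
      j <- s[q == g]
      out[g] <- .segment_max_sum(pmax(peaks$start[j], fstart[g]),
                                 pmin(peaks$end[j], fend[g]),
                                 peaks$signal_value[j])
    }
    if (aggregator == "mean") out <- out / l
  }
  out
}

# Integral of the per-position max of piecewise-constant peak signals:
# sweep over breakpoints, max of signals covering each segment.
.segment_max_sum <- function(starts, ends, sig) {
  bp <- sort(unique(c(starts, ends)))
  total <- 0
  for (k in seq_len(length(bp) - 1L)) {
    cover <- starts <= bp[k] & ends >= bp[k + 1L]
    if (any(cover)) total <- total + (bp[k + 1L] - bp[k]) * max(sig[cover])
  }
  total
}

#' Build the feature matrix Phi
#'
#' Featurises every gene against every mark: entry (g, h) is the
#' aggregated enrichment of mark h's peaks over gene g's input-field.
#' Computed with a genomic interval index, so memory is proportional to
#' the peaks and the output, not to n x l. An entry is 0 exactly when no
#' peak of that mark overlaps the gene's field (under max/sum/count).
#'
#' @param genes gene annotation \code{data.frame} (see [read_genes()]).
#' @param peak_tracks named list, one entry per mark, each either a peaks
#'   \code{data.frame} or a list \code{list(dialect =, peaks =)}.
#' @param l input-field length in bp (positive, even).
#' @param aggregator see [extract_feature()].
#' @param mark_order column order; defaults to [CORE_MARKS] order for the
#'   core marks (any others appended as given).
#' @return numeric matrix (genes x marks) with gene ids as rownames, mark
#'   names as colnames and attributes \code{"dialects"}, \code{"l"},
#'   \code{"aggregator"}.
#' @export
build_feature_matrix <- function(genes, peak_tracks, l = 10000L,
                                 aggregator = c("max", "mean", "sum", "count"),
                                 mark_order = NULL) {
  aggregator <- match.arg(aggregator)
  if (length(peak_tracks) == 0L) stop("no peak tracks given")
  if (is.null(names(peak_tracks)) || any(!nzchar(names(peak_tracks)))) {
    stop("'peak_tracks' must be a named list (one entry per mark)")
  }
  if (nrow(genes) == 0L) stop("no genes given")
  if (l <= 0 || l %% 2 != 0) stop("window length l must be positive and even")

  marks <- names(peak_tracks)
  if (is.null(mark_order)) {
    mark_order <- c(intersect(CORE_MARKS, marks), setdiff(marks, CORE_MARKS))
  }
  stopifnot(setequal(mark_order, marks))

  origin <- genes$tss - l / 2
  if (any(origin < 0)) {
    warning(sum(origin < 0), " input-field(s) clipped at chromosome start")
  }
  phi <- matrix(0, nrow = nrow(genes), ncol = length(marks),
                dimnames = list(genes$gene_id, mark_order))
  dialects <- character(0)
  for (h in mark_order) {
    track <- peak_tracks[[h]]
    if (is.data.frame(track)) {
      peaks <- track
      dialects[h] <- attr(track, "dialect") %||% NA_character_
    } else {
      peaks <- track$peaks
      dialects[h] <- track$dialect %||% attr(peaks, "dialect") %||% NA_character_
    }
    phi[, h] <- .featurise_track(peaks, genes$chrom, origin, l, aggregator)
  }
  attr(phi, "dialects") <- dialects
  attr(phi, "l") <- as.integer(l)
  attr(phi, "aggregator") <- aggregator
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
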