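# Readers and writers for the external formats the pipeline consumes:
# ENCODE peak BED dialects, gene/TSS annotation tables, expression tables,
# ChromHMM emission matrices, and the package's own feature-matrix TSV.
#
# Coordinates are 0-based half-open [start, end) throughout, the standard
# ENCODE BED convention; no downstream step introduces +/-1 shifts.

.dialect_ncol <- c(narrow = 10L, broad = 9L, gapped = 15L)
.dialect_signal_col <- c(narrow = 7L, broad = 7L, gapped = 13L)

#' Read an ENCODE peak BED track
#'
#' Parses peak calls in one of the three ENCODE BED dialects: narrowPeak
#' (BED6+4, 10 columns), broadPeak (BED6+3, 9 columns) or gappedPeak
#' (BED12+3, 15 columns). The per-peak enrichment is taken from the
#' dialect's signalValue column (column 7 for narrow/broad, column 13 for
#' gapped) and is the quantity localised and aggregated downstream.
#' Header lines starting with \code{track}, \code{browser} or \code{#} are
#' skipped. Coordinates are kept 0-based half-open.
#'
#' @param path path to a tab-separated peak file.
#' @param dialect one of \code{"narrow"}, \code{"broad"}, \code{"gapped"}.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand},
#'   \code{signal_value}, \code{p_value}, \code{q_value} plus
#'   dialect-specific extras (\code{peak} point-source offset for narrow;
#'   thick/block columns for gapped), and attribute \code{"dialect"}.
#'   Missing p/q values are encoded as -1 per ENCODE convention.
#' @export
read_peaks <- function(path, dialect = c("narrow", "broad", "gapped")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  hdr <- grepl("^(track|browser|#)", lines)
  if (any(hdr)) message("skipping ", sum(hdr), " header line(s) in ", path)
  keep <- !hdr & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) return(.empty_peaks(dialect))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- .dialect_ncol[[dialect]]
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop("malformed ", dialect, "Peak line ", lineno[bad], " in ", path,
         ": expected ", want, " columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = want, byrow = TRUE)

  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("malformed ", dialect, "Peak line ", lineno[bad[1L]], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("malformed ", dialect, "Peak line ", lineno[bad[1L]], " in ", path,
         ": requires 0 <= start < end")
  }
  sig <- suppressWarnings(as.numeric(m[, .dialect_signal_col[[dialect]]]))
  bad <- which(!is.finite(sig) | sig < 0)
  if (length(bad)) {
    stop("malformed ", dialect, "Peak line ", lineno[bad[1L]], " in ", path,
         ": signalValue must be a nonnegative number")
  }

  pk <- data.frame(
    chrom = m[, 1L], start = start, end = end, name = m[, 4L],
    score = suppressWarnings(as.integer(m[, 5L])), strand = m[, 6L],
    signal_value = sig, stringsAsFactors = FALSE
  )
  if (dialect == "narrow") {
    pk$p_value <- as.numeric(m[, 8L]); pk$q_value <- as.numeric(m[, 9L])
    pk$peak <- as.integer(m[, 10L])
  } else if (dialect == "broad") {
    pk$p_value <- as.numeric(m[, 8L]); pk$q_value <- as.numeric(m[, 9L])
  } else {
    pk$thick_start <- as.numeric(m[, 7L]); pk$thick_end <- as.numeric(m[, 8L])
    pk$item_rgb <- m[, 9L]; pk$block_count <- as.integer(m[, 10L])
    pk$block_sizes <- m[, 11L]; pk$block_starts <- m[, 12L]
    pk$p_value <- as.numeric(m[, 14L]); pk$q_value <- as.numeric(m[, 15L])
  }
  attr(pk, "dialect") <- dialect
  pk
}

.empty_peaks <- function(dialect) {
  pk <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   name = character(), score = integer(), strand = character(),
                   signal_value = numeric(), p_value = numeric(),
                   q_value = numeric(), stringsAsFactors = FALSE)
  attr(pk, "dialect") <- dialect
  pk
}

#' Write peaks in an ENCODE BED dialect
#'
#' Inverse of [read_peaks()]. Dialect-specific columns absent from the
#' input are filled with conventional defaults (point source -1; a single
#' block spanning the whole peak for gappedPeak).
#'
#' @param peaks a peaks \code{data.frame} as returned by [read_peaks()].
#' @param path output path.
#' @param dialect target dialect; defaults to the \code{"dialect"} attribute.
#' @return \code{path}, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = attr(peaks, "dialect")) {
  if (is.null(dialect)) stop("no dialect given and none recorded on 'peaks'")
  dialect <- match.arg(dialect, c("narrow", "broad", "gapped"))
  n <- nrow(peaks)
  num <- function(x) format(x, digits = 15L, scientific = FALSE, trim = TRUE)
  get0n <- function(col, default) {
    if (!is.null(peaks[[col]])) peaks[[col]] else rep(default, n)
  }
  pv <- num(get0n("p_value", -1)); qv <- num(get0n("q_value", -1))
  base6 <- cbind(peaks$chrom, num(peaks$start), num(peaks$end),
                 get0n("name", "."), get0n("score", 0L), get0n("strand", "."))
  out <- switch(dialect,
    narrow = cbind(base6, num(peaks$signal_value), pv, qv,
                   get0n("peak", -1L)),
    broad = cbind(base6, num(peaks$signal_value), pv, qv),
    gapped = cbind(base6,
                   num(get0n("thick_start", peaks$start)),
                   num(get0n("thick_end", peaks$end)),
                   get0n("item_rgb", "0"),
                   get0n("block_count", 1L),
                   get0n("block_sizes", num(peaks$end - peaks$start)),
                   get0n("block_starts", "0"),
                   num(peaks$signal_value), pv, qv))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene/TSS annotation table
#'
#' Reads a tab- or comma-separated table (separator sniffed from the header
#' line) with one row per gene. The TSS must already be strand-resolved:
#' for minus-strand genes the annotation supplies the transcription start,
#' not the interval minimum.
#'
#' @param path path to the table.
#' @param columns named character vector mapping the required fields
#'   \code{gene_id}, \code{chrom}, \code{tss}, \code{strand} to the file's
#'   column names.
#' @return a \code{data.frame} with columns \code{gene_id}, \code{chrom},
#'   \code{tss} (0-based bp), \code{strand}, in file order.
#' @export
read_genes <- function(path,
                       columns = c(gene_id = "gene_id", chrom = "chrom",
                                   tss = "tss", strand = "strand")) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(columns))) {
    stop("'columns' must name all of: ", paste(need, collapse = ", "))
  }
  tab <- .read_table_sniff(path)
  miss <- setdiff(unname(columns[need]), names(tab))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "))
  genes <- data.frame(gene_id = as.character(tab[[columns[["gene_id"]]]]),
                      chrom = as.character(tab[[columns[["chrom"]]]]),
                      tss = as.numeric(tab[[columns[["tss"]]]]),
                      strand = as.character(tab[[columns[["strand"]]]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         genes$gene_id[anyDuplicated(genes$gene_id)])
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (any(!is.finite(genes$tss) | genes$tss < 0)) {
    stop("gene tss must be a nonnegative coordinate")
  }
  genes
}

.read_table_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a gene expression table
#'
#' Two-column table (gene_id, rpkm) with header. RPKM values must be
#' nonnegative.
#'
#' @param path path to the table.
#' @return a named numeric vector of RPKM values, names are gene ids.
#' @export
read_expression <- function(path) {
  tab <- .read_table_sniff(path)
  if (ncol(tab) < 2L) stop("expression table needs two columns (gene_id, rpkm)")
  ids <- as.character(tab[[1L]])
  rpkm <- as.numeric(tab[[2L]])
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression table")
  if (any(!is.finite(rpkm) | rpkm < 0)) {
    stop("RPKM values must be nonnegative finite numbers")
  }
  stats::setNames(rpkm, ids)
}

#' Write an expression table
#' @param expr named numeric vector of RPKM values.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path) {
  write.table(data.frame(gene_id = names(expr), rpkm = unname(expr)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ChromHMM emission matrix
#'
#' Expects a states-by-marks table: the first column holds state labels,
#' the remaining (named) columns hold emission probabilities in [0, 1],
#' one per histone mark. Optionally attaches a state-to-group mapping read
#' from a two-column (state, group) table.
#'
#' @param path path to the emissions table (TSV/CSV with header).
#' @param groups_path optional path to a two-column state-to-group table.
#' @return an \code{emission_matrix} object; see [emission_matrix()].
#' @export
read_emissions <- function(path, groups_path = NULL) {
  tab <- .read_table_sniff(path)
  if (ncol(tab) < 2L) stop("emissions table needs a state column plus mark columns")
  E <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(E) <- "double"
  rownames(E) <- as.character(tab[[1L]])
  groups <- NULL
  if (!is.null(groups_path)) {
    gt <- .read_table_sniff(groups_path)
    groups <- stats::setNames(as.character(gt[[2L]]), as.character(gt[[1L]]))
  }
  emission_matrix(E, groups = groups)
}

#' Construct an emission matrix object
#'
#' @param E numeric matrix, states in rows (rownames = state labels),
#'   marks in columns (colnames = mark names), entries in [0, 1].
#' @param groups optional named character vector mapping every state label
#'   to a group label.
#' @return an object of class \code{emission_matrix}: a list with
#'   \code{states}, \code{marks}, \code{E} and \code{groups}.
#' @export
emission_matrix <- function(E, groups = NULL) {
  if (is.null(rownames(E)) || is.null(colnames(E))) {
    stop("emission matrix needs state rownames and mark colnames")
  }
  if (any(!is.finite(E)) || any(E < 0) || any(E > 1)) {
    stop("emission probabilities must lie in [0, 1]")
  }
  if (anyDuplicated(rownames(E))) stop("duplicate state labels")
  if (!is.null(groups)) {
    unknown <- setdiff(names(groups), rownames(E))
    if (length(unknown)) {
      stop("group table references unknown state(s): ",
           paste(unknown, collapse = ", "))
    }
    missing_states <- setdiff(rownames(E), names(groups))
    if (length(missing_states)) {
      stop("states missing from group mapping: ",
           paste(missing_states, collapse = ", "))
    }
  }
  structure(list(states = rownames(E), marks = colnames(E),
                 E = E, groups = groups),
            class = "emission_matrix")
}

#' @export
print.emission_matrix <- function(x, ...) {
  cat("emission_matrix:", length(x$states), "states x",
      length(x$marks), "marks\n")
  cat("marks:", paste(x$marks, collapse = ", "), "\n")
  if (!is.null(x$groups)) {
    cat("groups:", paste(unique(x$groups), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read the feature matrix TSV
#'
#' The feature matrix is emitted as a TSV with a \code{gene_id} column and
#' one column per mark. If the matrix carries dialect provenance and
#' featurisation parameters, a JSON sidecar (\code{<path>.json}) records
#' them.
#'
#' @param phi numeric feature matrix (genes x marks, dimnames set).
#' @param path output path.
#' @param sidecar write the JSON provenance sidecar (default TRUE when
#'   provenance attributes are present).
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(phi, path, sidecar = TRUE) {
  df <- data.frame(gene_id = rownames(phi), phi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dialects = as.list(attr(phi, "dialects")),
               l = attr(phi, "l"), aggregator = attr(phi, "aggregator"))
  if (sidecar && !is.null(attr(phi, "dialects"))) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- .read_table_sniff(path)
  phi <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(phi) <- "double"
  rownames(phi) <- as.character(tab[[1L]])
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(phi, "dialects") <- unlist(meta$dialects)
    attr(phi, "l") <- meta$l
    attr(phi, "aggregator") <- meta$aggregator
  }
  phi
}
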