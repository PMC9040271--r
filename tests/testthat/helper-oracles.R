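# Independent brute-force oracles, kept deliberately naive: the
# implementations under test must agree with these on small instances.

# Per-position membership scan: for every field position, the max
# signalValue over all peaks covering it (0 if none).
oracle_localise <- function(peaks, field) {
  pos <- field$origin + seq_len(field$l) - 1L   # 0-based genomic positions
  vapply(pos, function(p) {
    if (p < 0) return(0)
    cover <- peaks$chrom == field$chrom & peaks$start <= p & peaks$end > p
    if (any(cover)) max(peaks$signal_value[cover]) else 0
  }, 0)
}

# Naive per-gene double loop over the full localised vectors.
oracle_feature_matrix <- function(genes, tracks, l, aggregator = "max") {
  phi <- matrix(0, nrow(genes), length(tracks),
                dimnames = list(genes$gene_id, names(tracks)))
  for (g in seq_len(nrow(genes))) {
    field <- list(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
                  origin = genes$tss[g] - l / 2, l = l)
    field$start <- max(0, field$origin); field$end <- field$origin + l
    for (h in names(tracks)) {
      pk <- tracks[[h]]
      x <- oracle_localise(pk, field)
      phi[g, h] <- switch(aggregator,
        max = max(x), sum = sum(x), mean = mean(x),
        count = sum(pk$chrom == field$chrom & pk$start < field$end &
                      pk$end > field$start))
    }
  }
  phi
}

# AUROC as the fraction of concordant (ON, OFF) pairs, ties counting 1/2.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Drop featurisation provenance attributes, keeping only the bare matrix.
strip_phi <- function(phi) {
  attributes(phi) <- attributes(phi)[c("dim", "dimnames")]
  phi
}

# Permute a vector under a temporary seed without disturbing global RNG.
permute_with_seed <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  out <- x[sample.int(length(x))]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

# A random small peak/gene fixture on a short genome (for featurisation
# oracle-equivalence checks). Peaks may fall anywhere, including across
# field boundaries and on a decoy chromosome.
random_mini_fixture <- function(n_genes, n_peaks, l, genome = 50000L) {
  genes <- data.frame(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    tss = sample.int(genome, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  start <- sample.int(genome, n_peaks)
  width <- sample(10:2000, n_peaks, replace = TRUE)
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = start, end = start + width,
    name = paste0("pk", seq_len(n_peaks)), score = 0L, strand = ".",
    signal_value = round(stats::rlnorm(n_peaks, log(5), 0.6), 3),
    p_value = -1, q_value = -1, stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks, l = l)
}
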