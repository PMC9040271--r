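# Self-contained synthetic fixtures with planted ground truth: peak
# tracks in all three BED dialects, gene/TSS annotations, bimodal
# expression coupled to a planted logistic gene-state model, and
# well-separated emission matrices. Every other module is testable against
# these without external downloads.

#' Specify a synthetic fixture
#'
#' Describes a cohort of genes with non-overlapping TSS windows, per-mark
#' log-normal peak enrichments (sparse: a mark may call no peak on a
#' gene), a planted logistic ground truth P(ON) = sigmoid(b* + w*.phi*),
#' and a bimodal expression model (near-zero OFF component, high ON
#' component) coupled to the planted class so that thresholding recovers
#' it with high probability.
#'
#' @param n_genes number of genes.
#' @param marks mark names; defaults to the five core marks.
#' @param w_star planted weights, one per mark (activators positive,
#'   repressors negative).
#' @param b_star planted bias; default centers the planted logit at
#'   roughly zero so classes are near-balanced.
#' @param l input-field length (bp).
#' @param gap minimum spacing between consecutive windows (bp).
#' @param chrom_length genome length; default sized to fit all windows.
#' @param sparsity per-mark probability that a gene has no peak.
#' @param enrich_meanlog,enrich_sdlog log-normal enrichment parameters.
#' @param peak_meanlog,peak_sdlog log-normal peak-width parameters (bp).
#' @param decoy_rate Poisson rate of extra lower-enrichment peaks inside a
#'   window.
#' @param bg_rate Poisson rate of background peaks between windows.
#' @param noise_sd sd of Gaussian noise added to the planted logit.
#' @param flip_prob probability of flipping a gene's expression class.
#' @param deterministic if TRUE the class is 1(logit > 0) instead of a
#'   Bernoulli draw from sigmoid(logit).
#' @param expr_off_meanlog,expr_on_meanlog,expr_sdlog log-normal RPKM
#'   parameters of the OFF and ON components.
#' @param informative_dialect optional named vector mark -> dialect; the
#'   other dialects of that mark get their signalValues permuted across
#'   peaks, decoupling them from the planted enrichment (for
#'   peak-format-selection tests). Default: all dialects share the same
#'   peaks.
#' @param seed integer seed; fixed seed gives identical fixtures.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_genes = 500L,
                         marks = CORE_MARKS,
                         w_star = c(0.8, 0.45, 0.6, -0.5, -0.9),
                         b_star = NULL,
                         l = 10000L, gap = 4000L, chrom_length = NULL,
                         sparsity = 0.3,
                         enrich_meanlog = log(3), enrich_sdlog = 0.5,
                         peak_meanlog = log(600), peak_sdlog = 0.4,
                         decoy_rate = 0.7, bg_rate = 0.3,
                         noise_sd = 0, flip_prob = 0,
                         deterministic = FALSE,
                         expr_off_meanlog = log(0.05),
                         expr_on_meanlog = log(50),
                         expr_sdlog = 0.8,
                         informative_dialect = NULL,
                         seed = 1L) {
  if (length(w_star) != length(marks)) {
    stop("w_star must have one weight per mark")
  }
  if (l <= 0 || l %% 2 != 0) stop("l must be positive and even")
  if (gap <= 0) stop("gap must be positive")
  if (is.null(b_star)) {
    # center E[logit] at 0: E[phi] = (1 - sparsity) * E[lognormal]
    b_star <- -sum(w_star) * (1 - sparsity) *
      exp(enrich_meanlog + enrich_sdlog^2 / 2)
  }
  spec <- list(n_genes = as.integer(n_genes), marks = marks,
               w_star = stats::setNames(w_star, marks), b_star = b_star,
               l = as.integer(l), gap = as.integer(gap),
               chrom_length = chrom_length, sparsity = sparsity,
               enrich_meanlog = enrich_meanlog, enrich_sdlog = enrich_sdlog,
               peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
               decoy_rate = decoy_rate, bg_rate = bg_rate,
               noise_sd = noise_sd, flip_prob = flip_prob,
               deterministic = deterministic,
               expr_off_meanlog = expr_off_meanlog,
               expr_on_meanlog = expr_on_meanlog, expr_sdlog = expr_sdlog,
               informative_dialect = informative_dialect,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a synthetic fixture
#'
#' Materialises the cohort described by a [fixture_spec()]: gene windows
#' are placed without overlap along a synthetic chromosome; each gene's
#' planted per-mark enrichment is realised as a main peak carrying exactly
#' that signalValue (plus optional lower decoy peaks inside the window and
#' background peaks between windows); the latent ON/OFF class follows the
#' planted logistic model on the planted enrichments; expression is drawn
#' from the class-conditional bimodal mixture. Peaks are emitted in all
#' three BED dialects (same underlying calls, dialect-appropriate
#' columns). Deterministic given the spec's seed.
#'
#' @param spec a \code{fixture_spec}.
#' @return a list of class \code{hm_fixture}: \code{genes} (annotation
#'   data.frame), \code{expression} (named RPKM vector), \code{tracks}
#'   (mark -> dialect -> peaks data.frame), and \code{truth} (planted
#'   \code{w_star}, \code{b_star}, \code{phi_star} matrix, \code{eta}
#'   logits, \code{class}, and the separating expression threshold
#'   \code{class_threshold}).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, .generate_fixture_impl(spec))
}

.generate_fixture_impl <- function(spec) {
  n <- spec$n_genes; m <- length(spec$marks); l <- spec$l; gap <- spec$gap
  pitch <- l + gap
  needed <- n * pitch + l
  chrom_length <- spec$chrom_length %||% needed
  if (chrom_length < needed) {
    stop("cannot place ", n, " non-overlapping ", l, " bp windows in a ",
         chrom_length, " bp chromosome; increase chrom_length to >= ", needed)
  }
  # windows at a fixed pitch with jitter < gap/2, so they never overlap
  tss <- l / 2 + (seq_len(n) - 1L) * pitch +
    floor(stats::runif(n, 0, gap / 2))
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                      chrom = "chr1", tss = tss,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  win_start <- tss - l / 2
  win_end <- tss + l / 2

  # planted per-gene per-mark enrichments (0 = no peak called)
  phi_star <- matrix(0, n, m, dimnames = list(genes$gene_id, spec$marks))
  has_peak <- matrix(stats::runif(n * m) >= spec$sparsity, n, m)
  phi_star[has_peak] <- round(stats::rlnorm(sum(has_peak),
                                            spec$enrich_meanlog,
                                            spec$enrich_sdlog), 4)
  # guard against a rounded draw of exactly 0
  phi_star[has_peak & phi_star == 0] <- 1e-4

  eta <- spec$b_star + drop(phi_star %*% spec$w_star)
  if (spec$noise_sd > 0) eta <- eta + stats::rnorm(n, 0, spec$noise_sd)
  cls <- if (spec$deterministic) as.integer(eta > 0)
         else stats::rbinom(n, 1L, stats::plogis(eta))
  expr_cls <- cls
  if (spec$flip_prob > 0) {
    flip <- stats::runif(n) < spec$flip_prob
    expr_cls[flip] <- 1L - expr_cls[flip]
  }
  rpkm <- numeric(n)
  rpkm[expr_cls == 0L] <- stats::rlnorm(sum(expr_cls == 0L),
                                        spec$expr_off_meanlog, spec$expr_sdlog)
  rpkm[expr_cls == 1L] <- stats::rlnorm(sum(expr_cls == 1L),
                                        spec$expr_on_meanlog, spec$expr_sdlog)
  expression <- stats::setNames(round(rpkm, 4), genes$gene_id)

  rwidth <- function(k) pmin(l - 2L, pmax(50L, round(stats::rlnorm(
    k, spec$peak_meanlog, spec$peak_sdlog))))

  tracks <- vector("list", m)
  names(tracks) <- spec$marks
  for (j in seq_len(m)) {
    ps <- pe <- numeric(0); sig <- numeric(0)
    # main peak realises the planted enrichment exactly (max over window)
    idx <- which(has_peak[, j])
    if (length(idx)) {
      w0 <- rwidth(length(idx))
      off <- floor(stats::runif(length(idx)) * (l - w0))
      ps <- win_start[idx] + off
      pe <- ps + w0
      sig <- phi_star[idx, j]
      # decoy peaks: strictly lower signal, inside the window
      nd <- stats::rpois(length(idx), spec$decoy_rate)
      di <- rep(seq_along(idx), nd)
      if (length(di)) {
        wd <- rwidth(length(di))
        offd <- floor(stats::runif(length(di)) * (l - wd))
        ps <- c(ps, win_start[idx][di] + offd)
        pe <- c(pe, win_start[idx][di] + offd + wd)
        sig <- c(sig, round(phi_star[idx, j][di] *
                              stats::runif(length(di), 0.3, 0.95), 4))
      }
    }
    # background peaks between windows (never overlapping any window)
    slack <- gap / 2 - 400  # jitter < gap/2 leaves at least this much room
    nb <- if (slack >= 300) stats::rpois(n, spec$bg_rate) else integer(n)
    bi <- rep(seq_len(n), nb)
    if (length(bi)) {
      wb <- pmax(100L, pmin(round(slack), rwidth(length(bi))))
      bs <- win_end[bi] + 200 + floor(stats::runif(length(bi), 0,
                                                   pmax(1, slack - wb)))
      keep <- bs + wb <= chrom_length
      ps <- c(ps, bs[keep]); pe <- c(pe, (bs + wb)[keep])
      sig <- c(sig, round(stats::rlnorm(sum(keep), spec$enrich_meanlog,
                                        spec$enrich_sdlog), 4))
    }
    o <- order(ps)
    peaks <- data.frame(chrom = "chr1", start = ps[o], end = pe[o],
                        name = sprintf("%s_pk%05d", spec$marks[j],
                                       seq_along(ps)),
                        score = pmin(1000L, as.integer(round(sig[o] * 100))),
                        strand = ".", signal_value = sig[o],
                        p_value = -1, q_value = -1,
                        stringsAsFactors = FALSE)
    tracks[[j]] <- .emit_dialects(peaks, spec$marks[j],
                                  spec$informative_dialect)
  }

  structure(list(genes = genes, expression = expression, tracks = tracks,
                 truth = list(w_star = spec$w_star, b_star = spec$b_star,
                              phi_star = phi_star, eta = eta, class = cls,
                              class_threshold = 1.0),
                 spec = spec),
            class = "hm_fixture")
}

# One peaks table -> the three dialect variants. If an informative dialect
# is declared for the mark, the other dialects get permuted signalValues.
.emit_dialects <- function(peaks, mark, informative_dialect) {
  out <- list()
  info <- informative_dialect[[mark]] %||% NA_character_
  for (d in c("narrow", "broad", "gapped")) {
    pk <- peaks
    if (!is.na(info) && d != info && nrow(pk) > 1L) {
      pk$signal_value <- sample(pk$signal_value)
      pk$score <- pmin(1000L, as.integer(round(pk$signal_value * 100)))
    }
    if (d == "narrow") {
      pk$peak <- as.integer(floor((pk$end - pk$start) / 2))
    } else if (d == "gapped") {
      pk$thick_start <- pk$start; pk$thick_end <- pk$end
      pk$item_rgb <- "0"; pk$block_count <- 1L
      pk$block_sizes <- as.character(pk$end - pk$start)
      pk$block_starts <- "0"
    }
    attr(pk, "dialect") <- d
    out[[d]] <- pk
  }
  out
}

#' Write a fixture to disk
#'
#' Emits one peak file per mark and dialect (\code{<mark>.narrowPeak},
#' \code{<mark>.broadPeak}, \code{<mark>.gappedPeak}), \code{genes.tsv},
#' \code{expr.tsv} and \code{truth.json}.
#'
#' @param fixture an \code{hm_fixture}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "hm_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(narrow = "narrowPeak", broad = "broadPeak", gapped = "gappedPeak")
  for (h in names(fixture$tracks)) {
    for (d in names(fixture$tracks[[h]])) {
      write_peaks(fixture$tracks[[h]][[d]],
                  file.path(dir, paste0(h, ".", ext[[d]])), dialect = d)
    }
  }
  write.table(fixture$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression(fixture$expression, file.path(dir, "expr.tsv"))
  tr <- fixture$truth
  jsonlite::write_json(list(w_star = as.list(tr$w_star), b_star = tr$b_star,
                            class_threshold = tr$class_threshold,
                            class = tr$class, seed = fixture$spec$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a well-separated emission matrix
#'
#' Draws S emission rows over m marks with U-shaped (near 0/1) entries and
#' accepts each row only if its mean-centered cosine similarity with every
#' previously accepted row stays at or below \code{max_sim}, so states are
#' pairwise distinguishable after centering. For S = 15 the rows carry the
#' REMC 15-state mnemonics (so [default_state_groups()] applies).
#'
#' @param S number of states (>= 2).
#' @param m number of marks (>= 2); up to five draw the core mark names.
#' @param seed integer seed.
#' @param max_sim maximum allowed pairwise centered cosine similarity.
#' @param max_tries per-row rejection budget before giving up.
#' @return an \code{emission_matrix}.
#' @export
generate_emission_fixture <- function(S, m, seed = 1L, max_sim = 0.8,
                                      max_tries = 5000L) {
  if (S < 2L || m < 2L) stop("need S >= 2 states and m >= 2 marks")
  marks <- if (m <= length(CORE_MARKS)) CORE_MARKS[seq_len(m)]
           else paste0("mark", seq_len(m))
  states <- if (S == 15L) names(default_state_groups())
            else paste0("S", seq_len(S))
  E <- .with_seed(seed, {
    E <- matrix(NA_real_, S, m)
    for (s in seq_len(S)) {
      ok <- FALSE
      for (tr in seq_len(max_tries)) {
        row <- stats::rbeta(m, 0.4, 0.4)
        rc <- row - mean(row)
        if (sqrt(sum(rc^2)) < 1e-3) next
        sims <- if (s == 1L) 0 else apply(E[seq_len(s - 1L), , drop = FALSE],
                                          1L, function(e) {
          ec <- e - mean(e)
          sum(rc * ec) / (sqrt(sum(rc^2)) * sqrt(sum(ec^2)))
        })
        if (all(sims <= max_sim)) { E[s, ] <- row; ok <- TRUE; break }
      }
      if (!ok) stop("could not draw ", S, " emission rows with pairwise ",
                    "centered cosine <= ", max_sim, " in ", max_tries,
                    " tries; relax max_sim or reduce S")
    }
    E
  })
  dimnames(E) <- list(states, marks)
  emission_matrix(round(E, 6))
}

#' Simulate patterns that are noisy copies of emission rows
#'
#' Assigns each gene a state uniformly at random and builds its pattern as
#' a positively scaled copy of that state's emission row plus Gaussian
#' noise - the planted assignment that [match_states()] should recover.
#'
#' @param emissions an \code{emission_matrix}.
#' @param n_genes number of genes.
#' @param noise_sd sd of additive Gaussian noise on the pattern.
#' @param scale_range range of the positive per-gene scale factor.
#' @param seed integer seed.
#' @return a list: \code{patterns} (a \code{pattern_set} with zero bias)
#'   and \code{true_state} (character vector of planted state labels).
#' @export
simulate_state_patterns <- function(emissions, n_genes, noise_sd = 0.05,
                                    scale_range = c(0.5, 2), seed = 1L) {
  stopifnot(inherits(emissions, "emission_matrix"))
  S <- length(emissions$states); m <- length(emissions$marks)
  res <- .with_seed(seed, {
    st <- sample.int(S, n_genes, replace = TRUE)
    a <- stats::runif(n_genes, scale_range[1L], scale_range[2L])
    psi <- emissions$E[st, , drop = FALSE] * a +
      matrix(stats::rnorm(n_genes * m, 0, noise_sd), n_genes, m)
    list(st = st, psi = psi)
  })
  gene_ids <- sprintf("sim%05d", seq_len(n_genes))
  psi <- res$psi
  dimnames(psi) <- list(gene_ids, emissions$marks)
  patterns <- structure(list(gene_ids = gene_ids, marks = emissions$marks,
                             psi = psi, bias = 0, logit = rowSums(psi),
                             significant = stats::setNames(
                               rep(NA, m), emissions$marks),
                             alpha = NA_real_),
                        class = "pattern_set")
  list(patterns = patterns, true_state = emissions$states[res$st])
}
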