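# Matching gene-wise regulative patterns against ChromHMM-style emission
# vectors, and ranking chromatin states (or coarser state groups) by the
# mean predicted activation logit of their matched genes:
#   (1) State matching - each gene joins the state whose emission vector
#       maximises the Pearson correlation with its pattern (equivalently,
#       the cosine similarity of the two mean-centered vectors);
#   (2) Activation prediction - the gene's output logit y = b + sum(psi);
#   (3) Gathering - mean logit of the genes matched to each state;
#   (4) Ranking - states (or groups) ordered by decreasing mean logit.

#' Pearson correlation between a pattern and an emission vector
#'
#' Equal to the cosine similarity of the two mean-centered vectors. When
#' either vector is constant (zero centered norm) the correlation is
#' undefined and reported as 0 with a warning.
#'
#' @param psi numeric pattern vector, length m.
#' @param emission_row numeric emission vector, length m, same mark order.
#' @return correlation in [-1, 1].
#' @export
pattern_state_correlation <- function(psi, emission_row) {
  if (length(psi) != length(emission_row)) {
    stop("pattern and emission vector differ in length")
  }
  a <- psi - mean(psi)
  b <- emission_row - mean(emission_row)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("constant vector: correlation undefined, reported as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Match regulative patterns to chromatin states
#'
#' Associates each gene with the state whose emission vector maximises the
#' mean-centered cosine similarity with the gene's pattern. Emission
#' columns are realigned to the pattern mark order by name. Ties go to the
#' lowest state index. Genes with an identically-zero pattern (no peaks)
#' have correlation 0 to every state; they are assigned the tie-break
#' state but flagged \code{unmatched} and excluded from gathering by
#' default.
#'
#' @param patterns a \code{pattern_set} from [compute_patterns()].
#' @param emissions an \code{emission_matrix}.
#' @return data.frame with \code{gene_id}, \code{state},
#'   \code{correlation}, \code{unmatched}.
#' @export
match_states <- function(patterns, emissions) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(emissions, "emission_matrix"))
  if (!setequal(patterns$marks, emissions$marks)) {
    stop("pattern marks and emission marks do not agree: ",
         paste(setdiff(patterns$marks, emissions$marks), collapse = ", "))
  }
  E <- emissions$E[, patterns$marks, drop = FALSE]
  psi <- patterns$psi
  psi_c <- psi - rowMeans(psi)
  E_c <- E - rowMeans(E)
  psi_n <- sqrt(rowSums(psi_c^2))
  E_n <- sqrt(rowSums(E_c^2))
  if (any(E_n == 0)) stop("emission matrix contains a constant state row")
  unmatched <- psi_n == 0
  C <- (psi_c %*% t(E_c)) / (pmax(psi_n, .Machine$double.eps) %o% E_n)
  C[unmatched, ] <- 0
  best <- max.col(C, ties.method = "first")
  data.frame(gene_id = patterns$gene_ids %||% seq_len(nrow(psi)),
             state = emissions$states[best],
             correlation = C[cbind(seq_len(nrow(C)), best)],
             unmatched = unmatched,
             stringsAsFactors = FALSE)
}

#' Gather matched genes and rank states or groups by mean logit
#'
#' At state level, the mean output logit of the genes matched to each
#' state is computed and states are ranked by decreasing mean (rank 1 =
#' highest). With a state-to-group mapping, genes are pooled by their
#' matched state's group and ranks are computed directly at the group
#' level (never averaged from state ranks). Labels with no matched genes
#' are reported with a missing mean and excluded from the ranking.
#'
#' @param matches output of [match_states()].
#' @param patterns the matching \code{pattern_set} (source of the logits).
#' @param grouping optional named character vector state -> group; when
#'   given, ranking is at group level.
#' @param include_unmatched include genes flagged unmatched (default
#'   FALSE).
#' @param labels optional full label set (e.g. all emission states), so
#'   that states never matched are still reported (with missing mean).
#' @return a \code{rank_table}: data.frame with \code{label},
#'   \code{mean_logit}, \code{n_genes}, \code{rank} (NA for empty
#'   labels), with attribute \code{"level"} = \code{"state"} or
#'   \code{"group"}.
#' @export
gather_and_rank <- function(matches, patterns, grouping = NULL,
                            include_unmatched = FALSE, labels = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  keep <- if (include_unmatched) rep(TRUE, nrow(matches)) else !matches$unmatched
  if (sum(!keep) > 0) {
    message(sum(!keep), " zero-pattern gene(s) excluded from gathering")
  }
  logits <- patterns$logit[keep]
  state <- matches$state[keep]
  if (is.null(grouping)) {
    level <- "state"
    labels_all <- labels %||% unique(matches$state)
    key <- state
  } else {
    level <- "group"
    miss <- setdiff(unique(matches$state), names(grouping))
    if (length(miss)) {
      stop("matched state(s) missing from grouping: ",
           paste(miss, collapse = ", "))
    }
    labels_all <- labels %||% unique(unname(grouping))
    key <- unname(grouping[state])
  }
  mean_logit <- vapply(labels_all,
                       function(lb) if (any(key == lb)) mean(logits[key == lb])
                                    else NA_real_, 0)
  n_genes <- vapply(labels_all, function(lb) sum(key == lb), 0L)
  empty <- is.na(mean_logit)
  if (any(empty)) {
    message(sum(empty), " ", level, "(s) with no matched genes excluded ",
            "from ranking: ", paste(labels_all[empty], collapse = ", "))
  }
  rk <- rep(NA_integer_, length(labels_all))
  rk[!empty] <- rank(-mean_logit[!empty], ties.method = "first")
  out <- data.frame(label = labels_all, mean_logit = mean_logit,
                    n_genes = n_genes, rank = rk,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(is.na(out$rank), out$rank), ]
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Histogram of group ranks across epigenomes
#'
#' Summarises, for each state group, how often it attains each rank
#' across a cohort of per-epigenome rank tables.
#'
#' @param rank_tables a list of \code{rank_table}s sharing one label set.
#' @return an integer matrix: rows = labels, columns = rank values,
#'   entry = number of epigenomes where that label scored that rank.
#' @export
rank_histogram <- function(rank_tables) {
  if (length(rank_tables) == 0L) stop("no rank tables given")
  labels <- sort(rank_tables[[1L]]$label)
  for (rt in rank_tables) {
    if (!identical(sort(rt$label), labels)) {
      stop("rank tables have inconsistent label sets")
    }
  }
  ranks <- seq_len(length(labels))
  H <- matrix(0L, nrow = length(labels), ncol = length(ranks),
              dimnames = list(labels, paste0("rank", ranks)))
  for (rt in rank_tables) {
    ok <- !is.na(rt$rank)
    for (i in which(ok)) H[rt$label[i], rt$rank[i]] <- H[rt$label[i], rt$rank[i]] + 1L
  }
  H
}

#' Default 4-group mapping for the 15 REMC chromatin-state mnemonics
#'
#' A reconstruction of the conventional grouping of the 15-state core-mark
#' ChromHMM model into four semantically consistent groups: Active
#' transcription (TssA, TssAFlnk, TxFlnk, Tx, TxWk), Enhancers (EnhG,
#' Enh), Bivalent/poised (TssBiv, BivFlnk, EnhBiv) and Repressed/quiescent
#' (ZNF/Rpts, Het, ReprPC, ReprPCWk, Quies). User-overridable: pass any
#' named state -> group vector wherever a grouping is accepted. Also
#' shipped as \code{inst/extdata/remc15_state_groups_reconstructed.tsv}.
#'
#' @return named character vector state mnemonic -> group label.
#' @export
default_state_groups <- function() {
  c(TssA = "Active", TssAFlnk = "Active", TxFlnk = "Active",
    Tx = "Active", TxWk = "Active",
    EnhG = "Enhancer", Enh = "Enhancer",
    TssBiv = "Bivalent", BivFlnk = "Bivalent", EnhBiv = "Bivalent",
    `ZNF/Rpts` = "Repressed", Het = "Repressed", ReprPC = "Repressed",
    ReprPCWk = "Repressed", Quies = "Repressed")
}
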