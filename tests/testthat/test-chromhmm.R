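# Matching regulative patterns to chromatin-state emission vectors and
# ranking states/groups by mean activation logit.

make_pattern_set <- function(psi, logit = rowSums(psi), bias = 0) {
  structure(list(gene_ids = rownames(psi) %||% paste0("g", seq_len(nrow(psi))),
                 marks = colnames(psi), psi = psi, bias = bias,
                 logit = logit,
                 significant = stats::setNames(rep(NA, ncol(psi)),
                                               colnames(psi)),
                 alpha = NA_real_),
            class = "pattern_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pattern-state correlation is the mean-centered cosine", {
  e <- c(0.1, 0.1, 0.5, 0.9, 0.9)
  expect_equal(pattern_state_correlation(e, e), 1.0)
  expect_equal(pattern_state_correlation(-e, e), -1.0)
  psi <- c(1, 2, 3, 4, 5)
  expect_equal(pattern_state_correlation(psi, e),
               sum((psi - mean(psi)) * (e - mean(e))) /
                 sqrt(sum((psi - mean(psi))^2) * sum((e - mean(e))^2)))
  expect_equal(pattern_state_correlation(psi, e), cor(psi, e))
  expect_warning(r <- pattern_state_correlation(rep(2, 5), e), "constant")
  expect_equal(r, 0)
  expect_error(pattern_state_correlation(1:3, 1:4), "length")
})

test_that("correlation is invariant to positive affine transforms", {
  set.seed(61)
  for (i in 1:20) {
    psi <- rnorm(5); e <- runif(5)
    a <- runif(1, 0.1, 10); c0 <- rnorm(1)
    expect_equal(pattern_state_correlation(a * psi + c0, e),
                 pattern_state_correlation(psi, e), tolerance = 1e-12)
  }
})

test_that("match_states recovers collinear states and realigns marks", {
  E <- rbind(S1 = c(0.9, 0.1, 0.1, 0.9, 0.5),
             S2 = c(0.1, 0.9, 0.9, 0.1, 0.5))
  colnames(E) <- CORE_MARKS
  em <- emission_matrix(E)
  psi <- rbind(gA = 2 * E["S1", ], gB = 3 * E["S2", ] + 1)
  pats <- make_pattern_set(psi)
  mm <- match_states(pats, em)
  expect_equal(mm$state, c("S1", "S2"))
  expect_equal(mm$correlation, c(1, 1), tolerance = 1e-12)

  # permuting the emission mark columns changes nothing after realignment
  perm <- c(3, 1, 5, 2, 4)
  em2 <- emission_matrix(E[, perm])
  expect_equal(match_states(pats, em2), mm)

  bad <- emission_matrix(matrix(runif(10), 2, 5,
                                dimnames = list(c("S1", "S2"),
                                                paste0("other", 1:5))))
  expect_error(match_states(pats, bad), "marks")
})

test_that("matching equals the exhaustive argmax oracle", {
  set.seed(62)
  em <- generate_emission_fixture(8, 5, seed = 63)
  psi <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(paste0("g", 1:20), em$marks))
  mm <- match_states(make_pattern_set(psi), em)
  for (g in 1:20) {
    cors <- apply(em$E, 1, function(e) pattern_state_correlation(psi[g, ], e))
    expect_equal(mm$state[g], em$states[which.max(cors)])
    expect_equal(mm$correlation[g], max(cors))
  }
})

test_that("zero patterns are flagged unmatched and excluded by default", {
  em <- generate_emission_fixture(4, 5, seed = 64)
  psi <- rbind(gA = em$E[2, ] * 1.5, gB = rep(0, 5))
  colnames(psi) <- em$marks
  pats <- make_pattern_set(psi, logit = c(2, -1))
  mm <- match_states(pats, em)
  expect_false(mm$unmatched[1])
  expect_true(mm$unmatched[2])
  expect_equal(mm$correlation[2], 0)
  expect_equal(mm$state[2], em$states[1])  # tie-break: lowest state index
  expect_message(rt <- gather_and_rank(mm, pats), "excluded")
  expect_equal(sum(rt$n_genes), 1L)
})

test_that("display normalisation does not change the matched state", {
  set.seed(65)
  em <- generate_emission_fixture(6, 5, seed = 66)
  sim <- simulate_state_patterns(em, 30, noise_sd = 0.1, seed = 67)
  mm0 <- match_states(sim$patterns, em)
  scaled <- sim$patterns
  scaled$psi <- scaled$psi * 0.25   # positive rescale, as in display
  mm1 <- match_states(scaled, em)
  expect_equal(mm0$state, mm1$state)
})

test_that("planted state assignments are recovered at low noise", {
  em <- generate_emission_fixture(15, 5, seed = 68, max_sim = 0.8)
  sim <- simulate_state_patterns(em, 400, noise_sd = 0.03, seed = 69)
  mm <- match_states(sim$patterns, em)
  expect_gte(mean(mm$state == sim$true_state), 0.95)
})

test_that("gathering pools logits and ranks by decreasing mean", {
  em <- generate_emission_fixture(4, 5, seed = 70)
  st <- rep(em$states, times = c(3, 2, 4, 1))
  psi <- em$E[st, ] * 1.2
  rownames(psi) <- paste0("g", seq_along(st))
  logits <- c(3, 3, 3, -2, -2, 1, 1, 1, 1, 0)  # per matched state
  pats <- make_pattern_set(psi, logit = logits)
  mm <- match_states(pats, em)
  expect_equal(mm$state, st)

  rt <- gather_and_rank(mm, pats)
  expect_equal(attr(rt, "level"), "state")
  expect_equal(rt$label[rt$rank == 1], em$states[1])
  expect_equal(sort(rt$rank), 1:4)
  expect_true(all(diff(rt$mean_logit[order(rt$rank)]) <= 0))

  # two groups: mean of pooled logits, not mean of state means
  grouping <- stats::setNames(c("hot", "hot", "cold", "cold"), em$states)
  rg <- gather_and_rank(mm, pats, grouping = grouping)
  expect_equal(attr(rg, "level"), "group")
  hot <- rg[rg$label == "hot", ]
  expect_equal(hot$mean_logit, mean(c(3, 3, 3, -2, -2)))
  expect_equal(hot$n_genes, 5L)
  # weighted-mean identity with the state-level table
  w_mean <- sum(rt$mean_logit[match(c(em$states[1], em$states[2]), rt$label)] *
                  c(3, 2)) / 5
  expect_equal(hot$mean_logit, w_mean)
  expect_equal(rg$rank[order(-rg$mean_logit)], 1:2)

  expect_error(gather_and_rank(mm, pats, grouping = grouping[-1]),
               "missing from grouping")
})

test_that("rank histograms count ranks per group across epigenomes", {
  rt <- structure(data.frame(label = c("A", "B"), mean_logit = c(2, -1),
                             n_genes = c(3L, 3L), rank = c(1L, 2L)),
                  class = c("rank_table", "data.frame"), level = "group")
  H <- rank_histogram(list(rt, rt, rt))
  expect_equal(H["A", "rank1"], 3L)
  expect_equal(H["B", "rank2"], 3L)
  expect_equal(sum(H), 6L)
  expect_error(rank_histogram(list()), "no rank tables")
  other <- rt; other$label <- c("A", "C")
  expect_error(rank_histogram(list(rt, other)), "inconsistent")
})

test_that("a group planted to dominate always lands at rank 1", {
  set.seed(71)
  em <- generate_emission_fixture(8, 5, seed = 72)
  grouping <- stats::setNames(rep(c("Active", "Rest"), each = 4), em$states)
  tables <- lapply(1:5, function(e) {
    sim <- simulate_state_patterns(em, 200, noise_sd = 0.02, seed = 100 + e)
    pats <- sim$patterns
    # planted logit ordering: Active-matched genes get the higher logits
    pats$logit <- ifelse(grouping[sim$true_state] == "Active",
                         rnorm(200, 5), rnorm(200, -5))
    gather_and_rank(match_states(pats, em), pats, grouping = grouping)
  })
  H <- rank_histogram(tables)
  expect_equal(H["Active", "rank1"], 5L)
  expect_equal(sum(H["Active", -1]), 0L)
})
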