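# Supervised dataset assembly and model fitting: binarise expression at a
# threshold, split genes into train/validation/test thirds, fit logistic
# regression on raw max-enrichment features, select per-mark peak-format
# hyperparameters on validation AUROC, and evaluate over repeated splits.

#' Median expression threshold
#'
#' The class threshold is the median RPKM observed in the cell line or
#' tissue, making the ON/OFF split problem-instance specific and (for
#' tie-free expression) balanced.
#'
#' @param expr named numeric vector of RPKM values.
#' @return the median, a nonnegative scalar.
#' @export
median_threshold <- function(expr) {
  if (length(expr) == 0L) stop("empty expression table")
  t_bar <- stats::median(expr)
  if (length(unique(expr)) == 1L) {
    warning("all expression values are equal; every gene will be OFF ",
            "(t_g <= t_bar) - degenerate labeling")
  }
  t_bar
}

#' Valley expression threshold
#'
#' Alternative to the median rule: places the threshold at the local
#' minimum ("valley") of a kernel-density estimate of log(1 + RPKM)
#' between its two largest modes, separating the near-zero and the
#' actively-expressed components of the typically bimodal RPKM
#' distribution. Falls back to the median with a warning when the KDE has
#' no interior local minimum between two modes.
#'
#' @param expr named numeric vector of RPKM values.
#' @param bw KDE bandwidth selector, passed to [stats::density()].
#' @return the threshold on the RPKM scale.
#' @export
valley_threshold <- function(expr, bw = "nrd0") {
  if (length(expr) == 0L) stop("empty expression table")
  z <- log1p(expr)
  if (length(unique(z)) < 3L || stats::sd(z) == 0) {
    warning("expression not bimodal; falling back to median threshold")
    return(median_threshold(expr))
  }
  d <- stats::density(z, bw = bw)
  y <- d$y
  ds <- diff(sign(diff(y)))
  maxima <- which(ds == -2) + 1L
  minima <- which(ds == 2) + 1L
  if (length(maxima) < 2L) {
    warning("expression not bimodal; falling back to median threshold")
    return(median_threshold(expr))
  }
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  between <- minima[minima > top2[1L] & minima < top2[2L]]
  if (length(between) == 0L) {
    warning("no valley between the two largest modes; falling back to median")
    return(median_threshold(expr))
  }
  valley <- between[which.min(y[between])]
  expm1(d$x[valley])
}

#' Binarise expression into ON/OFF labels
#'
#' A gene with abundance \eqn{t_g \le \bar t} is OFF (class 0), otherwise
#' ON (class 1); ties at the threshold go OFF.
#'
#' @param expr named numeric vector of RPKM values.
#' @param t_bar nonnegative class threshold.
#' @param rule character tag recording how the threshold was chosen
#'   (\code{"median"}, \code{"valley"} or \code{"fixed"}).
#' @return named integer 0/1 vector with attributes \code{"t_bar"} and
#'   \code{"rule"}.
#' @export
binarise <- function(expr, t_bar, rule = "fixed") {
  if (!is.finite(t_bar) || t_bar < 0) stop("t_bar must be a nonnegative number")
  labels <- stats::setNames(as.integer(expr > t_bar), names(expr))
  attr(labels, "t_bar") <- t_bar
  attr(labels, "rule") <- rule
  labels
}

#' Split genes into train/validation/test thirds
#'
#' A uniform random permutation under the seed, cut into ceil-balanced
#' thirds: train takes ceil(n/3) genes, validation ceil of half the rest,
#' test the remainder. For n = 19802 this yields 6601/6601/6600.
#'
#' @param n number of genes (>= 3).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return a list of class \code{dataset_split} with disjoint index
#'   vectors \code{train}, \code{val}, \code{test} covering 1..n, and
#'   \code{seed}.
#' @export
split_dataset <- function(n, seed) {
  if (n < 3L) stop("need at least 3 genes to form three sets")
  perm <- .with_seed(seed, sample.int(n))
  n_train <- ceiling(n / 3)
  n_val <- ceiling((n - n_train) / 2)
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[(n_train + n_val + 1):n],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

# Evaluate an expression under a temporary RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit the logistic gene-state classifier
#'
#' Unpenalised maximum-likelihood logistic regression of the ON/OFF labels
#' on the raw (unstandardised) enrichment features, with intercept.
#' Standard errors come from the inverse observed information; Wald
#' z = w/se and two-sided p-values are reported per mark. Raw features are
#' kept deliberately: the gene-wise regulative patterns
#' \eqn{\psi = \phi \odot w} are interpreted against raw enrichments, and
#' standardisation would change their meaning.
#'
#' On (quasi-)perfect separation the MLE diverges; the fit then falls back
#' to a weakly ridge-penalised IRLS solution, keeps the weights finite,
#' and flags the model (\code{separation = TRUE}) so that Wald inference
#' is refused downstream.
#'
#' @param phi numeric feature matrix (genes x marks), colnames = marks.
#' @param labels 0/1 integer labels aligned with \code{phi} rows.
#' @param ridge_lambda L2 penalty used only by the separation fallback.
#' @return an object of class \code{hm_logit}: list with \code{marks},
#'   \code{w}, \code{b}, \code{se}, \code{z}, \code{p}, \code{converged},
#'   \code{separation}, \code{H} (per-mark dialect provenance, if any).
#' @export
fit_logistic <- function(phi, labels, ridge_lambda = 1e-2) {
  phi <- as.matrix(phi)
  labels <- as.integer(labels)
  if (nrow(phi) != length(labels)) stop("phi rows and labels differ in length")
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("training labels contain a single class")
  if (any(tab < 2L)) stop("need at least 2 samples per class")
  marks <- colnames(phi) %||% paste0("V", seq_len(ncol(phi)))

  df <- data.frame(.y = labels, phi, check.names = FALSE)
  fml <- stats::as.formula(paste0(".y ~ `", paste(marks, collapse = "` + `"), "`"))
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  w <- unname(co[-1L, 1L]); b <- unname(co[1L, 1L])
  se <- unname(co[-1L, 2L]); se_b <- unname(co[1L, 2L])

  separation <- !fit$converged || fit$deviance < 1e-6 ||
    any(!is.finite(se)) || any(abs(w) > 1e3)
  if (separation) {
    rf <- .ridge_logistic(phi, labels, lambda = ridge_lambda)
    w <- rf$w; b <- rf$b
    se <- rep(NA_real_, length(w)); se_b <- NA_real_
  }
  z <- w / se
  structure(list(marks = marks,
                 w = stats::setNames(w, marks), b = b,
                 se = stats::setNames(se, marks), se_b = se_b,
                 z = stats::setNames(z, marks),
                 p = stats::setNames(2 * stats::pnorm(-abs(z)), marks),
                 converged = if (separation) TRUE else fit$converged,
                 separation = separation,
                 H = attr(phi, "dialects")),
            class = "hm_logit")
}

# Ridge-penalised logistic IRLS (penalty on weights, not the intercept).
.ridge_logistic <- function(X, y, lambda, maxit = 50L, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    XtW <- t(X1 * wts)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  list(b = beta[1L], w = beta[-1L])
}

#' @export
print.hm_logit <- function(x, ...) {
  cat("logistic gene-state model over", length(x$marks), "marks\n")
  cat(sprintf("  bias b = %.4f\n", x$b))
  tab <- data.frame(w = x$w, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  if (x$separation) {
    cat("  NOTE: separation detected; ridge fallback used, inference unreliable\n")
  }
  invisible(x)
}

#' Predict ON probabilities or logits
#'
#' @param object an \code{hm_logit} model.
#' @param phi feature matrix with the model's mark columns.
#' @param type \code{"response"} (probability) or \code{"link"} (logit).
#' @param ... unused.
#' @return numeric vector, one value per row of \code{phi}.
#' @export
predict.hm_logit <- function(object, phi, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L,
                                       dimnames = list(NULL, names(phi)))
  phi <- as.matrix(phi)
  if (!is.null(colnames(phi))) {
    if (!setequal(colnames(phi), object$marks)) {
      stop("feature columns do not match model marks")
    }
    phi <- phi[, object$marks, drop = FALSE]
  } else if (ncol(phi) != length(object$marks)) {
    stop("feature matrix has ", ncol(phi), " columns; model expects ",
         length(object$marks))
  }
  eta <- drop(phi %*% object$w) + object$b
  if (type == "link") eta else stats::plogis(eta)
}

#' Evaluate a fitted model on a test set
#'
#' @param model an \code{hm_logit} model.
#' @param phi_test test feature matrix.
#' @param labels_test 0/1 test labels.
#' @return list with \code{auroc}, \code{f1}, \code{aupr} (F1 computed at
#'   probability cutoff 0.5 with ON as the positive class).
#' @export
evaluate_model <- function(model, phi_test, labels_test) {
  prob <- predict(model, phi_test, type = "response")
  list(auroc = auroc(prob, labels_test),
       f1 = f1_score(prob, labels_test, cutoff = 0.5),
       aupr = aupr(prob, labels_test))
}

# Order a mark's candidate dialects by the fixed tie-break preference:
# narrow > broad > gapped, then lexicographic for anything else.
.dialect_preference <- function(dialects) {
  pref <- c(narrow = 1L, broad = 2L, gapped = 3L)
  key <- pref[dialects]
  key[is.na(key)] <- 4L
  dialects[order(key, dialects)]
}

#' Select per-mark peak-format hyperparameters
#'
#' The hyperparameter space is the Cartesian product of candidate peak
#' dialects per mark; the configuration maximising validation AUROC (model
#' fitted on the training set only) is returned. Exhaustive search by
#' default, with a greedy per-mark coordinate search for large products.
#' Ties are broken by the fixed dialect preference narrow > broad >
#' gapped, then lexicographically.
#'
#' @param feature_sets named list: per mark, a named list of per-dialect
#'   feature columns (numeric vectors over all n genes, identically
#'   ordered).
#' @param labels 0/1 labels for all n genes.
#' @param split a \code{dataset_split}; selection uses \code{train} to fit
#'   and \code{val} to score.
#' @param method \code{"exhaustive"} or \code{"greedy"}.
#' @param max_exhaustive with \code{method = "exhaustive"}, fall back to
#'   greedy (with a message) when the product exceeds this many
#'   configurations.
#' @return list with \code{H} (named character, mark -> chosen dialect),
#'   \code{val_auroc}, and \code{n_evaluated}.
#' @export
select_hyperparameters <- function(feature_sets, labels, split,
                                   method = c("exhaustive", "greedy"),
                                   max_exhaustive = 1024L) {
  method <- match.arg(method)
  marks <- names(feature_sets)
  if (is.null(marks) || any(!nzchar(marks))) {
    stop("'feature_sets' must be a named list (one entry per mark)")
  }
  cand <- lapply(feature_sets, function(fs) {
    if (length(fs) == 0L) stop("a mark has no candidate dialect")
    .dialect_preference(names(fs))
  })
  n_configs <- prod(lengths(cand))
  if (method == "exhaustive" && n_configs > max_exhaustive) {
    message("hyperparameter product has ", n_configs,
            " configurations; switching to greedy search")
    method <- "greedy"
  }

  assemble <- function(H) {
    phi <- vapply(marks, function(h) feature_sets[[h]][[H[[h]]]],
                  numeric(length(labels)))
    colnames(phi) <- marks
    phi
  }
  score <- function(H) {
    phi <- assemble(H)
    fit <- fit_logistic(phi[split$train, , drop = FALSE], labels[split$train])
    auroc(predict(fit, phi[split$val, , drop = FALSE]), labels[split$val])
  }

  n_eval <- 0L
  if (method == "exhaustive") {
    # expand.grid with the first factor varying fastest; candidate lists are
    # preference-ordered, so the first argmax realises the tie-break.
    grid <- expand.grid(cand, stringsAsFactors = FALSE)
    best <- NULL; best_auc <- -Inf
    for (i in seq_len(nrow(grid))) {
      H <- stats::setNames(as.character(grid[i, ]), marks)
      a <- score(H)
      n_eval <- n_eval + 1L
      if (a > best_auc) { best_auc <- a; best <- H }
    }
  } else {
    best <- stats::setNames(vapply(cand, `[[`, "", 1L), marks)
    best_auc <- score(best)
    n_eval <- 1L
    repeat {
      improved <- FALSE
      for (h in marks) {
        for (d in cand[[h]]) {
          if (d == best[[h]]) next
          H <- best; H[[h]] <- d
          a <- score(H)
          n_eval <- n_eval + 1L
          if (a > best_auc) { best_auc <- a; best <- H; improved <- TRUE }
        }
      }
      if (!improved) break
    }
  }
  list(H = best, val_auroc = best_auc, n_evaluated = n_eval)
}

#' Run the repeated-split tuning and evaluation experiment
#'
#' For each of k independent random splits: choose the per-mark dialect
#' configuration on validation AUROC, fit on the training set only, and
#' evaluate AUROC/F1/AUPR on the test set. The master seed expands
#' deterministically into k split seeds.
#'
#' @inheritParams select_hyperparameters
#' @param k number of repeated splits (default 10).
#' @param seed master seed.
#' @return an \code{eval_report}: list with \code{per_split} (data.frame
#'   of split seed, chosen dialects, auroc, f1, aupr), \code{mean} and
#'   \code{sd} (named vectors over the three metrics), \code{k},
#'   \code{seed}.
#' @export
run_experiment <- function(feature_sets, labels, k = 10L, seed = 1L,
                           method = c("exhaustive", "greedy"),
                           max_exhaustive = 1024L) {
  method <- match.arg(method)
  n <- length(labels)
  split_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
  marks <- names(feature_sets)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- split_dataset(n, split_seeds[i])
    sel <- select_hyperparameters(feature_sets, labels, sp,
                                  method = method,
                                  max_exhaustive = max_exhaustive)
    phi <- vapply(marks, function(h) feature_sets[[h]][[sel$H[[h]]]],
                  numeric(n))
    colnames(phi) <- marks
    fit <- fit_logistic(phi[sp$train, , drop = FALSE], labels[sp$train])
    ev <- evaluate_model(fit, phi[sp$test, , drop = FALSE], labels[sp$test])
    rows[[i]] <- data.frame(split = i, seed = split_seeds[i],
                            t(sel$H), val_auroc = sel$val_auroc,
                            auroc = ev$auroc, f1 = ev$f1, aupr = ev$aupr,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  per_split <- do.call(rbind, rows)
  metrics <- c("auroc", "f1", "aupr")
  means <- vapply(metrics, function(mm) mean(per_split[[mm]]), 0)
  sds <- if (k > 1L) vapply(metrics, function(mm) stats::sd(per_split[[mm]]), 0)
         else stats::setNames(rep(NA_real_, 3L), metrics)
  structure(list(per_split = per_split, mean = means, sd = sds,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("repeated-split evaluation:", x$k, "splits (master seed", x$seed, ")\n")
  for (mm in names(x$mean)) {
    cat(sprintf("  %-5s mean %.4f  sd %s\n", toupper(mm), x$mean[[mm]],
                ifelse(is.na(x$sd[[mm]]), "NA", sprintf("%.4f", x$sd[[mm]]))))
  }
  invisible(x)
}
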