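# Model interpretation via gene-wise regulative patterns: the weighted
# input vector psi = phi (.) w decomposes a gene's prediction logit
# y = b + sum(psi) into per-mark contributions, with Wald significance
# masking and a max-abs display normalisation.

#' Per-mark Wald significance tests
#'
#' For each mark, z = w/se with p = 2(1 - Phi(|z|)) under the standard
#' normal; a mark is significant when p <= alpha. Refused for
#' separation-flagged models, whose standard errors are unreliable.
#'
#' @param model an \code{hm_logit} model with valid standard errors.
#' @param alpha significance level (default 1e-4).
#' @return data.frame with columns \code{mark}, \code{w}, \code{se},
#'   \code{z}, \code{p}, \code{significant}.
#' @export
significance_test <- function(model, alpha = 1e-4) {
  if (isTRUE(model$separation)) {
    stop("model was fitted under separation; Wald inference is unreliable ",
         "and refused")
  }
  if (any(!is.finite(model$se)) || any(model$se <= 0)) {
    stop("model has degenerate standard errors")
  }
  z <- model$w / model$se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(mark = model$marks, w = unname(model$w), se = unname(model$se),
             z = unname(z), p = unname(p), significant = unname(p <= alpha),
             stringsAsFactors = FALSE)
}

#' Compute a gene's regulative pattern
#'
#' The weighted input vector \eqn{\psi = \phi \odot w} (element-wise
#' product of the gene's features with the model weights), the bias, and
#' the output logit \eqn{y = b + \sum_i \psi_i}. The per-mark significance
#' mask comes from the model's Wald p-values at level \code{alpha}; for a
#' zero feature vector the pattern is all-zero and the logit reduces to
#' the bias, the model's prior on gene state.
#'
#' @param phi_g numeric feature vector of length m (named by mark, or in
#'   model mark order).
#' @param model an \code{hm_logit} model.
#' @param alpha significance level for the mask (default 1e-4).
#' @param gene_id optional gene identifier carried on the pattern.
#' @return an object of class \code{regulative_pattern}: list with
#'   \code{gene_id}, \code{marks}, \code{psi}, \code{bias}, \code{logit},
#'   \code{significant} (logical per mark; NA if the model is
#'   separation-flagged), \code{alpha}, \code{normalised}.
#' @export
compute_pattern <- function(phi_g, model, alpha = 1e-4, gene_id = NULL) {
  if (length(phi_g) != length(model$marks)) {
    stop("feature vector length ", length(phi_g),
         " does not match the model's ", length(model$marks), " marks")
  }
  if (!is.null(names(phi_g))) {
    if (!setequal(names(phi_g), model$marks)) {
      stop("feature names do not match model marks")
    }
    phi_g <- phi_g[model$marks]
  }
  psi <- unname(phi_g) * unname(model$w)
  sig <- if (isTRUE(model$separation)) rep(NA, length(psi))
         else unname(model$p <= alpha)
  structure(list(gene_id = gene_id, marks = model$marks,
                 psi = stats::setNames(psi, model$marks),
                 bias = model$b, logit = model$b + sum(psi),
                 significant = stats::setNames(sig, model$marks),
                 alpha = alpha, normalised = FALSE),
            class = "regulative_pattern")
}

#' Compute regulative patterns for many genes at once
#'
#' @param phi feature matrix (genes x marks).
#' @param model an \code{hm_logit} model.
#' @param alpha significance level for the shared mask.
#' @return an object of class \code{pattern_set}: list with
#'   \code{gene_ids}, \code{marks}, \code{psi} (genes x marks matrix),
#'   \code{bias}, \code{logit} (vector), \code{significant}, \code{alpha}.
#' @export
compute_patterns <- function(phi, model, alpha = 1e-4) {
  phi <- as.matrix(phi)
  if (!is.null(colnames(phi))) {
    if (!setequal(colnames(phi), model$marks)) {
      stop("feature columns do not match model marks")
    }
    phi <- phi[, model$marks, drop = FALSE]
  } else if (ncol(phi) != length(model$marks)) {
    stop("feature matrix width does not match the model")
  }
  psi <- sweep(phi, 2L, model$w, `*`)
  colnames(psi) <- model$marks
  sig <- if (isTRUE(model$separation)) rep(NA, length(model$marks))
         else unname(model$p <= alpha)
  structure(list(gene_ids = rownames(phi), marks = model$marks, psi = psi,
                 bias = model$b, logit = model$b + rowSums(psi),
                 significant = stats::setNames(sig, model$marks),
                 alpha = alpha),
            class = "pattern_set")
}

#' Normalise a regulative pattern for display
#'
#' Divides the per-mark contributions and the bias jointly by the largest
#' absolute value among them, so the tallest bar is +/-1 and relative
#' signs and magnitudes are preserved; negative bars read as repressive
#' contributions, positive as activating, non-significant ones are
#' conventionally greyed. Idempotent; an all-zero pattern with zero bias
#' is returned unchanged with a warning.
#'
#' @param pattern a \code{regulative_pattern}.
#' @return a \code{regulative_pattern} with scaled \code{psi},
#'   \code{bias}, \code{logit} and \code{normalised = TRUE}.
#' @export
normalise_for_display <- function(pattern) {
  stopifnot(inherits(pattern, "regulative_pattern"))
  s <- max(abs(c(pattern$psi, pattern$bias)))
  if (s == 0) {
    warning("all-zero pattern with zero bias; returned unchanged")
    return(pattern)
  }
  pattern$psi <- pattern$psi / s
  pattern$bias <- pattern$bias / s
  pattern$logit <- pattern$logit / s
  pattern$normalised <- TRUE
  pattern
}

#' @export
print.regulative_pattern <- function(x, ...) {
  cat("regulative pattern",
      if (!is.null(x$gene_id)) paste0("for ", x$gene_id) else "",
      if (x$normalised) "(display-normalised)" else "", "\n")
  tab <- data.frame(psi = unname(x$psi), significant = unname(x$significant),
                    row.names = x$marks)
  print(round(tab["psi"], 4), right = TRUE)
  cat(sprintf("bias %.4f  logit %.4f\n", x$bias, x$logit))
  invisible(x)
}

#' Bar-chart of a regulative pattern
#'
#' Activating (positive) contributions in green, repressive (negative) in
#' red, marks whose weight is not significant at the pattern's alpha in
#' grey; the bias is drawn as an extra bar on the same axis.
#'
#' @param x a \code{regulative_pattern} (normalise first for a Fig-style
#'   common -1..1 axis).
#' @param ... passed to [graphics::barplot()].
#' @exportS3Method graphics::plot
plot.regulative_pattern <- function(x, ...) {
  vals <- c(x$psi, bias = x$bias)
  sig <- c(x$significant, TRUE)
  cols <- ifelse(!sig | is.na(sig), "grey70",
                 ifelse(vals >= 0, "forestgreen", "firebrick"))
  graphics::barplot(vals, col = cols, border = NA,
                    ylab = if (x$normalised) "normalised contribution"
                           else "contribution to logit",
                    main = x$gene_id %||% "regulative pattern", ...)
  graphics::abline(h = 0)
  invisible(x)
}
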