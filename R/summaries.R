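# Decision layer: Bayesian FDR on marginal posterior inclusion probabilities,
# thresholded association / network exports and TPR-FPR / ROC evaluators.

#' Bayes false discovery rate of a thresholded selection
#'
#' Selects every cell whose marginal posterior inclusion probability reaches
#' the threshold and reports the mean posterior exclusion probability among
#' the selected, `bFDR = mean(1 - mPIP)` over the selection (0 for an empty
#' selection).
#'
#' @param mpip Numeric vector or matrix of posterior inclusion probabilities.
#' @param threshold Selection threshold in (0,1).
#' @return List with `selected` (index matrix or vector), `bfdr`, `n_selected`.
#' @export
bayes_fdr <- function(mpip, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0,1)", call. = FALSE)
  sel <- which(mpip >= threshold, arr.ind = is.matrix(mpip))
  bfdr <- if (NROW(sel) == 0L) 0 else mean(1 - mpip[mpip >= threshold])
  list(selected = sel, bfdr = bfdr, n_selected = NROW(sel))
}

#' Threshold a fitted model into association and network exports
#'
#' Associations are (response, predictor) cells with `mPIP >= t_assoc`;
#' edges are response pairs with `mEPIP >= t_edge`.  The model-averaged edge
#' set need not form a decomposable graph even though every sampled graph is
#' decomposable.
#'
#' @param fit A `sur_fit` object (or a list with `mpip` / `mepip` and
#'   optionally `labels`, `pi_mean`).
#' @param t_edge,t_assoc Thresholds in (0,1); 0.5 is the default operating
#'   point, 0.9 a strict preset.
#' @return List with data frames `associations` (response, predictor, mPIP),
#'   `edges` (node1, node2, mEPIP) and `adjacency` (logical matrix).
#' @export
threshold_network <- function(fit, t_edge = 0.5, t_assoc = 0.5) {
  if (t_edge <= 0 || t_edge >= 1 || t_assoc <= 0 || t_assoc >= 1)
    stop("thresholds must be in (0,1)", call. = FALSE)
  mpip <- fit$mpip; mepip <- fit$mepip
  rn <- fit$labels$response
  pn <- fit$labels$predictor
  if (is.null(rn)) rn <- as.character(seq_len(nrow(mpip)))
  if (is.null(pn)) pn <- as.character(seq_len(ncol(mpip)))
  ai <- which(mpip >= t_assoc, arr.ind = TRUE)
  assoc <- data.frame(response = rn[ai[, 1L]], predictor = pn[ai[, 2L]],
                      mPIP = mpip[ai], stringsAsFactors = FALSE)
  assoc <- assoc[order(-assoc$mPIP), , drop = FALSE]
  ut <- upper.tri(mepip)
  ei <- which(ut & mepip >= t_edge, arr.ind = TRUE)
  edges <- data.frame(node1 = rn[ei[, 1L]], node2 = rn[ei[, 2L]],
                      mEPIP = mepip[ei], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$mEPIP), , drop = FALSE]
  adjacency <- mepip >= t_edge & (ut | t(ut))
  list(associations = assoc, edges = edges, adjacency = adjacency)
}

#' True / false positive rates and ROC curves for recovery evaluation
#'
#' Scores a probability matrix against a binary truth, either cell-wise
#' (associations) or over the upper-triangle off-diagonal entries (graph
#' edges).  With a threshold, returns the TPR / FPR pair at that operating
#' point; without one, the full ROC traced over the unique score values.
#' When the truth is degenerate (no positives or no negatives) the undefined
#' rate is reported as `NaN` with a warning.
#'
#' @param score Numeric matrix (or vector) of scores in any range.
#' @param truth Binary matrix (or vector) of the same shape.
#' @param threshold Optional operating threshold (`score >= threshold` calls
#'   a positive).
#' @param what `"cells"` or `"edges"` (upper triangle only).
#' @return For a threshold: list with `tpr`, `fpr`, counts.  Otherwise a
#'   data frame with columns `threshold`, `tpr`, `fpr` and an `auc`
#'   attribute.
#' @export
roc_tpr_fpr <- function(score, truth, threshold = NULL,
                        what = c("cells", "edges")) {
  what <- match.arg(what)
  if (!all(dim(as.matrix(score)) == dim(as.matrix(truth))))
    stop("score and truth shapes differ", call. = FALSE)
  if (what == "edges") {
    ut <- upper.tri(score)
    score <- score[ut]; truth <- truth[ut]
  }
  score <- as.vector(score); truth <- as.vector(truth) != 0
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L)
    warning("degenerate truth: ", if (np == 0L) "no positives" else "no negatives",
            "; undefined rate reported as NaN", call. = FALSE)
  rate <- function(t) {
    pos <- score >= t
    c(tpr = if (np) sum(pos & truth) / np else NaN,
      fpr = if (nn) sum(pos & !truth) / nn else NaN)
  }
  if (!is.null(threshold)) {
    r <- rate(threshold)
    return(list(tpr = unname(r["tpr"]), fpr = unname(r["fpr"]),
                tp = sum(score >= threshold & truth),
                fp = sum(score >= threshold & !truth),
                n_pos = np, n_neg = nn))
  }
  ts <- c(Inf, sort(unique(score), decreasing = TRUE))
  curve <- t(vapply(ts, rate, numeric(2)))
  out <- data.frame(threshold = ts, tpr = curve[, "tpr"], fpr = curve[, "fpr"])
  auc <- if (np && nn) sum(diff(out$fpr) * (out$tpr[-1] + out$tpr[-nrow(out)]) / 2)
         else NaN
  attr(out, "auc") <- auc
  out
}

#' Posterior summary of a fitted model
#'
#' Convenience accessor bundling mPIP, mEPIP, hotspot propensity means and
#' the bFDR-selected association set at a threshold.
#'
#' @param object A `sur_fit`.
#' @param threshold mPIP threshold for the selected set.
#' @param ... Unused.
#' @export
summary.sur_fit <- function(object, threshold = 0.5, ...) {
  bf <- bayes_fdr(object$mpip, threshold)
  structure(list(
    mpip = object$mpip, mepip = object$mepip,
    o_mean = object$o_mean, pi_mean = object$pi_mean,
    threshold = threshold, n_selected = bf$n_selected, bfdr = bf$bfdr,
    accept = object$accept,
    diagnostics = utils::tail(object$diagnostics, 5L)
  ), class = "summary.sur_fit")
}

#' @export
print.summary.sur_fit <- function(x, ...) {
  cat(sprintf("Associations with mPIP >= %.2f: %d (bFDR %.4f)\n",
              x$threshold, x$n_selected, x$bfdr))
  cat(sprintf("Edges with mEPIP >= %.2f: %d\n", x$threshold,
              sum(x$mepip[upper.tri(x$mepip)] >= x$threshold)))
  cat("Acceptance rates:\n")
  print(round(x$accept, 3))
  invisible(x)
}
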