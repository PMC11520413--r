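#' Weighted precision and recall at a threshold
#'
#' Protein-centric CAFA-style metrics with information-content weights.
#' At threshold `tau`, a protein's calls are its predicted terms with score
#' `>= tau`. Weighted precision averages `sum(IC[calls & truth]) /
#' sum(IC[calls])` over the `m(tau)` proteins with at least one call;
#' weighted recall averages `sum(IC[calls & truth]) / sum(IC[truth])` over
#' all `n_e` evaluated proteins (those present in the truth table). Branch
#' roots are expected to be excluded from both sides beforehand.
#'
#' @param preds data.frame `protein`, `term`, `score` (scores in `[0, 1]`).
#' @param truth named list protein -> true term ids, ancestor-propagated and
#'   root-free. Its names define the evaluated proteins.
#' @param ic named numeric vector of IC weights.
#' @param tau threshold in `[0, 1]`.
#' @return Named numeric `c(wpr, wrc, m)`.
#' @export
weighted_pr_rc <- function(preds, truth, ic, tau) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  n_e <- length(truth)
  calls <- preds[preds$score >= tau & preds$protein %in% names(truth), , drop = FALSE]
  calls_by <- split(calls$term, calls$protein)
  wpr_sum <- 0; m <- 0L; wrc_sum <- 0
  icw <- function(ts) sum(ic[ts], na.rm = TRUE)
  for (prot in names(truth)) {
    t_true <- truth[[prot]]
    t_call <- calls_by[[prot]] %||% character(0)
    if (length(t_call)) {
      m <- m + 1L
      denom <- icw(t_call)
      wpr_sum <- wpr_sum + if (denom > 0) icw(intersect(t_call, t_true)) / denom else 0
    }
    denom_rc <- icw(t_true)
    wrc_sum <- wrc_sum + if (denom_rc > 0) icw(intersect(t_call, t_true)) / denom_rc else 0
  }
  c(wpr = if (m > 0) wpr_sum / m else 0,
    wrc = if (n_e > 0) wrc_sum / n_e else 0,
    m = m)
}

#' Weighted maximum F-measure over a threshold grid
#'
#' Sweeps `tau` over the grid (default 0.01 steps over `[0.01, 1]`, the CAFA
#' convention), computes weighted precision/recall at each threshold, and
#' returns the maximum harmonic mean together with the full curve and the
#' optimizing threshold.
#'
#' @inheritParams weighted_pr_rc
#' @param tau_grid thresholds in `(0, 1]`.
#' @return An `eval_result`: list with `wfmax`, `tau`, `curve` (data.frame
#'   `tau`, `wpr`, `wrc`, `f`, `m`), `n_e`.
#' @export
wfmax <- function(preds, truth, ic, tau_grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(all(tau_grid > 0), all(tau_grid <= 1))
  if (!nrow(preds)) warning("no predictions; wFmax is 0")
  curve <- t(vapply(tau_grid, function(tau) weighted_pr_rc(preds, truth, ic, tau),
                    numeric(3)))
  f <- ifelse(curve[, "wpr"] + curve[, "wrc"] > 0,
              2 * curve[, "wpr"] * curve[, "wrc"] / (curve[, "wpr"] + curve[, "wrc"]),
              0)
  best <- which.max(f)
  structure(list(wfmax = unname(f[best]), tau = tau_grid[best],
                 curve = data.frame(tau = tau_grid, wpr = curve[, "wpr"],
                                    wrc = curve[, "wrc"], f = f, m = curve[, "m"]),
                 n_e = length(truth)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> wFmax = %.3f at tau = %.2f (n = %d proteins)\n",
              x$wfmax, x$tau, x$n_e))
  invisible(x)
}

#' F1 score from confusion counts
#'
#' `2TP / (2TP + FP + FN)`; errors when all three counts are zero.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param digits decimals for display rounding (`NULL` for no rounding).
#' @return F1 in `[0, 1]`.
#' @export
f1_from_counts <- function(tp, fp, fn, digits = 3) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (2 * tp + fp + fn == 0) stop("undefined F1: all counts are zero")
  f1 <- 2 * tp / (2 * tp + fp + fn)
  if (is.null(digits)) f1 else round(f1, digits)
}

#' Unweighted F1 between a candidate term set and the true set
#'
#' Used to validate the retrieval depth k: precision and recall between the
#' retrieved candidate set and the protein's (propagated, root-free) truth.
#'
#' @param cands a `candidate_set` or character vector of term ids.
#' @param truth character vector of true term ids.
#' @return F1 in `[0, 1]`; 0 (with a warning) when both sets are empty.
#' @export
candidate_set_f1 <- function(cands, truth) {
  terms <- if (inherits(cands, "candidate_set")) cands$terms else cands
  if (!length(terms) && !length(truth)) {
    warning("both candidate and truth sets are empty; F1 defined as 0")
    return(0)
  }
  tp <- length(intersect(terms, truth))
  2 * tp / (length(terms) + length(truth))
}

#' Macro average of branch-level scores
#'
#' @param values numeric vector (e.g. per-branch wFmax).
#' @param digits decimals for display rounding.
#' @return Arithmetic mean.
#' @export
macro_average <- function(values, digits = 3) {
  if (!length(values)) stop("cannot average an empty vector")
  round(mean(values), digits)
}

#' Relative improvement of one score over another, in percent
#'
#' `100 * (a - b) / b`, displayed to one decimal.
#'
#' @param a,b scores; `b` must be positive.
#' @param digits decimals for display rounding.
#' @return Percent improvement.
#' @export
relative_improvement <- function(a, b, digits = 1) {
  if (b <= 0) stop("baseline must be positive")
  round(100 * (a - b) / b, digits)
}
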