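#' Confusion counts between an inferred and a reference network
#'
#' Compares the edge sets of the inferred network and the reference
#' (ground-truth) network over the full pair universe of the roster —
#' `N(N-1)` ordered pairs for directed networks, `N(N-1)/2` unordered pairs
#' for undirected ones, self-pairs excluded. TP counts edges present in
#' both, TN pairs absent from both, FP edges only in the inferred network,
#' FN edges only in the reference.
#'
#' @param bt inferred [social_network].
#' @param gt reference [social_network]; must share directedness with `bt`.
#' @param roster pair universe; defaults to the union of the two node sets
#'   and must contain both.
#' @return object of class `confusion_counts`: named integer vector
#'   `tp, tn, fp, fn`.
#' @export
confusion <- function(bt, gt, roster = NULL) {
  stopifnot(inherits(bt, "social_network"), inherits(gt, "social_network"))
  if (bt$directed != gt$directed) {
    stop("networks must share connection type (both directed or both undirected)",
         call. = FALSE)
  }
  if (is.null(roster)) roster <- union(bt$nodes, gt$nodes)
  if (!all(c(bt$nodes, gt$nodes) %in% roster)) {
    stop("roster must contain all nodes of both networks", call. = FALSE)
  }
  n <- length(roster)
  total <- if (bt$directed) n * (n - 1L) else n * (n - 1L) / 2L
  eb <- edge_set(bt)
  eg <- edge_set(gt)
  tp <- length(intersect(eb, eg))
  fp <- length(setdiff(eb, eg))
  fn <- length(setdiff(eg, eb))
  tn <- total - tp - fp - fn
  structure(c(tp = tp, tn = as.integer(tn), fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d TN=%d FP=%d FN=%d>\n",
              x[["tp"]], x[["tn"]], x[["fp"]], x[["fn"]]))
  invisible(x)
}

#' Classification accuracy of edge inference
#'
#' Fraction of node pairs whose edge/non-edge status agrees between the
#' inferred and the reference network: `(TP + TN) / (TP + TN + FP + FN)`.
#' Appropriate when edge and non-edge classes are roughly balanced (dense
#' class networks); for sparse references prefer [mcc()].
#'
#' @param cc a [confusion()] result, or any vector with named elements
#'   `tp`, `tn`, `fp`, `fn`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cc) {
  tot <- cc[["tp"]] + cc[["tn"]] + cc[["fp"]] + cc[["fn"]]
  if (tot <= 0) stop("empty pair universe", call. = FALSE)
  (cc[["tp"]] + cc[["tn"]]) / tot
}

#' Matthews correlation coefficient of edge inference
#'
#' Correlation-style score over the confusion matrix,
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`:
#' +1 for perfect classification, -1 for perfect misclassification, 0 for a
#' coin-tossing classifier. Robust to class imbalance, hence the metric of
#' choice when the reference network is sparse. When any factor of the
#' denominator is zero the score is defined as 0.
#'
#' @inheritParams accuracy
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc[["tp"]]); tn <- as.numeric(cc[["tn"]])
  fp <- as.numeric(cc[["fp"]]); fn <- as.numeric(cc[["fn"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}
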