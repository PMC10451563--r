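#' Compare a learned network against a ground truth
#'
#' Directed-edge recovery metrics. An edge counts as a true positive only
#' with identical direction. A learned edge whose reverse exists in the truth
#' is a false positive (and the truth edge a false negative) for
#' precision/recall, but contributes exactly one reversal to the structural
#' Hamming distance. The SHD decomposes as
#' `SHD = Redu + Miss + Reve`: redundant learned edges absent from the truth
#' in either orientation, truth edges absent from the learned graph in either
#' orientation, and wrongly oriented edges.
#'
#' Degenerate ratios (`0/0` when a graph is empty) are defined as 0 and
#' flagged via the `degenerate` field rather than raising an error.
#'
#' @param learned,truth [cbn()] objects on the same node set (reconciled by
#'   label).
#' @return list of class `"cbn_eval"` with fields `tp`, `fp`, `fn`, `redu`,
#'   `miss`, `reve`, `precision`, `recall`, `f1`, `shd`, `degenerate`.
#' @examples
#' tr <- cbn_from_edges(cbind("A", "B"), labels = c("A", "B", "C"))
#' le <- cbn_from_edges(cbind("B", "A"), labels = c("A", "B", "C"))
#' compare_cbn(le, tr)$shd  # one reversal
#' @export
compare_cbn <- function(learned, truth) {
  stopifnot(inherits(learned, "cbn"), inherits(truth, "cbn"))
  if (!setequal(learned$labels, truth$labels))
    stop("learned and truth graphs are over different node sets")
  L <- cbn_adjacency(learned)
  Tm <- cbn_adjacency(truth)[learned$labels, learned$labels]

  tp <- sum(L == 1L & Tm == 1L)
  fp <- sum(L == 1L & Tm == 0L)
  fn <- sum(Tm == 1L & L == 0L)
  reve <- sum(L == 1L & Tm == 0L & t(Tm) == 1L)
  redu <- sum(L == 1L & Tm == 0L & t(Tm) == 0L)
  miss <- sum(Tm == 1L & L == 0L & t(L) == 0L)

  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, redu = redu, miss = miss,
                 reve = reve, precision = precision, recall = recall,
                 f1 = f1, shd = redu + miss + reve,
                 degenerate = degenerate),
            class = "cbn_eval")
}

#' @export
print.cbn_eval <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Precision %.*f  Recall %.*f  F1 %.*f  SHD %d  (TP %d FP %d FN %d | redundant %d missing %d reversed %d)%s\n",
    digits, x$precision, digits, x$recall, digits, x$f1, x$shd,
    x$tp, x$fp, x$fn, x$redu, x$miss, x$reve,
    if (x$degenerate) "  [degenerate: empty graph]" else ""))
  invisible(x)
}

#' Tabulate evaluation reports
#'
#' Collects a list of [compare_cbn()] reports into a data frame of
#' precision / recall / F1 / SHD per run, with mean and standard-deviation
#' summary rows appended.
#'
#' @param reports list of `"cbn_eval"` objects.
#' @param labels optional run labels (default `run1..runK`).
#' @return data frame with one row per report plus `mean` and `sd` rows.
#' @export
eval_table <- function(reports, labels = NULL) {
  if (inherits(reports, "cbn_eval")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  if (is.null(labels)) labels <- paste0("run", seq_along(reports))
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(precision = r$precision, recall = r$recall, f1 = r$f1,
               shd = r$shd)))
  rownames(tab) <- labels
  summary <- rbind(mean = colMeans(tab), sd = apply(tab, 2L, stats::sd))
  rbind(tab, summary)
}
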