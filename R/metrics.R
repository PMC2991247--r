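## Metric-comparison bench: alternative association measures, pairwise
## ranking matrices, and the similarity-to-significance measure D.

#' ROC area from site and control distances
#'
#' Probability that a random experimental-site distance is smaller than a
#' random control distance, ties counting one half (rank formulation;
#' identical to sweeping the window threshold over all distances).
#'
#' @param siteDist,ctrlDist numeric distance vectors (may contain Inf).
#' @return AUC in `[0, 1]`.
#' @export
aucROC <- function(siteDist, ctrlDist) {
  if (!length(siteDist) || !length(ctrlDist))
    inputError("aucROC requires non-empty distance vectors")
  nV <- length(siteDist); nC <- length(ctrlDist)
  r <- rank(c(siteDist, ctrlDist))
  uC <- sum(r[(nV + 1):(nV + nC)]) - nC * (nC + 1) / 2
  uC / (nV * nC)
}

#' Area under the precision-recall curve (normalized precision)
#'
#' The window threshold is swept over all observed distances; at each
#' threshold recall is the fraction of experimental sites within, and
#' precision uses the normalized false-positive count `fp' = fp * V / C` to
#' stay on the same precision scale as the F score. Trapezoidal integration
#' over recall, the curve anchored at recall 0 with the first threshold's
#' precision.
#'
#' @inheritParams aucROC
#' @param V,C dataset sizes; default the vector lengths.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(siteDist, ctrlDist, V = length(siteDist),
                 C = length(ctrlDist)) {
  if (!length(siteDist) || !length(ctrlDist))
    inputError("aupr requires non-empty distance vectors")
  th <- sort(unique(c(siteDist, ctrlDist)))
  tp <- vapply(th, function(t) sum(siteDist <= t), numeric(1))
  fp <- vapply(th, function(t) sum(ctrlDist <= t), numeric(1))
  fpn <- fp * V / C
  R <- tp / V
  P <- ifelse(tp + fpn > 0, tp / (tp + fpn), 1)
  R <- c(0, R); P <- c(P[1L], P)
  sum(diff(R) * (head(P, -1) + tail(P, -1)) / 2)
}

#' Odds ratio of a contingency table
#'
#' `(tp * tn) / (fn * fp)`; when any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) and the result is flagged.
#'
#' @param tab a [ContingencyTable-class].
#' @return list with `or` and `corrected` flag.
#' @export
oddsRatio <- function(tab) {
  cells <- c(tab@tp, tab@fn, tab@fp, tab@tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(or = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       corrected = corrected)
}

#' Shannon mutual information of a contingency table
#'
#' Empirical mutual information (base 2) between the class label
#' (experimental vs control) and the association status (within vs beyond),
#' with 0 log 0 = 0.
#'
#' @param tab a [ContingencyTable-class].
#' @return mutual information in bits (>= 0).
#' @export
shannonMI <- function(tab) {
  n <- c(tab@tp, tab@fn, tab@fp, tab@tn)
  N <- sum(n)
  if (N == 0) inputError("empty table")
  p <- matrix(n / N, 2, 2, byrow = TRUE)  # rows: class; cols: within/beyond
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  max(sum(terms[p > 0]), 0)
}

#' Difference of proportions
#'
#' `tp/V - fp/C`.
#' @param tab a [ContingencyTable-class].
#' @return numeric in `[-1, 1]`.
#' @export
diffProportions <- function(tab) {
  V <- tab@tp + tab@fn; C <- tab@fp + tab@tn
  if (V == 0 || C == 0) inputError("diffProportions requires V, C > 0")
  tab@tp / V - tab@fp / C
}

#' Pairwise ranking matrix of marker scores
#'
#' N x N 0/1 matrix; entry (i, j) is 1 iff marker i strictly outranks marker
#' j under the metric. Ties leave both entries 0.
#'
#' @param scores named numeric vector of per-marker scores.
#' @return 0/1 matrix with marker dimnames.
#' @export
rankingMatrix <- function(scores) {
  if (length(scores) < 2L) inputError("need at least 2 markers")
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    inputError("scores must have unique marker names")
  M <- 1 * outer(scores, scores, `>`)
  diag(M) <- 0
  dimnames(M) <- list(names(scores), names(scores))
  M
}

#' Similarity of a metric's ranking to the significance ranking
#'
#' `D = 1 - sum(|M_X - S|) / (N (N - 1))` over all ordered pairs; D = 1 iff
#' the two pairwise rankings agree on every ordered pair.
#'
#' @param MX ranking matrix of the metric (see [rankingMatrix()]).
#' @param S ranking matrix of the significance reference.
#' @return list with `D` and a data.frame of discordant ordered pairs.
#' @export
similarityD <- function(MX, S) {
  if (!identical(dimnames(MX), dimnames(S)) || is.null(dimnames(MX)))
    inputError("ranking matrices must carry identical marker labels")
  N <- nrow(MX)
  diff <- abs(MX - S)
  D <- 1 - sum(diff) / (N * (N - 1))
  idx <- which(diff != 0, arr.ind = TRUE)
  list(D = D,
       discordant = data.frame(i = rownames(MX)[idx[, 1]],
                               j = colnames(MX)[idx[, 2]]))
}

## Significance score used for the reference ranking: -log10 raw p, capped
## at the 1e-350 reporting floor.
significanceScore <- function(log10p) pmin(-log10p, 350)

#' Run the full metric bench over a set of markers
#'
#' Computes every requested metric for each marker at one window, ranks the
#' markers per metric, and reports the similarity D of each metric's ranking
#' to the ranking by Fisher significance (-log10 raw p, capped at 350).
#'
#' @inheritParams associate
#' @param markers named list of [PeakSet-class] objects (>= 2).
#' @param metrics subset of c("auc","aupr","f0.5","f1","f2","or","smi","dop").
#' @return list with `scores` (data.frame, one row per marker), `D`
#'   (data.frame metric/D), and `discordant` (named list of pair tables).
#' @export
rankBench <- function(sites, controls, markers, window = 2000,
                      metrics = c("auc", "aupr", "f0.5", "f1", "f2", "or",
                                  "smi", "dop"),
                      mode = c("summit", "boundary")) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(markers) < 2L) inputError("need at least 2 markers")
  if (is.null(names(markers)) || anyDuplicated(names(markers)))
    inputError("markers must be a uniquely named list")
  V <- length(sites); C <- length(controls)
  rows <- lapply(names(markers), function(nm) {
    ds <- markerDistances(sites, markers[[nm]], mode)
    dc <- markerDistances(controls, markers[[nm]], mode)
    tab <- contingencyFromDistances(ds, dc, window)
    out <- data.frame(marker = nm)
    if ("auc" %in% metrics) out$auc <- aucROC(ds, dc)
    if ("aupr" %in% metrics) out$aupr <- aupr(ds, dc, V, C)
    for (b in c(0.5, 1, 2)) {
      key <- paste0("f", sub("\\.0$", "", format(b)))
      if (key %in% metrics) out[[key]] <- fScore(tab, b)$fscore
    }
    if ("or" %in% metrics) out$or <- oddsRatio(tab)$or
    if ("smi" %in% metrics) out$smi <- shannonMI(tab)
    if ("dop" %in% metrics) out$dop <- diffProportions(tab)
    out$neglog10p <- significanceScore(fisherPvalue(tab)$log10p)
    out
  })
  scores <- do.call(rbind, rows)
  S <- rankingMatrix(stats::setNames(scores$neglog10p, scores$marker))
  Drows <- list(); discordant <- list()
  for (m in setdiff(colnames(scores), c("marker", "neglog10p"))) {
    sim <- similarityD(rankingMatrix(stats::setNames(scores[[m]],
                                                     scores$marker)), S)
    Drows[[m]] <- data.frame(metric = m, D = sim$D)
    discordant[[m]] <- sim$discordant
  }
  list(scores = scores, D = do.call(rbind, Drows), discordant = discordant)
}
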