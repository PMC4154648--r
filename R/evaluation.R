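# Classification-performance machinery, randomization controls,
# profile-agreement statistics and phenotype-map coordinates.

#' ROC, precision-recall and balanced-accuracy curves for a gene ranking
#'
#' Genes are scored by p-value (ascending = better) and compared against
#' positive/negative label sets. The threshold sweep runs over the sorted
#' distinct scores, inclusive (score <= threshold predicts positive), so
#' tied scores move in one step. Balanced accuracy is
#' (sensitivity + specificity)/2; with balanced classes it equals plain
#' accuracy at every threshold. The AUC is the trapezoidal integral of
#' the ROC curve, with the Hanley-McNeil standard error and a one-sided
#' z-test against the chance level 0.5.
#'
#' @param scores named numeric vector of gene scores in `[0, 1]` (lower is
#'   better). Labeled genes missing from `scores` are dropped.
#' @param positives,negatives character vectors of gene identifiers.
#' @return an object of class `eval_curves`: data frames `roc`
#'   (threshold, fpr, tpr), `pr` (recall, precision), `bacc` (threshold,
#'   bacc), plus `auc`, `sem`, `p_vs_random`, `n_pos`, `n_neg`.
#' @export
roc_pr_bacc <- function(scores, positives, negatives) {
  lab <- c(stats::setNames(rep(TRUE, length(positives)), positives),
           stats::setNames(rep(FALSE, length(negatives)), negatives))
  lab <- lab[names(lab) %in% names(scores)]
  if (!any(lab) || !any(!lab))
    stop("need at least one positive and one negative labeled gene")
  s <- scores[names(lab)]
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  thr <- sort(unique(s))
  ord <- order(s, method = "radix")
  s_sorted <- s[ord]
  lab_sorted <- lab[ord]
  cum_tp <- cumsum(lab_sorted)
  cum_fp <- cumsum(!lab_sorted)
  last <- findInterval(thr, s_sorted)      # index of last score <= thr
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  tnr <- 1 - fpr
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  roc <- data.frame(threshold = c(-Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = Inf, fpr = 1, tpr = 1))
  auc <- auc_trapezoid(roc$fpr, roc$tpr)
  sem <- hanley_sem(auc, n_pos, n_neg)
  structure(list(
    roc = roc,
    pr = data.frame(threshold = thr, recall = tpr, precision = prec),
    bacc = data.frame(threshold = thr, bacc = (tpr + tnr) / 2),
    auc = auc, sem = sem, p_vs_random = auc_ztest(auc, sem),
    n_pos = n_pos, n_neg = n_neg),
    class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("eval_curves: AUC = %.4f (sem %.4f, p vs 0.5 = %.3g), %d positives / %d negatives\n",
              x$auc, x$sem, x$p_vs_random, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.eval_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "FPR",
                 ylab = "TPR", main = sprintf("ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::plot(x$pr$recall, x$pr$precision, type = "l", xlab = "recall",
                 ylab = "precision", main = "Precision-recall", ...)
  graphics::plot(x$bacc$threshold, x$bacc$bacc, type = "l",
                 xlab = "p-value threshold", ylab = "balanced accuracy",
                 main = "BACC", ...)
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param fpr,tpr coordinates of the ROC curve, ordered by `fpr`.
#' @return the trapezoidal integral in `[0, 1]`.
#' @export
auc_trapezoid <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr), length(fpr) >= 2)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Uses Q1 = A/(2-A) and Q2 = 2A^2/(1+A).
#'
#' @param auc the AUC value A in `[0, 1]`.
#' @param n_pos,n_neg numbers of positive and negative cases.
#' @return the standard error.
#' @export
hanley_sem <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1, auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' One-sided z-test of an AUC against chance
#'
#' Tests AUC > 0.5 via z = (AUC - 0.5)/sem.
#'
#' @param auc the AUC value.
#' @param sem its standard error (e.g. [hanley_sem()]).
#' @return one-sided p-value; 0.5 at AUC = 0.5, and the `sem = 0` limit
#'   gives 0 (1) for AUC above (below) 0.5.
#' @export
auc_ztest <- function(auc, sem) {
  if (sem == 0) return(if (auc > 0.5) 0 else if (auc < 0.5) 1 else 0.5)
  stats::pnorm((auc - 0.5) / sem, lower.tail = FALSE)
}

#' Compare two AUCs by stratified bootstrap
#'
#' Resamples positives and negatives separately (with replacement),
#' recomputes both rankings' AUCs on each replicate and applies a z-test
#' to D = (A1 - A2) / sd(A1* - A2*). Two identical rankings give p = 1 by
#' convention (the 0/0 statistic is guarded).
#'
#' @param scores1,scores2 named score vectors (lower = better) over a
#'   shared label set.
#' @param positives,negatives label gene sets.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param rng_seed optional integer seed.
#' @return list with `auc1`, `auc2`, `D`, `p_value`, `n_boot`.
#' @export
bootstrap_auc_compare <- function(scores1, scores2, positives, negatives,
                                  n_boot = 1000, rng_seed = NULL) {
  stopifnot(n_boot >= 100)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pos <- intersect(positives, intersect(names(scores1), names(scores2)))
  neg <- intersect(negatives, intersect(names(scores1), names(scores2)))
  a1 <- .auc_fast(scores1, pos, neg)
  a2 <- .auc_fast(scores2, pos, neg)
  d <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pb <- sample(pos, replace = TRUE)
    nb <- sample(neg, replace = TRUE)
    d[b] <- .auc_values(scores1[pb], scores1[nb]) -
      .auc_values(scores2[pb], scores2[nb])
  }
  sdd <- stats::sd(d)
  if (sdd == 0 || is.na(sdd)) {
    D <- 0
    p <- if (a1 == a2) 1 else 0
  } else {
    D <- (a1 - a2) / sdd
    p <- 2 * stats::pnorm(-abs(D))
  }
  list(auc1 = a1, auc2 = a2, D = D, p_value = p, n_boot = n_boot)
}

# rank-based AUC (tie-corrected Mann-Whitney); lower score = better, so
# the AUC is the probability a positive scores below a negative
.auc_values <- function(sp, sn) {
  rk <- rank(c(sp, sn))
  u <- sum(rk[length(sp) + seq_along(sn)]) -
    length(sn) * (length(sn) + 1) / 2
  u / (length(sp) * length(sn))
}

.auc_fast <- function(scores, pos, neg) .auc_values(scores[pos], scores[neg])

#' Randomization controls for network and screen
#'
#' Produces the randomized counterparts used as negative controls:
#' \describe{
#'   \item{`"edges"`}{degree-preserving double-edge swaps (at least
#'     10x the edge count), destroying topology but keeping the degree
#'     sequence;}
#'   \item{`"genes"`}{permutes gene labels over the network nodes
#'     (profiles travel with their gene, topology unchanged);}
#'   \item{`"profiles"`}{permutes whole per-gene profile bundles between
#'     genes with identical profile counts, keeping the profiles-per-gene
#'     structure intact;}
#'   \item{`"edges+profiles"`}{composes the edge and profile shuffles.}
#' }
#'
#' @param network an igraph network.
#' @param screen a [phenotype_screen].
#' @param mode one of `"edges"`, `"genes"`, `"profiles"`,
#'   `"edges+profiles"`.
#' @param rng_seed optional integer seed.
#' @return list with elements `network` and `screen`.
#' @export
shuffle_network <- function(network, screen,
                            mode = c("edges", "genes", "profiles",
                                     "edges+profiles"),
                            rng_seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (mode %in% c("edges", "edges+profiles")) {
    network <- igraph::rewire(
      network, igraph::keeping_degseq(niter = max(10 * igraph::ecount(network), 1)))
  }
  if (mode == "genes") {
    nm <- igraph::V(network)$name
    igraph::V(network)$name <- sample(nm)
  }
  if (mode %in% c("profiles", "edges+profiles")) {
    m <- profile_counts(screen)
    new_gene <- stats::setNames(names(m), names(m))
    for (c0 in unique(m)) {
      g <- names(m)[m == c0]
      if (length(g) > 1L) new_gene[g] <- sample(g)
    }
    # gene g's bundle is handed to new_gene[g]; rebuild row labels
    gene2 <- unname(new_gene[screen$gene])
    ord <- order(match(gene2, screen$genes),
                 stats::ave(seq_along(gene2), gene2, FUN = seq_along))
    screen <- phenotype_screen(screen$values[ord, , drop = FALSE],
                               gene2[ord], screen$oligo[ord],
                               screen$parameter_names)
  }
  list(network = network, screen = screen)
}

#' Add Gaussian measurement noise to a screen
#'
#' Adds an independent N(0, sigma) increment to every parameter of every
#' profile, emulating extra technical noise on z-normalized data.
#'
#' @param screen a [phenotype_screen].
#' @param sigma noise standard deviation (>= 0).
#' @param rng_seed optional integer seed.
#' @return the perturbed [phenotype_screen].
#' @export
add_noise <- function(screen, sigma, rng_seed = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (sigma == 0) return(screen)
  out <- screen
  out$values <- screen$values +
    matrix(stats::rnorm(length(screen$values), 0, sigma),
           nrow(screen$values), ncol(screen$values))
  out
}

#' Cross-group profile agreement
#'
#' All pairwise Pearson correlations between the profiles of two groups
#' (e.g. the profiles selected for a gene versus its independent rescreen
#' profiles). Two such correlation distributions are compared with
#' [agreement_tests()].
#'
#' @param group_a,group_b numeric matrices, profiles in rows (a single
#'   profile may be given as a vector).
#' @return numeric vector of cross-group correlations.
#' @export
profile_agreement <- function(group_a, group_b) {
  if (is.null(dim(group_a))) group_a <- matrix(group_a, 1)
  if (is.null(dim(group_b))) group_b <- matrix(group_b, 1)
  stopifnot(nrow(group_a) >= 1, nrow(group_b) >= 1)
  Za <- .row_standardize(group_a)
  Zb <- .row_standardize(group_b)
  as.vector(tcrossprod(Za, Zb))
}

#' Compare two correlation distributions
#'
#' Two-sample Kolmogorov-Smirnov and Mann-Whitney U tests of the
#' difference between two distributions of correlation values (e.g.
#' selected-vs-rescreen against rejected-vs-rescreen).
#'
#' @param r1,r2 numeric vectors of correlation values.
#' @return list with `ks_p` and `mw_p`.
#' @export
agreement_tests <- function(r1, r2) {
  ks <- suppressWarnings(stats::ks.test(r1, r2))
  mw <- suppressWarnings(stats::wilcox.test(r1, r2))
  list(ks_p = ks$p.value, mw_p = mw$p.value)
}

#' Phenotype-map coordinates of a reference profile
#'
#' Maps a reference profile onto two interpretable axes from a two-channel
#' parameter partition (e.g. transferrin and EGF endocytosis parameters):
#' x is the difference of the channel L2 norms (which cargo dominates) and
#' y their sum (overall phenotype strength).
#'
#' @param reference numeric vector (length N) or matrix of reference
#'   profiles in rows.
#' @param channel1,channel2 integer indices of the two channels' parameters
#'   (disjoint). `x = ||channel2|| - ||channel1||`,
#'   `y = ||channel2|| + ||channel1||`; swap the arguments to flip roles.
#' @return data frame with columns `x` and `y`.
#' @export
phenotype_map_coords <- function(reference, channel1, channel2) {
  if (is.null(dim(reference))) reference <- matrix(reference, 1)
  if (length(intersect(channel1, channel2)))
    stop("channel index sets must be disjoint")
  if (any(c(channel1, channel2) < 1) ||
      any(c(channel1, channel2) > ncol(reference)))
    stop("channel indices out of range")
  n1 <- sqrt(rowSums(reference[, channel1, drop = FALSE]^2))
  n2 <- sqrt(rowSums(reference[, channel2, drop = FALSE]^2))
  data.frame(x = n2 - n1, y = n2 + n1)
}

#' Chi-square phenotype-strength baseline
#'
#' The screen-only baseline that ignores prior information: each gene's
#' profiles are collapsed to one (per-parameter average, or the "mode"
#' profile implemented as the medoid oligo profile) and scored by the
#' upper-tail chi-square probability of the squared profile norm on N
#' degrees of freedom. Smaller p = stronger phenotype.
#'
#' @param screen a z-normalized [phenotype_screen].
#' @param collapse `"mode"` or `"average"`.
#' @return named numeric vector of p-values (ascending = stronger).
#' @export
chi_square_baseline <- function(screen, collapse = c("mode", "average")) {
  collapse <- match.arg(collapse)
  coll <- collapse_screen(screen, if (collapse == "mode") "mode" else "average")
  stat <- rowSums(coll$values^2)
  stats::setNames(stats::pchisq(stat, df = ncol(coll$values),
                                lower.tail = FALSE),
                  coll$gene)
}
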