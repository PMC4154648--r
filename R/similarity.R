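# Profile-similarity primitives shared by the set- and module-based searches.
# Correlations are computed from row-standardized profile matrices so that a
# pairwise similarity matrix is a single tcrossprod.

# rows scaled to mean 0 and unit sum of squares; zero-variance rows -> NA
.row_standardize <- function(values) {
  x <- values - rowMeans(values)
  ss <- sqrt(rowSums(x * x))
  ss[ss < .Machine$double.eps^0.5 * sqrt(ncol(values))] <- NA_real_
  x / ss
}

#' Pearson correlation between two profiles
#'
#' Returns `NA` (an "undefined correlation" signal; callers treat it as
#' not-similar) when either profile has zero variance, instead of aborting.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return Pearson r in `[-1, 1]`, or `NA`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (length(a) < 3L) stop("profiles must have at least 3 parameters")
  sa <- stats::sd(a); sb <- stats::sd(b)
  eps <- .Machine$double.eps^0.5
  if (is.na(sa) || is.na(sb) || sa < eps || sb < eps) return(NA_real_)
  stats::cor(a, b)
}

#' Pairwise similarity matrix of a set of profiles
#'
#' All pairwise Pearson correlations between the rows of a profile matrix.
#' Pairs involving a zero-variance profile are `NA` (not similar); the
#' diagonal is 1.
#'
#' @param values numeric matrix, profiles in rows.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(values) {
  values <- as.matrix(values)
  S <- tcrossprod(.row_standardize(values))
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(rownames(values), rownames(values))
  S
}

#' Similarity policy
#'
#' A similarity call declares two profiles "similar" when their Pearson
#' correlation passes a threshold `T`. In `"positive"` mode only positive
#' correlations count (`r >= T`, used by the gene-set search); in
#' `"absolute"` mode anti-correlated profiles count too (`|r| >= T`, used
#' by the module search, where profile sign is handled by orientation).
#' The threshold is closed (equality passes).
#'
#' @param T similarity threshold in `(0, 1]`; the screen-analysis operating
#'   point used throughout is 0.7.
#' @param mode `"positive"` or `"absolute"`.
#' @return an object of class `similarity_policy`.
#' @export
similarity_policy <- function(T = 0.7, mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0 || T > 1)
    stop("'T' must be a single value in (0, 1]")
  structure(list(T = T, mode = mode), class = "similarity_policy")
}

#' @export
print.similarity_policy <- function(x, ...) {
  cat(sprintf("similarity_policy: %s, T = %g\n",
              if (x$mode == "positive") "r >= T" else "|r| >= T", x$T))
  invisible(x)
}

#' Apply a similarity policy
#'
#' @param r numeric vector of correlation values (`NA` = undefined).
#' @param policy a [similarity_policy].
#' @return logical vector; undefined correlations are `FALSE`.
#' @export
is_similar <- function(r, policy) {
  stopifnot(inherits(policy, "similarity_policy"))
  out <- if (policy$mode == "positive") r >= policy$T else abs(r) >= policy$T
  out[is.na(out)] <- FALSE
  out
}
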