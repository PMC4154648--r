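# Gene-set analysis: find the phenotypic pattern shared by the largest
# number of genes in a set, summarize it as a reference profile, and assess
# it with structure-preserving permutations (random pseudo-sets with the
# same number of genes and the same profiles-per-gene structure, keeping
# each gene's profiles together so within-gene correlation is preserved).

# Core search over a row subset of the screen. `Z` is the row-standardized
# profile matrix for the whole screen (see .row_standardize); `rows` are
# global row indices. Returns local/global indices of the winning anchor
# and its selected profiles.
.pattern_search <- function(rows, screen, Z, policy) {
  Zs <- Z[rows, , drop = FALSE]
  S <- tcrossprod(Zs)
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  SIM <- if (policy$mode == "positive") S >= policy$T else abs(S) >= policy$T
  SIM[is.na(SIM)] <- FALSE
  diag(SIM) <- TRUE                      # a profile always matches itself
  g <- screen$gene[rows]
  f <- factor(g)
  covered <- rowsum(t(SIM) + 0L, f) > 0  # genes x anchors
  n_T <- colSums(covered)
  W <- if (policy$mode == "positive") S else abs(S)
  W[!SIM] <- 0
  sum_r <- rowSums(W)
  best <- order(-n_T, -sum_r, g, screen$oligo[rows], method = "radix")[1L]
  sel <- which(SIM[best, ])
  list(anchor = rows[best], selected = rows[sel], r = S[best, sel],
       n_T = n_T[[best]], sum_r = sum_r[[best]], n_selected = length(sel))
}

#' Find the enriched phenotypic pattern of a gene set
#'
#' Scans every profile of the set as a candidate anchor and counts the
#' number of distinct genes owning at least one profile similar to it
#' under `policy` (the anchor's own gene always counts). The anchor
#' maximizing that gene count `n_T` wins; ties are broken by the maximal
#' sum of (absolute, in absolute mode) correlation values of the selected
#' profiles, remaining ties by lowest (gene, oligo) label order. The
#' selected profiles are, for each covered gene, all of its profiles
#' passing the policy against the anchor.
#'
#' @param set_genes character vector of member gene identifiers.
#' @param screen a [phenotype_screen] (normally z-normalized).
#' @param policy a [similarity_policy]; the set analysis uses positive
#'   mode by default since complex members are expected to co-vary.
#' @return an object of class `enriched_pattern` with elements `anchor`
#'   (gene, oligo, row), `selected` (data frame of gene, oligo, row, r),
#'   `n_T`, `sum_r` and `n_selected`.
#' @export
find_enriched_pattern <- function(set_genes, screen,
                                  policy = similarity_policy()) {
  stopifnot(inherits(screen, "phenotype_screen"))
  rows <- which(screen$gene %in% set_genes)
  if (length(rows) == 0L) stop("empty set after restriction to the screen")
  Z <- .row_standardize(screen$values[rows, , drop = FALSE])
  res <- .pattern_search(seq_along(rows), list(gene = screen$gene[rows],
                                               oligo = screen$oligo[rows]),
                         Z, policy)
  res$anchor <- rows[res$anchor]
  res$selected <- rows[res$selected]
  .as_pattern(res, screen)
}

.as_pattern <- function(res, screen) {
  structure(list(
    anchor = list(gene = screen$gene[res$anchor],
                  oligo = screen$oligo[res$anchor],
                  row = res$anchor),
    selected = data.frame(gene = screen$gene[res$selected],
                          oligo = screen$oligo[res$selected],
                          row = res$selected, r = res$r,
                          stringsAsFactors = FALSE),
    n_T = res$n_T, sum_r = res$sum_r, n_selected = res$n_selected),
    class = "enriched_pattern")
}

#' @export
print.enriched_pattern <- function(x, ...) {
  cat(sprintf("enriched_pattern: anchor %s/%s, %d gene(s) covered, %d profile(s) selected\n",
              x$anchor$gene, x$anchor$oligo, x$n_T, x$n_selected))
  invisible(x)
}

#' Reference profile of a selection of profiles
#'
#' The per-parameter median of the (optionally sign-adjusted) selected
#' profiles; even counts use the midpoint of the two central values.
#'
#' @param values numeric matrix, selected profiles in rows.
#' @param signs optional vector of +1/-1 per profile (anti-correlated
#'   profiles are swapped before taking the median).
#' @return numeric vector of length `ncol(values)`.
#' @export
reference_profile <- function(values, signs = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("no profiles selected")
  if (!is.null(signs)) {
    if (length(signs) != nrow(values))
      stop("'signs' must have one entry per profile")
    values <- values * signs
  }
  apply(values, 2, stats::median)
}

# Assign each required profile count to a sampling stratum: genes with the
# exact same count when the pool allows (at least 5 candidates, so the
# draw is not degenerate), otherwise the count's profile-count bin.
.permutation_strata <- function(req_counts, pool_counts, bin_breaks = NULL) {
  req <- table(req_counts)
  strata <- list()
  pool_bins <- .count_bin(pool_counts, bin_breaks)
  for (cs in names(req)) {
    c0 <- as.integer(cs)
    need <- as.integer(req[[cs]])
    exact <- names(pool_counts)[pool_counts == c0]
    if (length(exact) >= max(need, 5L)) {
      key <- paste0("m=", c0)
      pool <- exact
    } else {
      b <- .count_bin(c0, bin_breaks)
      key <- paste0("bin=", b)
      pool <- names(pool_counts)[pool_bins == b]
    }
    if (is.null(strata[[key]])) strata[[key]] <- list(pool = pool, need = 0L)
    strata[[key]]$need <- strata[[key]]$need + need
  }
  # overlapping strata are sampled without replacement across the whole
  # pseudo-set, so require each stratum alone to be large enough and the
  # union to cover the total demand
  for (key in names(strata)) {
    if (length(strata[[key]]$pool) < strata[[key]]$need)
      stop("insufficient genes in profile-count stratum ", key,
           " (need ", strata[[key]]$need, ", have ",
           length(strata[[key]]$pool), ")")
  }
  strata[order(vapply(strata, function(s) length(s$pool), 0L))]
}

#' Structure-preserving permutation p-value for a gene set
#'
#' Assembles `n_rand` random pseudo-sets with the same number of genes and
#' the same per-gene profile counts as the observed set (drawing genes
#' without replacement within one randomization from genes with matching
#' profile counts; a count stratum falls back to its profile-count bin
#' when too few genes match exactly), reruns the enriched-pattern search
#' on each, and reports the fraction of randomizations whose statistic
#' reaches the observed one.
#'
#' @param set_genes character vector of member gene identifiers.
#' @param screen a [phenotype_screen].
#' @param policy a [similarity_policy].
#' @param n_rand number of randomizations (the operating default used for
#'   screens is 5000).
#' @param statistic `"profiles"` (default; compares the number of selected
#'   profiles) or `"genes"` (compares the covered gene count `n_T`).
#' @param rng_seed optional integer; when given, results are reproducible.
#' @param laplace if `TRUE`, report the (count + 1)/(n_rand + 1) estimator
#'   instead of the plain fraction (which can be exactly 0, reported with
#'   resolution `< 1/n_rand`).
#' @return an object of class `permutation_test`: `p_value`, `count`,
#'   `n_rand`, `statistic`, `observed`, `resolution`.
#' @export
permutation_pvalue <- function(set_genes, screen,
                               policy = similarity_policy(),
                               n_rand = 5000,
                               statistic = c("profiles", "genes"),
                               rng_seed = NULL, laplace = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(n_rand >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  Z <- .row_standardize(screen$values)
  gene_rows <- split(seq_along(screen$gene),
                     factor(screen$gene, levels = screen$genes))
  m <- profile_counts(screen)
  present <- intersect(set_genes, screen$genes)
  if (length(present) == 0L) stop("empty set after restriction to the screen")
  obs <- .pattern_search(unlist(gene_rows[present], use.names = FALSE),
                         screen, Z, policy)
  .perm_core(obs, m[present], screen, Z, gene_rows, m, policy, n_rand,
             statistic, laplace)
}

.perm_core <- function(obs, req_counts, screen, Z, gene_rows, pool_counts,
                       policy, n_rand, statistic, laplace) {
  obs_stat <- if (statistic == "profiles") obs$n_selected else obs$n_T
  strata <- .permutation_strata(req_counts, pool_counts)
  stats_rand <- integer(n_rand)
  for (i in seq_len(n_rand)) {
    chosen <- character(0)
    for (s in strata) {
      pool <- s$pool
      if (length(chosen)) pool <- pool[!pool %in% chosen]
      pick <- if (length(pool) == 1L) pool else sample(pool, s$need)
      chosen <- c(chosen, pick)
    }
    res <- .pattern_search(unlist(gene_rows[chosen], use.names = FALSE),
                           screen, Z, policy)
    stats_rand[i] <- if (statistic == "profiles") res$n_selected else res$n_T
  }
  count <- sum(stats_rand >= obs_stat)
  p <- if (laplace) (count + 1) / (n_rand + 1) else count / n_rand
  structure(list(p_value = p, count = count, n_rand = n_rand,
                 statistic = statistic, observed = obs_stat,
                 resolution = 1 / n_rand),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  ptxt <- if (x$count == 0L) sprintf("< %g", x$resolution) else format(x$p_value)
  cat(sprintf("permutation test: observed %s = %d, p %s (%d randomizations)\n",
              x$statistic, x$observed, ptxt, x$n_rand))
  invisible(x)
}

#' Gene-set analysis of a phenotype screen
#'
#' Runs the enriched-pattern search and its structure-preserving
#' permutation test on every gene set with phenotype data, producing per
#' set the enriched pattern, its reference profile (per-parameter median
#' of the selected profiles, sign-adjusted in absolute mode) and an
#' empirical p-value with a background specific to that set's size and
#' profiles-per-gene structure.
#'
#' @param sets a [gene_set_collection].
#' @param screen a z-normalized [phenotype_screen].
#' @param policy a [similarity_policy] (default: positive mode, T = 0.7).
#' @param n_rand randomizations per set (default 5000).
#' @param statistic comparison statistic, see [permutation_pvalue()].
#' @param rng_seed optional integer seed; identical seeds give identical
#'   p-values.
#' @param laplace see [permutation_pvalue()].
#' @return an object of class `enriched_sets`: a `results` data frame
#'   (set_id, n_g, n_p, n_selected_genes, n_selected_profiles, p_value)
#'   sorted by ascending p, plus per-set patterns and reference profiles.
#' @export
enriched_sets <- function(sets, screen, policy = similarity_policy(),
                          n_rand = 5000,
                          statistic = c("profiles", "genes"),
                          rng_seed = NULL, laplace = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(sets, "gene_set_collection"),
            inherits(screen, "phenotype_screen"))
  sets <- suppressMessages(restrict_to_screen(sets, screen))
  if (length(sets$sets) == 0L) stop("no gene set has phenotype data")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  Z <- .row_standardize(screen$values)
  gene_rows <- split(seq_along(screen$gene),
                     factor(screen$gene, levels = screen$genes))
  m <- profile_counts(screen)
  ids <- names(sets$sets)
  patterns <- vector("list", length(ids))
  refs <- matrix(NA_real_, length(ids), ncol(screen$values),
                 dimnames = list(ids, screen$parameter_names))
  rows_list <- lapply(sets$sets, function(gs)
    unlist(gene_rows[gs], use.names = FALSE))
  out <- data.frame(set_id = ids,
                    n_g = lengths(sets$sets),
                    n_p = lengths(rows_list),
                    n_selected_genes = NA_integer_,
                    n_selected_profiles = NA_integer_,
                    p_value = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(ids)) {
    obs <- .pattern_search(rows_list[[i]], screen, Z, policy)
    pt <- .perm_core(obs, m[sets$sets[[i]]], screen, Z, gene_rows, m,
                     policy, n_rand, statistic, laplace)
    pat <- .as_pattern(obs, screen)
    signs <- if (policy$mode == "absolute") sign(pat$selected$r) else NULL
    if (!is.null(signs)) signs[signs == 0] <- 1
    refs[i, ] <- reference_profile(
      screen$values[pat$selected$row, , drop = FALSE], signs)
    patterns[[i]] <- pat
    out$n_selected_genes[i] <- obs$n_T
    out$n_selected_profiles[i] <- obs$n_selected
    out$p_value[i] <- pt$p_value
  }
  ord <- order(out$p_value, out$set_id, method = "radix")
  structure(list(results = out[ord, , drop = FALSE],
                 patterns = stats::setNames(patterns, ids)[ord],
                 reference = refs[ord, , drop = FALSE],
                 sets = sets, policy = policy,
                 n_rand = n_rand, statistic = statistic),
            class = "enriched_sets")
}

#' @export
print.enriched_sets <- function(x, n = 6L, ...) {
  cat(sprintf("enriched_sets: %d sets analysed (T = %g, %s mode, %d randomizations)\n",
              nrow(x$results), x$policy$T, x$policy$mode, x$n_rand))
  print(utils::head(x$results, n), row.names = FALSE)
  if (nrow(x$results) > n) cat("  ...\n")
  invisible(x)
}

#' @export
summary.enriched_sets <- function(object, alpha = 0.05, ...) {
  r <- object$results
  list(n_sets = nrow(r),
       n_significant = sum(r$p_value <= alpha),
       alpha = alpha,
       min_p = min(r$p_value))
}

#' @export
as.data.frame.enriched_sets <- function(x, ...) x$results

#' @export
plot.enriched_sets <- function(x, ...) {
  graphics::hist(x$results$p_value, breaks = seq(0, 1, by = 0.05),
                 main = "Gene-set p-values", xlab = "permutation p-value",
                 col = "grey80", border = "white", ...)
  invisible(x)
}

#' Write gene-set results as TSV
#'
#' One row per set: set_id, n_g, n_p, n_selected_genes,
#' n_selected_profiles, p_value, followed by the N reference-profile
#' values.
#'
#' @param x an `enriched_sets` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_set_results <- function(x, path) {
  stopifnot(inherits(x, "enriched_sets"))
  df <- cbind(x$results, as.data.frame(x$reference, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene scores from set or module results
#'
#' Ranks genes by the p-values of the gene sets or network modules they
#' belong to: each gene's score is the minimum p-value over the sets or
#' modules containing it (ascending = better). Genes in no analysed set
#' or module are absent from the ranking.
#'
#' @param x an `enriched_sets` or `phenotype_modules` result.
#' @param ... unused.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
gene_scores <- function(x, ...) UseMethod("gene_scores")

#' @export
gene_scores.enriched_sets <- function(x, ...) {
  genes <- unlist(x$sets$sets[x$results$set_id], use.names = FALSE)
  p <- rep(x$results$p_value, lengths(x$sets$sets[x$results$set_id]))
  out <- tapply(p, genes, min)
  stats::setNames(as.numeric(out), names(out))
}
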