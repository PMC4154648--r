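# Network-module analysis: seed selection over node neighborhoods, greedy
# module expansion against a fixed consensus seed profile, profile-specific
# empirical backgrounds stratified by profiles-per-gene bins, and a
# semi-analytical module p-value that multiplies Poisson-binomial state
# probabilities over the expansion trajectory.

#' Parameters of the network-module search
#'
#' @param T expansion similarity threshold on the Pearson correlation to
#'   the fixed seed profile (operating default 0.7).
#' @param k minimal number of a gene's profiles that must be similar for
#'   the gene to join a module (default 3, the stringent setting; 2 is the
#'   discovery setting), or a fraction when `k_is_fraction = TRUE`.
#' @param k_is_fraction interpret `k` as the minimal fraction of a gene's
#'   profiles (ceiling of `k * m_i`, at least 1).
#' @param T_s seed-selection similarity threshold (default 0.8).
#' @param k_s minimal number of profiles a node needs to be tested as a
#'   seed (default 2).
#' @param max_steps expansion cap in states (default 50).
#' @param n_bin optional number of quantile bins for the profiles-per-gene
#'   strata; the default (`NULL`) uses one bin per exact profile count
#'   1..7 plus a pooled bin for 8 or more profiles, since genes with many
#'   profiles are rare.
#' @param n_rand_bg background draws per bin (default 1000, bounding the
#'   Monte-Carlo error of each background probability at about 0.016);
#'   `Inf` computes the exhaustive fraction over the bin instead.
#' @param mode similarity mode, `"absolute"` (default; anti-correlated
#'   profiles count, with per-gene sign orientation) or `"positive"`.
#' @param seed_rule when is a tested node kept as a seed:
#'   `"center-anchor"` (default) requires the winning anchor profile of
#'   the neighborhood's enriched pattern to belong to the tested node
#'   itself, so a seed always reflects similarity between the node and
#'   its neighbours; `"any-anchor"` keeps the node whenever the pattern
#'   selects at least one neighbor profile, wherever the anchor sits
#'   (more seeds, but a gene's own profiles can then anchor a neighbor's
#'   seed, which weakens randomization controls).
#' @param state_variant how a state probability is computed:
#'   `"pmf"` (default) is the Poisson-binomial probability of exactly the
#'   observed number of qualifying neighbors, which reduces to the
#'   homogeneous binomial mass when all background probabilities in a
#'   state are equal; `"config"` is the literal product over the observed
#'   per-neighbor outcome; `"tail"` is the Poisson-binomial probability of
#'   at least the observed number.
#' @return an object of class `module_params`.
#' @export
module_params <- function(T = 0.7, k = 3, k_is_fraction = FALSE,
                          T_s = 0.8, k_s = 2, max_steps = 50,
                          n_bin = NULL, n_rand_bg = 1000,
                          mode = c("absolute", "positive"),
                          seed_rule = c("center-anchor", "any-anchor"),
                          state_variant = c("pmf", "config", "tail")) {
  mode <- match.arg(mode)
  seed_rule <- match.arg(seed_rule)
  state_variant <- match.arg(state_variant)
  stopifnot(T > 0, T <= 1, T_s > 0, T_s <= 1, max_steps >= 1,
            k_s >= 1, n_rand_bg >= 1)
  if (k_is_fraction) {
    if (k <= 0 || k > 1) stop("fractional 'k' must be in (0, 1]")
  } else if (k < 1) stop("'k' must be at least 1")
  structure(list(T = T, k = k, k_is_fraction = k_is_fraction,
                 T_s = T_s, k_s = k_s, max_steps = max_steps,
                 n_bin = n_bin, n_rand_bg = n_rand_bg, mode = mode,
                 seed_rule = seed_rule, state_variant = state_variant),
            class = "module_params")
}

#' @export
print.module_params <- function(x, ...) {
  cat(sprintf("module_params: T = %g, k = %g%s, T_s = %g, k_s = %d, max_steps = %d, %s mode, state variant '%s'\n",
              x$T, x$k, if (x$k_is_fraction) " (fraction)" else "",
              x$T_s, x$k_s, x$max_steps, x$mode, x$state_variant))
  invisible(x)
}

.k_eff <- function(params, m) {
  if (params$k_is_fraction) pmax(1L, ceiling(params$k * m)) else
    rep(as.integer(params$k), length(m))
}

# profile-count bin of count m; default one bin per count 1..7 and a
# pooled ">=8" bin, otherwise explicit quantile breaks
.count_bin <- function(m, breaks = NULL) {
  out <- if (is.null(breaks)) pmin(as.integer(m), 8L)
         else findInterval(m, breaks, all.inside = TRUE)
  names(out) <- names(m)
  out
}

.count_breaks <- function(m, n_bin) {
  if (is.null(n_bin)) return(NULL)
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bin + 1),
                               type = 1))
  if (length(br) < 2L) br <- c(br, br + 1L)
  br
}

# correlation of one profile against every screen profile (vector length P)
.seed_correlations <- function(seed_profile, Z) {
  zs <- seed_profile - mean(seed_profile)
  n <- sqrt(sum(zs * zs))
  if (n < .Machine$double.eps^0.5) return(rep(NA_real_, nrow(Z)))
  r <- as.vector(Z %*% (zs / n))
  pmin(1, pmax(-1, r))
}

# Per-gene qualification against a fixed seed profile: resolves the sign
# orientation (profiles passing with mixed signs keep the orientation with
# the larger sum of |r|, ties positive; minority-sign profiles dropped) and
# requires at least k effective same-orientation passing profiles.
.gene_qualification <- function(r, screen, params, policy) {
  pass <- is_similar(r, policy)
  f <- factor(screen$gene, levels = screen$genes)
  pos <- pass & !is.na(r) & r > 0
  neg <- pass & !is.na(r) & r < 0
  ra <- abs(r)
  ra[is.na(ra)] <- 0
  sum_pos <- rowsum(ra * pos, f)[, 1]
  sum_neg <- rowsum(ra * neg, f)[, 1]
  n_pos <- rowsum(pos + 0L, f)[, 1]
  n_neg <- rowsum(neg + 0L, f)[, 1]
  orient <- ifelse(sum_neg > sum_pos, -1L, 1L)
  kept <- ifelse(orient > 0, n_pos, n_neg)
  m <- profile_counts(screen)
  qual <- kept >= .k_eff(params, m)
  keep_row <- (pos & orient[f] > 0) | (neg & orient[f] < 0)
  list(qual = stats::setNames(qual, screen$genes),
       orient = stats::setNames(orient, screen$genes),
       kept = stats::setNames(as.integer(kept), screen$genes),
       keep_row = keep_row, r = r)
}

#' Select module seeds
#'
#' Tests every network node with at least `k_s` profiles as a potential
#' seed: the node and its direct neighbors are treated as a gene set and
#' scanned with the enriched-pattern search at threshold `T_s` (absolute
#' similarity by default). The node becomes a seed when the neighborhood
#' holds an enriched pattern whose winning anchor belongs to the node
#' itself and at least one neighbor profile is selected (the anchor
#' condition is relaxed under `seed_rule = "any-anchor"`). The seed
#' profile is the per-parameter median of the selected
#' profiles after swapping anti-correlated ones; a neighbor with passing
#' profiles of both signs keeps the orientation maximizing the sum of
#' absolute correlations (ties positive), dropping the others.
#'
#' @param network an igraph network restricted to the screen.
#' @param screen a z-normalized [phenotype_screen].
#' @param params a [module_params].
#' @return list of `module_seed` objects (gene, profile, selected
#'   neighborhood profiles with signs), in ascending gene order.
#' @export
select_seeds <- function(network, screen, params = module_params()) {
  stopifnot(inherits(screen, "phenotype_screen"))
  Z <- .row_standardize(screen$values)
  adj <- .adjacency(network)
  .select_seeds_impl(adj, screen, params, Z)
}

.adjacency <- function(network) {
  nm <- igraph::V(network)$name
  if (is.null(nm)) stop("network vertices must be named with gene identifiers")
  al <- igraph::as_adj_list(network)
  stats::setNames(lapply(al, function(v) nm[as.integer(v)]), nm)
}

.select_seeds_impl <- function(adj, screen, params, Z) {
  policy <- similarity_policy(params$T_s, params$mode)
  m <- profile_counts(screen)
  gene_rows <- split(seq_along(screen$gene),
                     factor(screen$gene, levels = screen$genes))
  nodes <- sort(intersect(names(adj), screen$genes))
  nodes <- nodes[m[nodes] >= params$k_s]
  seeds <- list()
  for (node in nodes) {
    nbrs <- intersect(adj[[node]], screen$genes)
    if (length(nbrs) == 0L) next
    rows <- unlist(gene_rows[c(node, nbrs)], use.names = FALSE)
    res <- .pattern_search(rows, screen, Z, policy)
    if (params$seed_rule == "center-anchor" &&
        screen$gene[res$anchor] != node) next
    sel_gene <- screen$gene[res$selected]
    if (!any(sel_gene != node)) next
    sgn <- sign(res$r)
    sgn[sgn == 0] <- 1
    keep <- rep(TRUE, length(res$selected))
    for (g in unique(sel_gene)) {
      i <- which(sel_gene == g)
      s_pos <- sum(abs(res$r[i])[sgn[i] > 0])
      s_neg <- sum(abs(res$r[i])[sgn[i] < 0])
      if (s_pos > 0 && s_neg > 0) {
        o <- if (s_neg > s_pos) -1 else 1
        keep[i] <- sgn[i] == o
      }
    }
    rows_sel <- res$selected[keep]
    signs <- sgn[keep]
    if (!any(screen$gene[rows_sel] != node)) next
    prof <- reference_profile(screen$values[rows_sel, , drop = FALSE], signs)
    seeds[[node]] <- structure(
      list(gene = node, profile = prof,
           selected = data.frame(gene = screen$gene[rows_sel],
                                 oligo = screen$oligo[rows_sel],
                                 row = rows_sel, r = res$r[keep],
                                 sign = signs, stringsAsFactors = FALSE)),
      class = "module_seed")
  }
  seeds
}

#' @export
print.module_seed <- function(x, ...) {
  cat(sprintf("module_seed: %s (%d selected profile(s) from %d gene(s))\n",
              x$gene, nrow(x$selected), length(unique(x$selected$gene))))
  invisible(x)
}

#' Profile-specific background table
#'
#' Estimates, for each profiles-per-gene bin, the probability that a gene
#' drawn at random from that bin has at least `k` profiles similar to the
#' given seed profile. This corrects module assessment for phenotypic
#' patterns that are frequent in the screen and for variable oligo
#' numbers. Per bin, `n_rand_bg` genes are drawn uniformly with
#' replacement (the exhaustive fraction is used when `n_rand_bg = Inf`).
#' Empty bins get no estimate; lookups for such bins fall back to the
#' nearest non-empty bin.
#'
#' @param seed_profile numeric vector of length N (the fixed seed profile).
#' @param screen a z-normalized [phenotype_screen].
#' @param params a [module_params].
#' @param rng_seed optional integer seed for the draws.
#' @return an object of class `background_table`: data frame `table` with
#'   bin, n_genes, p_hat, n_draws, plus the bin definition.
#' @export
estimate_background <- function(seed_profile, screen,
                                params = module_params(), rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  Z <- .row_standardize(screen$values)
  .estimate_background_impl(seed_profile, screen, params, Z)
}

.estimate_background_impl <- function(seed_profile, screen, params, Z) {
  policy <- similarity_policy(params$T, params$mode)
  r <- .seed_correlations(seed_profile, Z)
  q <- .gene_qualification(r, screen, params, policy)
  m <- profile_counts(screen)
  breaks <- .count_breaks(m, params$n_bin)
  bin <- .count_bin(m, breaks)
  all_bins <- if (is.null(breaks)) 1:8 else seq_len(max(1, length(breaks) - 1))
  tab <- data.frame(bin = all_bins,
                    n_genes = as.integer(tabulate(bin, length(all_bins))),
                    p_hat = NA_real_,
                    n_draws = 0)
  for (b in all_bins) {
    genes_b <- names(m)[bin == b]
    if (length(genes_b) == 0L) next
    if (is.infinite(params$n_rand_bg)) {
      tab$p_hat[tab$bin == b] <- mean(q$qual[genes_b])
      tab$n_draws[tab$bin == b] <- Inf
    } else {
      draw <- sample(genes_b, params$n_rand_bg, replace = TRUE)
      tab$p_hat[tab$bin == b] <- mean(q$qual[draw])
      tab$n_draws[tab$bin == b] <- params$n_rand_bg
    }
  }
  # nearest non-empty bin fallback (ties -> lower bin)
  lookup <- tab$p_hat
  filled <- which(!is.na(lookup))
  if (length(filled) == 0L) stop("no non-empty profile-count bin")
  for (b in seq_along(lookup)) {
    if (is.na(lookup[b])) {
      nb <- filled[order(abs(filled - b), filled)][1L]
      lookup[b] <- tab$p_hat[nb]
    }
  }
  structure(list(table = tab, lookup = lookup, breaks = breaks,
                 n_rand_bg = params$n_rand_bg),
            class = "background_table")
}

#' @export
print.background_table <- function(x, ...) {
  cat("background_table:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# clamped background probability for a vector of bins; half a count away
# from 0/1 so Monte-Carlo zeros cannot zero out a module p-value
.bg_prob <- function(background, bins) {
  p <- background$lookup[bins]
  if (is.finite(background$n_rand_bg)) {
    eps <- 0.5 / background$n_rand_bg
    p <- pmin(1 - eps, pmax(eps, p))
  }
  p
}

#' Poisson-binomial distribution
#'
#' Mass and cumulative distribution of the number of successes among
#' independent Bernoulli trials with heterogeneous success probabilities,
#' computed by the dynamic-programming convolution. With all
#' probabilities equal this reduces exactly to the binomial distribution.
#'
#' @param k number of successes (scalar, `0 <= k <= length(prob)`).
#' @param prob vector of per-trial success probabilities.
#' @return `dpoisbinom`: P(X = k); `ppoisbinom`: P(X <= k).
#' @export
dpoisbinom <- function(k, prob) {
  .poisbinom_vec(prob)[k + 1L]
}

#' @rdname dpoisbinom
#' @export
ppoisbinom <- function(k, prob) {
  sum(.poisbinom_vec(prob)[seq_len(k + 1L)])
}

.poisbinom_vec <- function(prob) {
  if (any(is.na(prob)) || any(prob < 0) || any(prob > 1))
    stop("'prob' must be probabilities in [0, 1]")
  dp <- 1
  for (p in prob) dp <- c(dp * (1 - p), 0) + c(0, dp * p)
  dp
}

#' Binomial mass and cumulative distribution
#'
#' Thin domain-checked wrappers used by the homogeneous limit of the
#' state-probability engine.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p success probability in `[0, 1]`.
#' @return `binomial_pmf`: P(X = k); `binomial_cdf`: P(X <= k).
#' @export
binomial_pmf <- function(k, n, p) {
  if (k < 0 || k > n || p < 0 || p > 1) stop("binomial domain violation")
  stats::dbinom(k, n, p)
}

#' @rdname binomial_pmf
#' @export
binomial_cdf <- function(k, n, p) {
  if (k < 0 || k > n || p < 0 || p > 1) stop("binomial domain violation")
  stats::pbinom(k, n, p)
}

#' Probability of one expansion state
#'
#' An expansion state treats the current module's direct neighbors as
#' independent Bernoulli trials whose success probabilities come from the
#' profile-specific background of their profiles-per-gene bins.
#'
#' @param state a list or data frame with per-neighbor `bin` and `similar`
#'   entries (as recorded by [expand_module()]); `k_obs` defaults to the
#'   number of similar neighbors.
#' @param background a [estimate_background()] table for the seed profile.
#' @param variant `"pmf"` (default): Poisson-binomial P(X = k_obs);
#'   `"config"`: literal product over the observed assignment;
#'   `"tail"`: Poisson-binomial P(X >= k_obs).
#' @return probability in (0, 1].
#' @export
state_probability <- function(state, background,
                              variant = c("pmf", "config", "tail")) {
  variant <- match.arg(variant)
  if (length(state$bin) == 0L) return(1)
  p <- .bg_prob(background, state$bin)
  k_obs <- if (!is.null(state$k_obs)) state$k_obs else sum(state$similar)
  switch(variant,
         pmf = dpoisbinom(k_obs, p),
         config = prod(ifelse(state$similar, p, 1 - p)),
         tail = {
           dp <- .poisbinom_vec(p)
           sum(dp[(k_obs + 1L):length(dp)])
         })
}

#' Combine state probabilities into a module p-value
#'
#' The module p-value is the product of the per-state probabilities over
#' the whole expansion trajectory (states assumed independent under the
#' null), computed in log space to avoid underflow.
#'
#' @param state_probs numeric vector of state probabilities in (0, 1].
#' @return the product, in (0, 1].
#' @export
module_pvalue <- function(state_probs) {
  if (length(state_probs) == 0L) stop("no expansion states")
  if (any(state_probs <= 0 | state_probs > 1))
    stop("state probabilities must be in (0, 1]")
  exp(sum(log(state_probs)))
}

#' Expand a module around a seed
#'
#' Greedy growth against the fixed seed profile: at each state, every
#' non-member gene adjacent to the module qualifies if at least `k` of
#' its profiles are similar to the seed profile (with per-gene sign
#' orientation; minority-sign passing profiles are dropped) — all
#' qualifying neighbors join simultaneously. The seed profile is never
#' updated. Expansion halts when no neighbor qualifies or after
#' `max_steps` states; every assessed state is recorded with its
#' Bernoulli composition and probability, including a terminal state with
#' zero qualifiers.
#'
#' @param seed a `module_seed` from [select_seeds()].
#' @param network an igraph network restricted to the screen.
#' @param screen a z-normalized [phenotype_screen].
#' @param params a [module_params].
#' @param background a [estimate_background()] table for this seed's
#'   profile.
#' @return an object of class `module_result`.
#' @export
expand_module <- function(seed, network, screen, params = module_params(),
                          background) {
  Z <- .row_standardize(screen$values)
  .expand_module_impl(seed, .adjacency(network), screen, params, background, Z)
}

.expand_module_impl <- function(seed, adj, screen, params, background, Z) {
  policy <- similarity_policy(params$T, params$mode)
  r <- .seed_correlations(seed$profile, Z)
  q <- .gene_qualification(r, screen, params, policy)
  m <- profile_counts(screen)
  bin <- .count_bin(m, background$breaks)
  members <- seed$gene
  states <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    nbr <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
    nbr <- intersect(nbr, screen$genes)
    if (length(nbr) == 0L) break
    similar <- q$qual[nbr]
    k_obs <- sum(similar)
    states[[step]] <- list(step = step, gene = nbr, bin = unname(bin[nbr]),
                           similar = unname(similar), n = length(nbr),
                           k_obs = k_obs)
    if (k_obs == 0L || step >= params$max_steps) break
    members <- c(members, nbr[similar])
  }
  probs <- vapply(states, state_probability, 0, background = background,
                  variant = params$state_variant)
  for (i in seq_along(states)) states[[i]]$probability <- probs[i]
  p <- if (length(probs)) module_pvalue(probs) else 1
  member_df <- data.frame(gene = members,
                          sign = unname(q$orient[members]),
                          n_selected = unname(
                            as.integer(rowsum((q$keep_row) + 0L,
                              factor(screen$gene, levels = screen$genes))[members, 1])),
                          stringsAsFactors = FALSE, row.names = NULL)
  sel_rows <- which(q$keep_row & screen$gene %in% members)
  if (length(sel_rows) == 0L) sel_rows <- seed$selected$row
  sel_sign <- sign(r[sel_rows])
  sel_sign[sel_sign == 0 | is.na(sel_sign)] <- 1
  orient <- if (sum(sel_sign > 0) >= sum(sel_sign < 0)) 1 else -1
  reference <- orient * reference_profile(
    screen$values[sel_rows, , drop = FALSE], sel_sign)
  structure(list(seed = seed, members = member_df, states = states,
                 p_value = p, log10_p = sum(log10(probs)),
                 reference = reference,
                 selected = data.frame(gene = screen$gene[sel_rows],
                                       oligo = screen$oligo[sel_rows],
                                       row = sel_rows, r = r[sel_rows],
                                       stringsAsFactors = FALSE),
                 seed_only = nrow(member_df) == 1L),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module_result: seed %s, %d member(s), %d state(s), p = %.3g%s\n",
              x$seed$gene, nrow(x$members), length(x$states), x$p_value,
              if (x$seed_only) " [seed only]" else ""))
  invisible(x)
}

#' Network-module analysis of a phenotype screen
#'
#' Runs the full three-step module search: seed selection, greedy module
#' expansion against the fixed seed profiles, and semi-analytical module
#' assessment with profile-specific backgrounds. Seeds are enumerated in
#' ascending gene order; modules with identical member sets are
#' deduplicated keeping the smallest p-value; results are sorted by
#' ascending p. Reproducible under `rng_seed`.
#'
#' @param network an igraph network (restricted to the screen
#'   automatically).
#' @param screen a z-normalized [phenotype_screen].
#' @param params a [module_params].
#' @param rng_seed optional integer seed for the background draws.
#' @param seeds optional list of `module_seed` objects to use instead of
#'   running seed selection (e.g. seeds at genes of interest).
#' @return an object of class `phenotype_modules`: a `results` data frame
#'   (module_id, seed_gene, n_members, n_states, p_value, seed_only) plus
#'   the full per-module results.
#' @export
phenotype_modules <- function(network, screen, params = module_params(),
                              rng_seed = NULL, seeds = NULL) {
  stopifnot(inherits(screen, "phenotype_screen"),
            inherits(params, "module_params"))
  network <- suppressMessages(restrict_to_screen(network, screen))
  Z <- .row_standardize(screen$values)
  adj <- .adjacency(network)
  if (is.null(seeds)) seeds <- .select_seeds_impl(adj, screen, params, Z)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (length(seeds) == 0L) {
    message("phenotype_modules: no node passed seed selection")
    return(structure(list(results = data.frame(
      module_id = character(), seed_gene = character(),
      n_members = integer(), n_states = integer(),
      p_value = numeric(), seed_only = logical(),
      stringsAsFactors = FALSE),
      modules = list(), params = params, network = network),
      class = "phenotype_modules"))
  }
  seeds <- seeds[order(vapply(seeds, `[[`, "", "gene"), method = "radix")]
  mods <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    bg <- .estimate_background_impl(seeds[[i]]$profile, screen, params, Z)
    mods[[i]] <- .expand_module_impl(seeds[[i]], adj, screen, params, bg, Z)
  }
  key <- vapply(mods, function(mo)
    paste(sort(mo$members$gene), collapse = "\r"), "")
  p <- vapply(mods, `[[`, 0, "p_value")
  keep <- !logical(length(mods))
  for (k2 in unique(key[duplicated(key)])) {
    i <- which(key == k2)
    keep[i] <- FALSE
    keep[i[which.min(p[i])]] <- TRUE
  }
  mods <- mods[keep]
  p <- p[keep]
  ord <- order(p, vapply(mods, function(mo) mo$seed$gene, ""),
               method = "radix")
  mods <- mods[ord]
  res <- data.frame(
    module_id = sprintf("M%03d", seq_along(mods)),
    seed_gene = vapply(mods, function(mo) mo$seed$gene, ""),
    n_members = vapply(mods, function(mo) nrow(mo$members), 0L),
    n_states = vapply(mods, function(mo) length(mo$states), 0L),
    p_value = vapply(mods, `[[`, 0, "p_value"),
    seed_only = vapply(mods, `[[`, TRUE, "seed_only"),
    stringsAsFactors = FALSE)
  structure(list(results = res, modules = stats::setNames(mods, res$module_id),
                 params = params, network = network),
            class = "phenotype_modules")
}

#' @export
print.phenotype_modules <- function(x, n = 6L, ...) {
  cat(sprintf("phenotype_modules: %d module(s) (T = %g, k = %g, %s mode)\n",
              nrow(x$results), x$params$T, x$params$k, x$params$mode))
  print(utils::head(x$results, n), row.names = FALSE)
  if (nrow(x$results) > n) cat("  ...\n")
  invisible(x)
}

#' @export
summary.phenotype_modules <- function(object, alpha = 0.05, ...) {
  r <- object$results
  list(n_modules = nrow(r),
       n_significant = sum(r$p_value <= alpha),
       n_seed_only = sum(r$seed_only),
       genes_covered = length(unique(unlist(
         lapply(object$modules, function(mo) mo$members$gene)))),
       alpha = alpha)
}

#' @export
as.data.frame.phenotype_modules <- function(x, ...) x$results

#' @export
plot.phenotype_modules <- function(x, ...) {
  r <- x$results
  graphics::plot(r$n_members, -log10(pmax(r$p_value, 1e-300)),
                 xlab = "module size (genes)",
                 ylab = expression(-log[10] ~ "module p-value"),
                 pch = 19, col = "grey30", ...)
  invisible(x)
}

#' @param include_seed_only for module results: whether modules that never
#'   grew beyond their seed gene contribute to the ranking. Default
#'   `FALSE` — a seed-only module carries no network support, and letting
#'   it score its gene would rank genes by phenotype consistency alone.
#' @rdname gene_scores
#' @export
gene_scores.phenotype_modules <- function(x, include_seed_only = FALSE, ...) {
  keep <- if (include_seed_only) rep(TRUE, nrow(x$results)) else
    !x$results$seed_only
  if (!any(keep)) return(stats::setNames(numeric(), character()))
  mods <- x$modules[keep]
  genes <- unlist(lapply(mods, function(mo) mo$members$gene),
                  use.names = FALSE)
  p <- rep(x$results$p_value[keep],
           vapply(mods, function(mo) nrow(mo$members), 0L))
  out <- tapply(p, genes, min)
  stats::setNames(as.numeric(out), names(out))
}

#' Write module results as TSV
#'
#' One row per module: module_id, seed_gene, n_members, n_states,
#' p_value, the signed member list (`gene:+1|gene:-1`), then the N
#' reference-profile values.
#'
#' @param x a `phenotype_modules` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_results <- function(x, path) {
  stopifnot(inherits(x, "phenotype_modules"))
  members <- vapply(x$modules, function(mo)
    paste(sprintf("%s:%+d", mo$members$gene, mo$members$sign),
          collapse = "|"), "")
  refs <- t(vapply(x$modules, `[[`, x$modules[[1]]$reference, "reference"))
  df <- cbind(x$results, members = members,
              as.data.frame(refs, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export module sub-networks as SIF
#'
#' Writes the edges induced by each module's members, using the module id
#' as the SIF relation, for loading into network viewers.
#'
#' @param x a `phenotype_modules` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_sif <- function(x, path) {
  stopifnot(inherits(x, "phenotype_modules"))
  lines <- character()
  for (id in names(x$modules)) {
    g <- igraph::induced_subgraph(x$network, x$modules[[id]]$members$gene)
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el))
      lines <- c(lines, paste(el[, 1], id, el[, 2], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
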