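# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles deliberately use plain loops / stats::cor and never
# call the implementation paths they check.

# a vector with exact Pearson correlation `r` to `base`, built from `noise`
# by Gram-Schmidt
profile_with_cor <- function(base, r, noise) {
  zb <- base - mean(base)
  zb <- zb / sqrt(sum(zb^2))
  n0 <- noise - mean(noise)
  n0 <- n0 - sum(n0 * zb) * zb
  n0 <- n0 / sqrt(sum(n0^2))
  v <- r * zb + sqrt(1 - r^2) * n0
  v - mean(v)
}

# screen from a list of (gene -> matrix of profiles)
screen_from_list <- function(lst, oligo = NULL) {
  vals <- do.call(rbind, lst)
  gene <- rep(names(lst), vapply(lst, nrow, 0L))
  phenotype_screen(vals, gene, oligo)
}

# brute-force enriched-pattern search: anchor loop with stats::cor
oracle_pattern <- function(set_genes, screen, T, mode = "positive") {
  rows <- which(screen$gene %in% set_genes)
  v <- screen$values
  best <- NULL
  for (a in rows) {
    r <- vapply(rows, function(j) {
      if (j == a) return(1)
      if (stats::sd(v[a, ]) == 0 || stats::sd(v[j, ]) == 0) return(NA_real_)
      stats::cor(v[a, ], v[j, ])
    }, 0)
    sim <- if (mode == "positive") !is.na(r) & r >= T else !is.na(r) & abs(r) >= T
    sim[rows == a] <- TRUE
    n_T <- length(unique(screen$gene[rows[sim]]))
    sum_r <- sum(if (mode == "positive") r[sim] else abs(r[sim]))
    cand <- list(anchor = a, n_T = n_T, sum_r = sum_r,
                 selected = rows[sim],
                 key = c(screen$gene[a], screen$oligo[a]))
    if (is.null(best) ||
        n_T > best$n_T ||
        (n_T == best$n_T && sum_r > best$sum_r + 1e-12) ||
        (n_T == best$n_T && abs(sum_r - best$sum_r) <= 1e-12 &&
         (cand$key[1] < best$key[1] ||
          (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
      best <- cand
  }
  best
}

# exhaustive Poisson-binomial mass by enumerating all 2^n outcomes
oracle_poisbinom <- function(k, p) {
  n <- length(p)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) == k)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# tie-corrected Mann-Whitney AUC (probability a positive scores lower)
oracle_auc <- function(scores, positives, negatives) {
  sp <- scores[positives]
  sn <- scores[negatives]
  w <- suppressWarnings(stats::wilcox.test(sn, sp))
  unname(w$statistic) / (length(sp) * length(sn))
}

# exhaustive structure-preserving pseudo-set enumeration: all ways to pick
# genes matching the per-count structure from the pool, exact p-value
oracle_perm_exact <- function(set_genes, screen, T, statistic = "profiles") {
  m <- profile_counts(screen)
  req <- table(m[intersect(set_genes, screen$genes)])
  pools <- lapply(names(req), function(cs)
    names(m)[m == as.integer(cs)])
  combos <- lapply(seq_along(pools), function(i)
    utils::combn(pools[[i]], req[[i]], simplify = FALSE))
  grid <- combos[[1]]
  if (length(combos) > 1) {
    for (i in 2:length(combos)) {
      grid <- unlist(lapply(grid, function(g)
        lapply(combos[[i]], function(h) c(g, h))), recursive = FALSE)
    }
  }
  stat_of <- function(genes) {
    pat <- oracle_pattern(genes, screen, T)
    if (statistic == "profiles") length(pat$selected) else pat$n_T
  }
  obs <- stat_of(set_genes)
  stats_rand <- vapply(grid, stat_of, 0)
  list(p = mean(stats_rand >= obs), obs = obs, n = length(grid))
}

# small planted-module study shared by several tests
planted_study <- function(n_genes = 120, n_modules = 2, module_size = 6,
                          ote_rate = 0.3, within_noise_sd = 0.1,
                          rng_seed = 42, network_model = "erdos-renyi",
                          gnp_p = 0.05, ...) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted <- lapply(seq_len(n_modules), function(i)
    list(genes = genes[((i - 1) * module_size + 1):(i * module_size)],
         archetype = i))
  cfg <- simulation_config(n_genes = n_genes, network_model = network_model,
                           gnp_p = gnp_p, planted_modules = planted,
                           ote_rate = ote_rate,
                           within_noise_sd = within_noise_sd,
                           rng_seed = rng_seed, ...)
  net <- generate_network(cfg)
  sim <- generate_screen(net, cfg)
  list(config = cfg, network = net, screen = sim$screen, truth = sim$truth,
       planted_genes = unlist(lapply(planted, `[[`, "genes")),
       planted = planted,
       null_genes = setdiff(genes, unlist(lapply(planted, `[[`, "genes"))))
}

# ranking over all simulated genes: min module p, 1 for uncovered genes
module_ranking <- function(mods, all_genes) {
  scores <- stats::setNames(rep(1, length(all_genes)), all_genes)
  gs <- gene_scores(mods)
  scores[names(gs)] <- pmin(scores[names(gs)], gs)
  scores
}
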