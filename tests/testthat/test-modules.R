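test_that("binomial wrappers evaluate the closed form with domain checks", {
  expect_equal(binomial_pmf(2, 3, 0.5), 0.375)
  expect_equal(binomial_pmf(0, 7, 0), 1)
  expect_equal(binomial_cdf(7, 7, 0.3), 1)
  expect_equal(sum(vapply(0:7, binomial_pmf, 0, n = 7, p = 0.3)), 1,
               tolerance = 1e-12)
  expect_error(binomial_pmf(4, 3, 0.5), "domain")
  expect_error(binomial_cdf(1, 3, 1.5), "domain")
})

test_that("Poisson-binomial engine matches enumeration and binomial limit", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    p <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(dpoisbinom(k, p), oracle_poisbinom(k, p),
                 tolerance = 1e-12)
    expect_equal(ppoisbinom(k, p),
                 sum(vapply(0:k, oracle_poisbinom, 0, p = p)),
                 tolerance = 1e-12)
  }
  # homogeneous case reduces exactly to the binomial mass
  for (k in 0:6)
    expect_equal(dpoisbinom(k, rep(0.3, 6)), dbinom(k, 6, 0.3),
                 tolerance = 1e-14)
  expect_error(dpoisbinom(1, c(0.5, 1.2)), "probabilities")
})

test_that("state probabilities cover the documented variants", {
  bg <- structure(list(table = data.frame(bin = 1:8, n_genes = 1,
                                          p_hat = NA, n_draws = Inf),
                       lookup = rep(0.5, 8), breaks = NULL,
                       n_rand_bg = Inf),
                  class = "background_table")
  st <- list(bin = c(1, 1, 1), similar = c(TRUE, TRUE, FALSE), k_obs = 2)
  expect_equal(state_probability(st, bg, "pmf"), 0.375)
  expect_equal(state_probability(st, bg, "config"), 0.125)
  expect_equal(state_probability(st, bg, "tail"), 0.5)

  bg$lookup <- c(0.5, 0.1, rep(0.5, 6))
  st2 <- list(bin = c(1, 2), similar = c(TRUE, FALSE), k_obs = 1)
  expect_equal(state_probability(st2, bg, "pmf"), 0.5 * 0.9 + 0.5 * 0.1)

  bg$lookup <- rep(1, 8)
  st3 <- list(bin = c(1, 2, 3), similar = rep(TRUE, 3), k_obs = 3)
  for (v in c("pmf", "config", "tail"))
    expect_equal(state_probability(st3, bg, v), 1)
  # empty neighbor set carries probability one
  expect_equal(state_probability(list(bin = integer(), similar = logical()),
                                 bg), 1)
})

test_that("module p-values multiply state probabilities in log space", {
  expect_equal(module_pvalue(c(0.375, 0.2)), 0.075)
  expect_equal(module_pvalue(1), 1)
  expect_equal(module_pvalue(rep(0.9, 50)), exp(50 * log(0.9)),
               tolerance = 1e-12)
  expect_equal(module_pvalue(rep(1e-12, 100)), exp(100 * log(1e-12)))
  expect_error(module_pvalue(numeric()), "no expansion states")
  expect_error(module_pvalue(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("seed selection requires a centre anchor and neighbor support", {
  set.seed(24)
  base <- rnorm(24)
  shared <- function(r) profile_with_cor(base, r, rnorm(24))
  # star: centre plus two leaves sharing the same shape, 2 profiles each;
  # the centre carries the cleanest copies so its anchor wins the tie-break
  lst <- list(hub = rbind(shared(0.998), shared(0.995)),
              l1 = rbind(shared(0.9), shared(0.1)),
              l2 = rbind(shared(0.88), shared(-0.05)))
  sc <- screen_from_list(lst)
  net <- igraph::graph_from_edgelist(rbind(c("hub", "l1"), c("hub", "l2")),
                                     directed = FALSE)
  seeds <- select_seeds(net, sc, module_params())
  expect_true("hub" %in% names(seeds))
  sp <- seeds[["hub"]]$profile
  expect_gt(cor(sp, base), 0.9)
  expect_true(any(seeds[["hub"]]$selected$gene != "hub"))

  # a node with a single profile is never a seed candidate at k_s = 2
  lst2 <- lst
  lst2$hub <- lst2$hub[1, , drop = FALSE]
  sc2 <- screen_from_list(lst2)
  seeds2 <- select_seeds(net, sc2, module_params())
  expect_false("hub" %in% names(seeds2))

  # neighbors below the seed threshold yield no seed
  lst3 <- list(hub = rbind(shared(0.97), shared(0.95)),
               l1 = rbind(profile_with_cor(base, 0.2, rnorm(24)),
                          profile_with_cor(base, 0.1, rnorm(24))),
               l2 = rbind(profile_with_cor(base, 0, rnorm(24)),
                          profile_with_cor(base, -0.1, rnorm(24))))
  sc3 <- screen_from_list(lst3)
  seeds3 <- select_seeds(net, sc3, module_params())
  expect_false("hub" %in% names(seeds3))
})

test_that("background estimation matches exhaustive qualification", {
  set.seed(25)
  base <- rnorm(30)
  # 20 genes with 2 profiles each; exactly 6 genes (30%) qualify at k = 2
  lst <- lapply(1:20, function(i) {
    r <- if (i <= 6) c(0.95, 0.9) else c(0.2, 0.1)
    rbind(profile_with_cor(base, r[1], rnorm(30)),
          profile_with_cor(base, r[2], rnorm(30)))
  })
  names(lst) <- sprintf("G%02d", 1:20)
  sc <- screen_from_list(lst)
  params <- module_params(T = 0.7, k = 2)
  bg <- estimate_background(base, sc, params, rng_seed = 31)
  expect_lt(abs(bg$table$p_hat[bg$table$bin == 2] - 0.3),
            3 * sqrt(0.3 * 0.7 / 1000))
  # exhaustive option reproduces the exact fraction
  bg_ex <- estimate_background(base, sc,
                               module_params(T = 0.7, k = 2, n_rand_bg = Inf))
  expect_equal(bg_ex$table$p_hat[bg_ex$table$bin == 2], 0.3)
  # saturation: with a tiny threshold every gene qualifies
  bg_sat <- estimate_background(base, sc,
                                module_params(T = 1e-6, k = 1, n_rand_bg = Inf))
  expect_equal(bg_sat$table$p_hat[bg_sat$table$bin == 2], 1)
  # a seed orthogonal to every profile qualifies nothing
  orth <- profile_with_cor(base, 0, rnorm(30))
  lst_orth <- lapply(1:10, function(i)
    rbind(profile_with_cor(orth, 0, rnorm(30)),
          profile_with_cor(orth, 0, rnorm(30))))
  names(lst_orth) <- sprintf("H%02d", 1:10)
  sc_orth <- screen_from_list(lst_orth)
  bg0 <- estimate_background(orth, sc_orth,
                             module_params(T = 0.2, k = 1, n_rand_bg = Inf))
  expect_equal(bg0$table$p_hat[bg0$table$bin == 2], 0)
  # empty bins fall back to the nearest non-empty bin in lookups
  expect_equal(bg_ex$lookup[5], bg_ex$table$p_hat[bg_ex$table$bin == 2])
})

test_that("module expansion recovers a planted clique and stops correctly", {
  set.seed(26)
  base <- rnorm(30)
  mk <- function(r1, r2) rbind(profile_with_cor(base, r1, rnorm(30)),
                               profile_with_cor(base, r2, rnorm(30)))
  lst <- list(c1 = mk(0.97, 0.95), c2 = mk(0.96, 0.9), c3 = mk(0.93, 0.92),
              c4 = mk(0.91, 0.9), c5 = mk(0.95, 0.89),
              n1 = mk(0.1, 0.05), n2 = mk(-0.1, 0.2), n3 = mk(0, 0.1))
  sc <- screen_from_list(lst)
  clique <- t(combn(paste0("c", 1:5), 2))
  extra <- rbind(c("c1", "n1"), c("c3", "n2"), c("n2", "n3"))
  net <- igraph::graph_from_edgelist(rbind(clique, extra), directed = FALSE)
  params <- module_params(T = 0.7, k = 2, n_rand_bg = Inf)
  seeds <- select_seeds(net, sc, params)
  expect_gt(length(seeds), 0)
  s <- seeds[[1]]
  bg <- estimate_background(s$profile, sc, params)
  mod <- expand_module(s, net, sc, params, bg)
  expect_setequal(mod$members$gene, paste0("c", 1:5))
  expect_lte(length(mod$states), 3)
  # every non-seed member qualified by the per-neighbor oracle
  r_seed <- vapply(seq_len(nrow(sc$values)), function(i)
    cor(s$profile, sc$values[i, ]), 0)
  for (g in setdiff(mod$members$gene, s$gene)) {
    rows <- which(sc$gene == g)
    expect_gte(sum(abs(r_seed[rows]) >= 0.7), 2)
  }
  # modules never leave the network, and p is in (0, 1]
  expect_true(all(mod$members$gene %in% igraph::V(net)$name))
  expect_gt(mod$p_value, 0)
  expect_lte(mod$p_value, 1)

  # seed whose neighbors all fail: one recorded state, zero qualifiers
  lone <- list(a = mk(0.97, 0.96), b = mk(0, 0.05), d = mk(0.1, -0.1))
  sc2 <- screen_from_list(lone)
  net2 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("a", "d")),
                                      directed = FALSE)
  s2 <- structure(list(gene = "a",
                       profile = reference_profile(lone$a),
                       selected = data.frame(gene = "a", oligo = "o",
                                             row = 1L, r = 1, sign = 1)),
                  class = "module_seed")
  bg2 <- estimate_background(s2$profile, sc2,
                             module_params(T = 0.7, k = 2, n_rand_bg = Inf))
  mod2 <- expand_module(s2, net2, sc2,
                        module_params(T = 0.7, k = 2, n_rand_bg = Inf), bg2)
  expect_equal(nrow(mod2$members), 1L)
  expect_true(mod2$seed_only)
  expect_equal(length(mod2$states), 1L)
  expect_equal(mod2$states[[1]]$k_obs, 0L)
  expect_equal(mod2$states[[1]]$n, 2L)
})

test_that("mixed-sign genes join with the dominant orientation only", {
  set.seed(27)
  base <- rnorm(30)
  pw <- function(r) profile_with_cor(base, r, rnorm(30))
  # neighbor with 2 strongly positive and 2 strongly negative profiles;
  # the negative pair has the larger summed |r|
  lst <- list(seed = rbind(pw(0.98), pw(0.97)),
              mix = rbind(pw(0.85), pw(0.86), pw(-0.95), pw(-0.96)))
  sc <- screen_from_list(lst)
  net <- igraph::graph_from_edgelist(rbind(c("seed", "mix")),
                                     directed = FALSE)
  params <- module_params(T = 0.7, k = 2, n_rand_bg = Inf)
  s <- structure(list(gene = "seed", profile = reference_profile(lst$seed),
                      selected = data.frame(gene = "seed", oligo = "o",
                                            row = 1L, r = 1, sign = 1)),
                 class = "module_seed")
  bg <- estimate_background(s$profile, sc, params)
  mod <- expand_module(s, net, sc, params, bg)
  mem <- mod$members[mod$members$gene == "mix", ]
  expect_equal(nrow(mem), 1L)
  expect_equal(mem$sign, -1L)
  expect_equal(mem$n_selected, 2L)
  sel <- mod$selected[mod$selected$gene == "mix", ]
  expect_true(all(sel$r < 0))

  # enumeration cross-check: the chosen orientation maximizes sum(|r|)
  r_mix <- vapply(3:6, function(i) cor(s$profile, sc$values[i, ]), 0)
  pass <- abs(r_mix) >= 0.7
  expect_gt(sum(abs(r_mix)[pass & r_mix < 0]), sum(abs(r_mix)[pass & r_mix > 0]))
})

test_that("full module run is deterministic, deduplicated and sign-invariant", {
  study <- planted_study(rng_seed = 42)
  params <- module_params()
  m1 <- phenotype_modules(study$network, study$screen, params, rng_seed = 7)
  m2 <- phenotype_modules(study$network, study$screen, params, rng_seed = 7)
  expect_identical(m1$results, m2$results)
  expect_false(any(duplicated(vapply(m1$modules, function(mo)
    paste(sort(mo$members$gene), collapse = "|"), ""))))
  expect_true(all(m1$results$p_value > 0 & m1$results$p_value <= 1))

  # flipping all profiles of one member gene flips orientation only
  flip_gene <- m1$modules[[1]]$members$gene[2]
  sc_flip <- study$screen
  rows <- which(sc_flip$gene == flip_gene)
  sc_flip$values[rows, ] <- -sc_flip$values[rows, ]
  m3 <- phenotype_modules(study$network, sc_flip, params, rng_seed = 7)
  expect_equal(m1$results$p_value, m3$results$p_value, tolerance = 1e-12)
  mem1 <- m1$modules[[1]]$members
  mem3 <- m3$modules[[1]]$members
  expect_setequal(mem1$gene, mem3$gene)
  s1 <- mem1$sign[match(flip_gene, mem1$gene)]
  s3 <- mem3$sign[match(flip_gene, mem3$gene)]
  expect_equal(s3, -s1)
})

test_that("planted modules score best and k relaxation is monotone", {
  study <- planted_study(rng_seed = 314)
  params3 <- module_params(k = 3)
  params2 <- module_params(k = 2)
  m3 <- phenotype_modules(study$network, study$screen, params3, rng_seed = 1)
  top <- m3$modules[[1]]$members$gene
  expect_gt(mean(top %in% study$planted_genes), 0.5)
  # per fixed seed, lowering k never loses a member
  m2 <- phenotype_modules(study$network, study$screen, params2, rng_seed = 1)
  seeds3 <- vapply(m3$modules, function(mo) mo$seed$gene, "")
  seeds2 <- vapply(m2$modules, function(mo) mo$seed$gene, "")
  shared <- intersect(seeds3, seeds2)
  expect_gt(length(shared), 0)
  for (sg in shared) {
    g3 <- m3$modules[[which(seeds3 == sg)[1]]]$members$gene
    g2 <- m2$modules[[which(seeds2 == sg)[1]]]$members$gene
    expect_true(all(g3 %in% g2))
  }
  # empty seed list produces an empty, well-formed result
  null_study <- planted_study(n_genes = 40, n_modules = 0, rng_seed = 8)
  expect_message(
    m0 <- phenotype_modules(null_study$network, null_study$screen,
                            module_params(), rng_seed = 1),
    "no node passed")
  expect_equal(nrow(m0$results), 0L)
  expect_equal(length(gene_scores(m0)), 0L)
})

test_that("module results export to TSV and SIF", {
  study <- planted_study(rng_seed = 42)
  m <- phenotype_modules(study$network, study$screen, module_params(),
                         rng_seed = 7)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_module_results(m, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(m$results))
  expect_true(all(c("module_id", "seed_gene", "p_value", "members") %in%
                    names(tab)))
  write_module_sif(m, sif)
  g <- read_network(sif, format = "sif")
  expect_true(all(igraph::V(g)$name %in%
                    unlist(lapply(m$modules, function(mo) mo$members$gene))))
})
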