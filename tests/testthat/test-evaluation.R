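test_that("curves handle perfect, tied and balanced rankings", {
  scores <- setNames(c(0.01, 0.02, 0.03, 0.8, 0.9, 0.95), letters[1:6])
  ev <- roc_pr_bacc(scores, letters[1:3], letters[4:6])
  expect_equal(ev$auc, 1)
  expect_equal(max(ev$bacc$bacc), 1)
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(ev$roc$tpr[1], 0)
  expect_equal(ev$roc$fpr[nrow(ev$roc)], 1)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)

  tied <- setNames(rep(0.5, 10), letters[1:10])
  expect_equal(roc_pr_bacc(tied, letters[1:5], letters[6:10])$auc, 0.5)

  # balanced classes: BACC equals plain accuracy at every threshold
  set.seed(31)
  s <- setNames(runif(20), paste0("g", 1:20))
  pos <- paste0("g", 1:10)
  neg <- paste0("g", 11:20)
  ev2 <- roc_pr_bacc(s, pos, neg)
  acc <- vapply(ev2$bacc$threshold, function(t) {
    pred <- s <= t
    mean(pred == (names(s) %in% pos))
  }, 0)
  expect_equal(ev2$bacc$bacc, acc, tolerance = 1e-12)
  expect_error(roc_pr_bacc(s, pos, character()), "at least one")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  expect_equal(auc_trapezoid(c(0, 0, 1), c(0, 1, 1)), 1)
  expect_equal(auc_trapezoid(c(0, 1), c(0, 1)), 0.5)
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- setNames(round(runif(n), sample(1:3, 1)), paste0("g", 1:n))
    pos <- paste0("g", 1:floor(n / 3))
    neg <- setdiff(names(scores), pos)
    ev <- roc_pr_bacc(scores, pos, neg)
    expect_equal(ev$auc, oracle_auc(scores, pos, neg), tolerance = 1e-10)
  }
  # independent implementation cross-check on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(33)
    scores <- setNames(runif(50), paste0("g", 1:50))
    pos <- paste0("g", 1:20)
    neg <- paste0("g", 21:50)
    ev <- roc_pr_bacc(scores, pos, neg)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = names(scores) %in% pos, predictor = -scores,
      quiet = TRUE, direction = "<")))
    expect_equal(ev$auc, proc_auc, tolerance = 1e-10)
  }
})

test_that("rankings are invariant under monotone score transforms", {
  set.seed(34)
  scores <- setNames(runif(30), paste0("g", 1:30))
  pos <- paste0("g", 1:12)
  neg <- setdiff(names(scores), pos)
  a0 <- roc_pr_bacc(scores, pos, neg)$auc
  for (f in list(function(x) x^3, function(x) plogis(5 * x)))
    expect_equal(roc_pr_bacc(f(scores), pos, neg)$auc, a0,
                 tolerance = 1e-12)
})

test_that("Hanley-McNeil sem and the z-test behave at the reference points", {
  expect_lt(abs(hanley_sem(0.5, 10, 10) - 0.13229), 1e-5)
  expect_equal(hanley_sem(1, 25, 40), 0)
  expect_equal(auc_ztest(1, 0), 0)
  expect_equal(auc_ztest(0.5, hanley_sem(0.5, 10, 10)), 0.5)
  expect_lt(auc_ztest(0.9, hanley_sem(0.9, 50, 50)), 1e-6)
})

test_that("bootstrap AUC comparison separates rankings and guards ties", {
  set.seed(35)
  genes <- paste0("g", 1:200)
  pos <- genes[1:60]
  neg <- genes[61:200]
  strong <- setNames(ifelse(genes %in% pos, runif(200, 0, 0.3),
                            runif(200, 0.2, 1)), genes)
  random <- setNames(runif(200), genes)
  cmp <- bootstrap_auc_compare(strong, random, pos, neg, n_boot = 400,
                               rng_seed = 9)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$auc1, cmp$auc2)
  same <- bootstrap_auc_compare(strong, strong, pos, neg, n_boot = 100,
                                rng_seed = 9)
  expect_equal(same$p_value, 1)
  cmp2 <- bootstrap_auc_compare(strong, random, pos, neg, n_boot = 400,
                                rng_seed = 9)
  expect_identical(cmp$p_value, cmp2$p_value)
})

test_that("randomization controls preserve the documented invariants", {
  study <- planted_study(rng_seed = 99)
  net <- study$network
  sc <- study$screen
  # edges: exact degree sequence, no loops or multi-edges
  sh <- shuffle_network(net, sc, "edges", rng_seed = 1)
  expect_equal(sort(igraph::degree(sh$network)),
               sort(igraph::degree(net)))
  expect_true(igraph::is_simple(sh$network))
  expect_identical(sh$screen$values, sc$values)
  # genes: topology untouched, only labels permuted; bundles intact
  sh2 <- shuffle_network(net, sc, "genes", rng_seed = 2)
  expect_equal(igraph::ecount(sh2$network), igraph::ecount(net))
  expect_setequal(igraph::V(sh2$network)$name, igraph::V(net)$name)
  expect_identical(sh2$screen$values, sc$values)
  # profiles: per-gene bundles move between genes of identical counts,
  # the global bundle multiset is preserved
  sh3 <- shuffle_network(net, sc, "profiles", rng_seed = 3)
  expect_equal(sort(unname(profile_counts(sh3$screen))),
               sort(unname(profile_counts(sc))))
  bundle_of <- function(s) {
    idx <- split(seq_along(s$gene), s$gene)
    sort(vapply(idx, function(i)
      paste(signif(as.vector(s$values[i, , drop = FALSE]), 10),
            collapse = ","), ""))
  }
  expect_identical(unname(bundle_of(sh3$screen)), unname(bundle_of(sc)))
  expect_false(identical(sh3$screen$values, sc$values))
})

test_that("added noise has the requested variance and is reproducible", {
  study <- planted_study(n_genes = 50, n_modules = 0, rng_seed = 12)
  sc <- study$screen
  expect_identical(add_noise(sc, 0)$values, sc$values)
  n1 <- add_noise(sc, 0.2, rng_seed = 5)
  n2 <- add_noise(sc, 0.2, rng_seed = 5)
  expect_identical(n1$values, n2$values)
  delta <- as.vector(n1$values - sc$values)
  expect_gt(length(delta), 1e4)
  se <- sqrt(2 / (length(delta) - 1)) * 0.04
  expect_lt(abs(var(delta) - 0.04), 3 * se)
  expect_lt(abs(mean(delta)), 3 * 0.2 / sqrt(length(delta)))
})

test_that("profile agreement separates matched from unrelated groups", {
  set.seed(36)
  base <- rnorm(40)
  matched <- t(vapply(1:8, function(i)
    profile_with_cor(base, 0.9, rnorm(40)), numeric(40)))
  fresh <- t(vapply(1:6, function(i)
    profile_with_cor(base, 0.85, rnorm(40)), numeric(40)))
  unrelated <- matrix(rnorm(6 * 40), 6)
  r_same <- profile_agreement(matched, matched)
  expect_gt(min(r_same), 0.5)
  r_sel <- profile_agreement(matched, fresh)
  r_rej <- profile_agreement(unrelated, fresh)
  expect_lt(mean(abs(r_rej)), 0.25)
  tests <- agreement_tests(r_sel, r_rej)
  expect_lt(tests$ks_p, 0.01)
  expect_lt(tests$mw_p, 0.01)
  null_tests <- agreement_tests(rnorm(100), rnorm(100))
  expect_gt(null_tests$ks_p, 0.001)
})

test_that("phenotype-map coordinates are channel norms", {
  ref <- c(0, 0, 0, 2, 0, 0)
  xy <- phenotype_map_coords(ref, 1:3, 4:6)
  expect_equal(xy$x, 2)
  expect_equal(xy$y, 2)
  expect_equal(unlist(phenotype_map_coords(rep(0, 6), 1:3, 4:6)),
               c(x = 0, y = 0))
  ref2 <- c(3, 0, 0, 0, 4, 0, 0, 0)
  xy2 <- phenotype_map_coords(ref2, 1:4, 5:8)
  expect_equal(xy2$x, 1)
  expect_equal(xy2$y, 7)
  # matrix input vectorizes by row
  m <- rbind(ref2, ref2)
  expect_equal(phenotype_map_coords(m, 1:4, 5:8)$x, c(1, 1))
  expect_error(phenotype_map_coords(ref2, 1:4, 4:8), "disjoint")
})

test_that("chi-square baseline scores phenotype strength", {
  set.seed(37)
  # gene with zero collapsed profile gets p = 1
  sc <- phenotype_screen(rbind(rep(0, 40), rnorm(40) * 2),
                         c("null", "strong"))
  p <- chi_square_baseline(sc, "average")
  expect_equal(unname(p["null"]), 1)
  expect_lt(p["strong"], p["null"])
  # planted genes outrank null genes on a simulated screen
  study <- planted_study(rng_seed = 21, ote_rate = 0.1,
                         within_noise_sd = 0.05)
  pv <- chi_square_baseline(study$screen, "average")
  ev <- roc_pr_bacc(pv, study$planted_genes, study$null_genes)
  expect_gt(ev$auc, 0.8)
})
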