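# Synthetic screens with known ground truth. The generator emulates the
# structure of a large image-based RNAi screen: ~40 z-normalized phenotype
# parameters, on average ~7 oligos per gene with variable counts, and
# off-target-contaminated replicate profiles drawn from a shared pool of
# archetypal phenotype shapes (so that frequent patterns exist and the
# profile-specific background correction is exercised).

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param n_params number of phenotype parameters (default 40).
#' @param oligo_lambda oligos per gene are `1 + Poisson(oligo_lambda)`;
#'   the default 6 gives on average 7 oligos per gene with minimum 1.
#' @param n_archetypes number of distinct true profile shapes in the pool
#'   (default 8); archetypes are random unit-norm vectors kept pairwise
#'   dissimilar (|r| < 0.3) by rejection sampling.
#' @param archetype_skew optional probability weights over archetypes for
#'   off-target draws, to emulate frequency biases among profile patterns
#'   (default uniform).
#' @param planted_modules list of planted gene groups; each element is a
#'   list with `genes` (character vector), `archetype` (index) and
#'   optional `sign` (+1/-1 per member, recycled). Planted genes carry
#'   their archetype as true profile; all other genes are null (true
#'   profile zero).
#' @param within_noise_sd per-parameter Gaussian noise around a gene's
#'   true profile (sigma_w, default 0.1).
#' @param ote_rate probability that an oligo's profile is replaced by a
#'   random archetype plus noise — the off-target model (default 0.3).
#' @param network_model `"erdos-renyi"`, `"barabasi-albert"` or
#'   `"from-file"` (supply `network` yourself).
#' @param gnp_p edge probability for the Erdos-Renyi model.
#' @param ba_m edges per new node for the Barabasi-Albert model.
#' @param planted_wiring `"clique"` (default) or `"tree"`: how planted
#'   module members are wired into connected subgraphs.
#' @param rng_seed integer seed driving the whole simulation.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500, n_params = 40,
                              oligo_lambda = 6, n_archetypes = 8,
                              archetype_skew = NULL,
                              planted_modules = list(),
                              within_noise_sd = 0.1, ote_rate = 0.3,
                              network_model = c("barabasi-albert",
                                                "erdos-renyi", "from-file"),
                              gnp_p = 0.02, ba_m = 3,
                              planted_wiring = c("clique", "tree"),
                              rng_seed = 1L) {
  network_model <- match.arg(network_model)
  planted_wiring <- match.arg(planted_wiring)
  stopifnot(n_genes >= 2, n_params >= 3, ote_rate >= 0, ote_rate < 1,
            within_noise_sd >= 0, oligo_lambda >= 0, n_archetypes >= 1)
  for (pm in planted_modules) {
    if (is.null(pm$genes) || is.null(pm$archetype))
      stop("each planted module needs 'genes' and 'archetype'")
    if (length(pm$genes) > n_genes)
      stop("planted module larger than the gene universe")
    if (pm$archetype > n_archetypes) stop("unknown archetype index")
  }
  structure(list(n_genes = n_genes, n_params = n_params,
                 oligo_lambda = oligo_lambda, n_archetypes = n_archetypes,
                 archetype_skew = archetype_skew,
                 planted_modules = planted_modules,
                 within_noise_sd = within_noise_sd, ote_rate = ote_rate,
                 network_model = network_model, gnp_p = gnp_p, ba_m = ba_m,
                 planted_wiring = planted_wiring,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

.sim_gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic interaction network
#'
#' Random graph per the configured model, with the planted module members
#' wired into connected subgraphs (clique or spanning tree) on top of the
#' random edges. Deterministic under the configuration seed.
#'
#' @param config a [simulation_config].
#' @return an igraph undirected simple graph with gene-named vertices.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  genes <- .sim_gene_names(config$n_genes)
  g <- switch(config$network_model,
              "erdos-renyi" = igraph::sample_gnp(config$n_genes, config$gnp_p),
              "barabasi-albert" = igraph::sample_pa(config$n_genes,
                                                    m = config$ba_m,
                                                    directed = FALSE),
              "from-file" = stop("network_model 'from-file': supply the network directly"))
  igraph::V(g)$name <- genes
  extra <- NULL
  for (pm in config$planted_modules) {
    if (!all(pm$genes %in% genes))
      stop("planted module members must exist in the gene universe")
    if (config$planted_wiring == "clique") {
      pairs <- t(utils::combn(pm$genes, 2))
    } else {
      pairs <- cbind(pm$genes[-length(pm$genes)], pm$genes[-1])
    }
    extra <- rbind(extra, pairs)
  }
  if (!is.null(extra))
    g <- igraph::add_edges(g, t(extra))
  igraph::simplify(g)
}

#' Generate a synthetic screen with ground truth
#'
#' Every planted gene's true profile is its archetype times its sign;
#' null genes have a zero true profile. Each oligo emits the gene's true
#' profile plus independent N(0, sigma_w) parameter noise, except with
#' probability `ote_rate` it is off-target: its profile is replaced by a
#' random archetype (drawn from the shared pool, optionally skewed) plus
#' noise. The finished screen is z-normalized.
#'
#' @param network an igraph network over the configured genes (e.g. from
#'   [generate_network()]).
#' @param config a [simulation_config].
#' @return list with `screen` (a z-normalized [phenotype_screen]),
#'   `truth` (a `ground_truth` object: per-gene true archetype/sign and
#'   module id, per-oligo off-target flags, the archetype matrix).
#' @export
generate_screen <- function(network, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 1L)
  genes <- .sim_gene_names(config$n_genes)
  arch <- .generate_archetypes(config$n_archetypes, config$n_params)
  gene_arch <- stats::setNames(rep(NA_integer_, config$n_genes), genes)
  gene_sign <- stats::setNames(rep(1L, config$n_genes), genes)
  gene_module <- stats::setNames(rep(NA_integer_, config$n_genes), genes)
  for (i in seq_along(config$planted_modules)) {
    pm <- config$planted_modules[[i]]
    sgn <- rep_len(if (is.null(pm$sign)) 1L else pm$sign, length(pm$genes))
    gene_arch[pm$genes] <- pm$archetype
    gene_sign[pm$genes] <- as.integer(sgn)
    gene_module[pm$genes] <- i
  }
  m <- 1L + stats::rpois(config$n_genes, config$oligo_lambda)
  gene_vec <- rep(genes, m)
  P <- sum(m)
  skew <- config$archetype_skew
  off <- stats::runif(P) < config$ote_rate
  off_arch <- sample(config$n_archetypes, P, replace = TRUE, prob = skew)
  true_mat <- matrix(0, P, config$n_params)
  planted_rows <- !is.na(gene_arch[gene_vec])
  if (any(planted_rows))
    true_mat[planted_rows, ] <- arch[gene_arch[gene_vec[planted_rows]], ,
                                     drop = FALSE] *
      gene_sign[gene_vec[planted_rows]]
  true_mat[off, ] <- arch[off_arch[off], , drop = FALSE]
  vals <- true_mat + matrix(stats::rnorm(P * config$n_params, 0,
                                         config$within_noise_sd),
                            P, config$n_params)
  colnames(vals) <- sprintf("par%02d", seq_len(config$n_params))
  screen <- znormalize(phenotype_screen(vals, gene_vec))
  truth <- structure(list(
    gene = data.frame(gene = genes, archetype = unname(gene_arch),
                      sign = unname(gene_sign), module = unname(gene_module),
                      stringsAsFactors = FALSE),
    oligo = data.frame(gene = gene_vec, oligo = screen$oligo,
                       off_target = off,
                       archetype = ifelse(off, off_arch,
                                          gene_arch[gene_vec]),
                       stringsAsFactors = FALSE),
    archetypes = arch,
    planted_modules = config$planted_modules),
    class = "ground_truth")
  list(screen = screen, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes (%d planted), %d oligos (%d off-target)\n",
              nrow(x$gene), sum(!is.na(x$gene$archetype)),
              nrow(x$oligo), sum(x$oligo$off_target)))
  invisible(x)
}

# random unit-norm archetypes, pairwise |r| < 0.3 by rejection sampling
.generate_archetypes <- function(n, n_params, max_r = 0.3) {
  out <- matrix(NA_real_, n, n_params)
  i <- 1L
  tries <- 0L
  while (i <= n) {
    cand <- stats::rnorm(n_params)
    cand <- cand / sqrt(sum(cand^2))
    ok <- TRUE
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        r <- stats::cor(cand, out[j, ])
        if (abs(r) >= max_r) { ok <- FALSE; break }
      }
    }
    if (ok) { out[i, ] <- cand; i <- i + 1L }
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("could not sample dissimilar archetypes; lower n_archetypes")
  }
  out
}

#' Write a canonical fixture bundle
#'
#' Generates a small synthetic study from a configuration and writes it
#' as plain-text files: the screen (TSV), the planted gene groups as a
#' GMT gene-set file, the network as SIF, and the ground truth as JSON.
#' Two calls with the same configuration produce byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param config a [simulation_config]; the default is a compact screen
#'   with three planted modules.
#' @return character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, config = NULL) {
  if (is.null(config)) {
    genes <- .sim_gene_names(60)
    config <- simulation_config(
      n_genes = 60, network_model = "erdos-renyi", gnp_p = 0.06,
      planted_modules = list(
        list(genes = genes[1:5], archetype = 1),
        list(genes = genes[6:10], archetype = 2),
        list(genes = genes[11:15], archetype = 3, sign = c(1, -1))),
      rng_seed = 20240101L)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(config)
  sim <- generate_screen(net, config)
  paths <- file.path(outdir, c("screen.tsv", "sets.gmt", "network.sif",
                               "truth.json"))
  write_phenotype_table(sim$screen, paths[1])
  sets <- gene_set_collection(
    stats::setNames(lapply(config$planted_modules, `[[`, "genes"),
                    sprintf("planted%02d", seq_along(config$planted_modules))))
  write_gene_sets(sets, paths[2])
  write_network(net, paths[3])
  jsonlite::write_json(list(gene = sim$truth$gene, oligo = sim$truth$oligo),
                       paths[4], digits = NA)
  invisible(paths)
}
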