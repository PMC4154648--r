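#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene identifiers);
#'   members are deduplicated, empty sets are rejected.
#' @param description optional named character vector of set descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) == 0L) {
    sets <- stats::setNames(list(), character())
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs an identifier")
  if (anyDuplicated(names(sets)))
    stop("duplicate set identifiers")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste0(min(lengths(x$sets)), "-",
                                         max(lengths(x$sets))) else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> member <TAB> member ...`.
#' Duplicate members within a set are collapsed. Gzip input is supported.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(gene_set_collection(stats::setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d (fewer than 3 fields)", short[1L]))
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_set_collection(stats::setNames(members, ids), stats::setNames(desc, ids))
}

#' Write gene sets in GMT format
#'
#' @param sets a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(id) {
    paste(c(id, sets$description[[id]], sets$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network
#'
#' Reads either SIF (`node <TAB> relation <TAB> node [node ...]`) or a
#' two-column tab-separated edge list. The graph is made undirected and
#' simple: reversed duplicates (`A-B` / `B-A`) collapse to one edge and
#' self-loops are dropped (a message reports the counts).
#'
#' @param path path to the network file (gzip supported).
#' @param format `"auto"` (default; 3+ columns is taken as SIF),
#'   `"sif"` or `"edge-list"`.
#' @return an [igraph::igraph] undirected simple graph.
#' @export
read_network <- function(path, format = c("auto", "sif", "edge-list")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (all(lengths(fields) == 2L)) "edge-list" else "sif"
  pairs <- if (format == "edge-list") {
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      stop(sprintf("malformed edge-list line %d (need 2 fields)", bad[1L]))
    do.call(rbind, fields)
  } else {
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
      stop(sprintf("malformed SIF line %d (need at least 3 fields)", bad[1L]))
    do.call(rbind, lapply(fields, function(f) {
      cbind(f[1L], f[3:length(f)])
    }))
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops || n_multi)
    message(sprintf("read_network: dropped %d self-loop(s), %d duplicate edge(s)",
                    n_loops, n_multi))
  g
}

#' Write a network as SIF
#'
#' @param network an igraph graph.
#' @param path output path.
#' @param relation relation label used in the middle SIF column.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, relation = "pp") {
  el <- igraph::as_edgelist(network, names = TRUE)
  lines <- if (nrow(el)) paste(el[, 1], relation, el[, 2], sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}

#' Restrict prior information to genes with phenotype data
#'
#' Drops genes absent from the screen: for gene-set collections, members
#' without phenotype data are removed and sets that become empty are
#' discarded; for networks, nodes without phenotype data are deleted along
#' with their edges. A message reports what was removed.
#'
#' @param prior a [gene_set_collection] or an igraph network.
#' @param screen a [phenotype_screen].
#' @return the restricted object (same type as `prior`).
#' @export
restrict_to_screen <- function(prior, screen) UseMethod("restrict_to_screen")

#' @export
restrict_to_screen.gene_set_collection <- function(prior, screen) {
  stopifnot(inherits(screen, "phenotype_screen"))
  kept <- lapply(prior$sets, function(m) m[m %in% screen$genes])
  drop <- lengths(kept) == 0L
  removed_genes <- sum(lengths(prior$sets)) - sum(lengths(kept))
  if (removed_genes || any(drop))
    message(sprintf("restrict_to_screen: removed %d member(s) without phenotype data; dropped %d empty set(s)",
                    removed_genes, sum(drop)))
  gene_set_collection(kept[!drop], prior$description[!drop])
}

#' @export
restrict_to_screen.igraph <- function(prior, screen) {
  stopifnot(inherits(screen, "phenotype_screen"))
  nm <- igraph::V(prior)$name
  if (is.null(nm)) stop("network vertices must be named with gene identifiers")
  drop <- setdiff(nm, screen$genes)
  if (length(drop))
    message(sprintf("restrict_to_screen: removed %d node(s) without phenotype data",
                    length(drop)))
  igraph::delete_vertices(prior, drop)
}
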