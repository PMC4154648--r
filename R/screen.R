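#' Construct a phenotype screen
#'
#' A phenotype screen holds the `P x N` matrix of phenotypic profiles
#' measured in a perturbation screen: one row per perturbation experiment
#' (e.g. one siRNA oligo), one column per quantitative phenotype parameter.
#' A gene may contribute several rows (one per oligo), and the number of
#' rows may differ between genes; the parameter set is identical for all.
#'
#' @param values numeric matrix, `P` profiles by `N` parameters. Column
#'   names are used as parameter names when `parameter_names` is `NULL`.
#' @param gene character vector of length `P`; the targeted gene of each row.
#' @param oligo optional character vector of length `P` identifying the
#'   perturbation reagent. Defaults to `"oligo1"`, `"oligo2"`, ... within
#'   each gene. The pair (gene, oligo) must be unique.
#' @param parameter_names optional character vector of length `N`.
#'
#' @return An object of class `phenotype_screen`: a list with elements
#'   `values`, `gene`, `oligo`, `parameter_names` and `genes` (unique gene
#'   identifiers in order of first appearance).
#' @export
phenotype_screen <- function(values, gene, oligo = NULL, parameter_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L) stop("no profiles")
  gene <- as.character(gene)
  if (length(gene) != nrow(values))
    stop("'gene' must have one entry per profile row")
  if (is.null(oligo)) {
    oligo <- stats::ave(gene, gene, FUN = function(g) paste0("oligo", seq_along(g)))
  }
  oligo <- as.character(oligo)
  if (length(oligo) != nrow(values))
    stop("'oligo' must have one entry per profile row")
  key <- paste(gene, oligo, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (gene, oligo) pair: ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  if (is.null(parameter_names)) parameter_names <- colnames(values)
  if (is.null(parameter_names)) parameter_names <- paste0("p", seq_len(ncol(values)))
  if (length(parameter_names) != ncol(values))
    stop("'parameter_names' must have one entry per parameter column")
  colnames(values) <- parameter_names
  rownames(values) <- paste(gene, oligo, sep = ":")
  structure(
    list(values = values, gene = gene, oligo = oligo,
         parameter_names = parameter_names,
         genes = unique(gene)),
    class = "phenotype_screen")
}

#' @export
print.phenotype_screen <- function(x, ...) {
  m <- profile_counts(x)
  cat(sprintf("phenotype_screen: %d profiles, %d genes, %d parameters\n",
              nrow(x$values), length(x$genes), ncol(x$values)))
  cat(sprintf("  profiles per gene: min %d, median %.3g, max %d\n",
              min(m), stats::median(m), max(m)))
  invisible(x)
}

#' @export
summary.phenotype_screen <- function(object, ...) {
  list(n_profiles = nrow(object$values),
       n_genes = length(object$genes),
       n_parameters = ncol(object$values),
       profiles_per_gene = summary(as.integer(profile_counts(object))))
}

#' Number of profiles per gene
#'
#' @param screen a [phenotype_screen].
#' @return named integer vector, one entry per gene (screen order).
#' @export
profile_counts <- function(screen) {
  stopifnot(inherits(screen, "phenotype_screen"))
  tab <- table(factor(screen$gene, levels = screen$genes))
  stats::setNames(as.integer(tab), screen$genes)
}

#' Subset a screen to a set of genes
#'
#' Keeps all profiles of the requested genes, preserving row order.
#'
#' @param screen a [phenotype_screen].
#' @param genes character vector of gene identifiers.
#' @return a [phenotype_screen] restricted to `genes`.
#' @export
screen_subset <- function(screen, genes) {
  keep <- screen$gene %in% genes
  if (!any(keep)) stop("no profiles left after subsetting")
  phenotype_screen(screen$values[keep, , drop = FALSE],
                   screen$gene[keep], screen$oligo[keep],
                   screen$parameter_names)
}

#' Read a phenotype table
#'
#' Reads a tab-separated phenotype table with a header row: one column
#' named by `gene_col` holding the gene identifier, an optional oligo
#' identifier column, and the remaining columns numeric phenotype
#' parameters. Rows are grouped by gene, preserving the within-gene row
#' order. Gzip-compressed files are read transparently.
#'
#' @param path path to a tab-separated text file.
#' @param gene_col name of the gene identifier column (default `"gene"`).
#' @param oligo_col name of the oligo identifier column; set to `NULL`
#'   when absent (default `"oligo"`, used only if present).
#' @return a [phenotype_screen].
#' @export
read_phenotype_table <- function(path, gene_col = "gene", oligo_col = "oligo") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!gene_col %in% names(df))
    stop("missing gene column '", gene_col, "' in ", path)
  if (nrow(df) == 0L) stop("no profiles in ", path)
  oligo <- NULL
  drop <- gene_col
  if (!is.null(oligo_col) && oligo_col %in% names(df)) {
    oligo <- as.character(df[[oligo_col]])
    drop <- c(drop, oligo_col)
  }
  pcols <- setdiff(names(df), drop)
  if (length(pcols) == 0L) stop("no parameter columns in ", path)
  vals <- matrix(NA_real_, nrow(df), length(pcols),
                 dimnames = list(NULL, pcols))
  for (j in seq_along(pcols)) {
    col <- df[[pcols[j]]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)) &
                     !(toupper(trimws(col)) %in% c("NA", "NAN")))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1L]], bad[1L], pcols[j]))
      col <- num
    }
    vals[, j] <- as.numeric(col)
  }
  phenotype_screen(vals, df[[gene_col]], oligo)
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotype_table()]; the written file round-trips to an
#' identical screen.
#'
#' @param screen a [phenotype_screen].
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(screen, path) {
  df <- data.frame(gene = screen$gene, oligo = screen$oligo,
                   screen$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-normalize a screen
#'
#' Standardizes every parameter column across all `P` profiles to mean 0
#' and unit sample standard deviation (denominator `P - 1`), so that all
#' parameters carry comparable weight in profile similarities.
#'
#' @param screen a [phenotype_screen].
#' @return the normalized [phenotype_screen].
#' @export
znormalize <- function(screen) {
  stopifnot(inherits(screen, "phenotype_screen"))
  v <- screen$values
  mu <- colMeans(v)
  sd <- apply(v, 2, stats::sd)
  const <- which(!is.na(sd) & sd < .Machine$double.eps^0.5)
  if (length(const))
    stop("constant parameter: ",
         paste(screen$parameter_names[const], collapse = ", "))
  v <- sweep(sweep(v, 2, mu, "-"), 2, sd, "/")
  out <- screen
  out$values <- v
  rownames(out$values) <- rownames(screen$values)
  out
}

#' Collapse a screen to one profile per gene
#'
#' Reduces each gene's profiles to a single profile, either the
#' per-parameter `"average"` or the `"mode"` profile, implemented as the
#' medoid: the oligo profile with the maximal summed Pearson correlation
#' to the gene's other profiles (for a single-profile gene, that profile).
#' Used by the chi-square baseline and by single-profile comparison runs.
#'
#' @param screen a [phenotype_screen].
#' @param method `"average"` or `"mode"`.
#' @return a [phenotype_screen] with one profile per gene.
#' @export
collapse_screen <- function(screen, method = c("average", "mode")) {
  method <- match.arg(method)
  idx <- split(seq_along(screen$gene), factor(screen$gene, levels = screen$genes))
  Z <- if (method == "mode") .row_standardize(screen$values) else NULL
  vals <- t(vapply(idx, function(i) {
    if (length(i) == 1L) return(screen$values[i, ])
    if (method == "average") return(colMeans(screen$values[i, , drop = FALSE]))
    S <- tcrossprod(Z[i, , drop = FALSE])
    S[is.na(S)] <- 0
    diag(S) <- 0
    screen$values[i[which.max(rowSums(S))], ]
  }, numeric(ncol(screen$values))))
  phenotype_screen(vals, screen$genes,
                   rep(method, length(screen$genes)),
                   screen$parameter_names)
}
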