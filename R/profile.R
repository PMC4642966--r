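#' Construct a binary differential-expression profile
#'
#' A `differential_profile` pairs a gene universe (everything measured, the
#' Fisher-test background) with the subset called differentially expressed.
#' DE genes missing from the universe are added to it with a warning rather
#' than silently dropped: a DE gene absent from the network still belongs in
#' the background and contributes to the c/d cells of the contingency table.
#'
#' @param universe Character vector of gene identifiers (non-empty).
#' @param de_genes Character vector of DE gene identifiers (may be empty).
#' @param case_normalize Lower-case identifiers before matching.
#' @return Object of class `differential_profile` with fields `universe`,
#'   `de_genes` (both sorted character vectors) and `n_de`.
#' @examples
#' differential_profile(paste0("g", 1:10), c("g2", "g5"))
#' @export
differential_profile <- function(universe, de_genes = character(),
                                 case_normalize = TRUE) {
  universe <- sort_ids(normalize_ids(universe, case_normalize))
  de_genes <- sort_ids(normalize_ids(de_genes, case_normalize))
  if (length(universe) == 0L) {
    stop("gene universe is empty", call. = FALSE)
  }
  extra <- setdiff(de_genes, universe)
  if (length(extra) > 0L) {
    warning(length(extra), " DE gene(s) absent from the universe were added",
            " to it (e.g. ", extra[[1]], ")", call. = FALSE)
    universe <- sort_ids(c(universe, extra))
  }
  structure(
    list(universe = universe, de_genes = de_genes, n_de = length(de_genes)),
    class = "differential_profile"
  )
}

#' @export
print.differential_profile <- function(x, ...) {
  cat("<differential_profile>: ", x$n_de, " DE genes / universe of ",
      length(x$universe), "\n", sep = "")
  invisible(x)
}

#' @export
glance.differential_profile <- function(x, ...) {
  tibble::tibble(n_universe = length(x$universe), n_de = x$n_de,
                 de_fraction = x$n_de / length(x$universe))
}

#' @export
tidy.differential_profile <- function(x, ...) {
  tibble::tibble(gene = x$universe, de = x$universe %in% x$de_genes)
}

read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Load a profile from plain gene-list files
#'
#' One gene per line, `#` comments allowed. An empty DE file yields a valid
#' profile with `n_de = 0` (with a warning); an empty universe is an error.
#'
#' @param universe_path,de_path Paths to the universe and DE gene lists.
#' @inheritParams differential_profile
#' @return A [differential_profile()].
#' @export
read_profile <- function(universe_path, de_path, case_normalize = TRUE) {
  universe <- read_gene_list(universe_path)
  de <- read_gene_list(de_path)
  if (length(universe) == 0L) {
    stop("universe file ", universe_path, " contains no genes", call. = FALSE)
  }
  if (length(de) == 0L) {
    warning("DE file ", de_path, " contains no genes; profile has n_de = 0",
            call. = FALSE)
  }
  differential_profile(universe, de, case_normalize = case_normalize)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of condition identifiers and a first column of gene
#' identifiers; entries are real-valued (log2-scale) expression values.
#'
#' @param path Path to the TSV file.
#' @return Tibble with first column `gene` followed by one numeric column
#'   per condition.
#' @export
read_expression_matrix <- function(path) {
  mat <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  names(mat)[1] <- "gene"
  mat$gene <- as.character(mat$gene)
  if (anyDuplicated(mat$gene)) {
    stop("duplicate gene rows in ", path, call. = FALSE)
  }
  finite <- rowSums(is.finite(as.matrix(mat[-1])))
  if (any(finite < 2)) {
    stop("every gene row needs >= 2 finite values (for a standard deviation)",
         call. = FALSE)
  }
  mat
}

#' Call differential expression by gene-wise z-score
#'
#' For each gene the expression value in `condition` is standardized against
#' that gene's mean and standard deviation across *all* conditions, so every
#' gene acts as its own control; genes with `|z| > threshold` form the DE
#' set and all measured genes form the universe. Constant genes (zero
#' standard deviation) have no defined z and are never called DE.
#'
#' @param mat Expression table as returned by [read_expression_matrix()]:
#'   first column gene identifiers, remaining columns conditions. A numeric
#'   matrix with gene rownames is also accepted.
#' @param condition Column (condition) identifier to call DE genes in.
#' @param threshold Positive z-score cutoff; strict inequality (default 2).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @param case_normalize Lower-case gene identifiers.
#' @return A [differential_profile()] over all genes in `mat`.
#' @export
zscore_de_call <- function(mat, condition, threshold = 2,
                           sd_type = c("population", "sample"),
                           case_normalize = TRUE) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (is.matrix(mat)) {
    genes <- rownames(mat)
    values <- mat
  } else {
    stopifnot(is.data.frame(mat))
    genes <- as.character(mat[[1]])
    values <- as.matrix(mat[-1])
  }
  if (is.null(genes)) stop("expression matrix has no gene identifiers",
                           call. = FALSE)
  if (!condition %in% colnames(values)) {
    stop("condition '", condition, "' is not a column of the matrix",
         call. = FALSE)
  }
  mu <- rowMeans(values)
  n <- ncol(values)
  ss <- rowSums((values - mu)^2)
  sdev <- sqrt(ss / if (sd_type == "population") n else n - 1L)
  x <- values[, condition]
  z <- ifelse(sdev > 0, (x - mu) / sdev, NA_real_)
  if (anyNA(z)) {
    message(sum(is.na(z)), " constant gene row(s) have undefined z-scores",
            " and are never called DE")
  }
  de <- genes[!is.na(z) & abs(z) > threshold]
  differential_profile(genes, de, case_normalize = case_normalize)
}
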