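#' Construct a regulatory network from an edge table
#'
#' A `regulatory_network` is a bipartite map from transcription factors to
#' the genes they directly regulate. Duplicate edges collapse; every TF must
#' end up with at least one target. A TF identifier may also occur as a gene
#' (autoregulation and TF-encoding genes are permitted).
#'
#' @param edges Data frame with one row per TF-gene interaction.
#' @param tf,gene Names of the TF and target-gene columns.
#' @param case_normalize Lower-case identifiers before matching (default
#'   `TRUE`; RegulonDB gene symbols and array annotations differ in case
#'   conventions).
#' @return An object of class `regulatory_network` with fields `tf_ids`,
#'   `gene_ids`, `targets_of` (named list of character vectors) and
#'   `out_degree` (named integer vector).
#' @examples
#' net <- regulatory_network(
#'   tibble::tibble(tf = c("A", "A", "B"), gene = c("g1", "g2", "g2"))
#' )
#' net$out_degree
#' @export
regulatory_network <- function(edges, tf = "tf", gene = "gene",
                               case_normalize = TRUE) {
  stopifnot(is.data.frame(edges))
  if (!all(c(tf, gene) %in% names(edges))) {
    stop("`edges` must contain columns '", tf, "' and '", gene, "'",
         call. = FALSE)
  }
  tfs <- normalize_ids(edges[[tf]], case_normalize)
  genes <- normalize_ids(edges[[gene]], case_normalize)
  keep <- !is.na(tfs) & !is.na(genes) & nzchar(tfs) & nzchar(genes)
  tfs <- tfs[keep]
  genes <- genes[keep]
  if (length(tfs) == 0L) {
    stop("no edges: cannot construct an empty regulatory network",
         call. = FALSE)
  }
  targets_of <- split(genes, tfs)
  targets_of <- lapply(targets_of, sort_ids)
  targets_of <- targets_of[sort(names(targets_of), method = "radix")]
  new_regulatory_network(targets_of)
}

new_regulatory_network <- function(targets_of) {
  out_degree <- vapply(targets_of, length, integer(1))
  stopifnot(all(out_degree > 0L))
  structure(
    list(
      tf_ids = names(targets_of),
      gene_ids = sort_ids(unlist(targets_of, use.names = FALSE)),
      targets_of = targets_of,
      out_degree = out_degree
    ),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network>: ", length(x$tf_ids), " TFs, ",
      length(x$gene_ids), " genes, ", sum(x$out_degree),
      " interactions\n", sep = "")
  invisible(x)
}

# Shared line-oriented parser for the two table dialects.
parse_network_file <- function(path, tf_column, gene_column, split_regex,
                               case_normalize) {
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  need <- max(tf_column, gene_column)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(lines[[i]], split_regex)[[1]]
    fields <- fields[nzchar(fields) | seq_along(fields) <= need]
    if (length(fields) < need) {
      stop("line ", i, " of ", path, " has fewer than ", need,
           " columns", call. = FALSE)
    }
    c(fields[[tf_column]], fields[[gene_column]])
  })
  if (length(rows) == 0L) {
    stop("no parseable edges in ", path, call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  regulatory_network(
    tibble::tibble(tf = mat[, 1], gene = mat[, 2]),
    case_normalize = case_normalize
  )
}

#' Read a RegulonDB-style TF-gene interaction table
#'
#' Parses the tab-separated `network_tf_gene` dialect: `#` comment lines,
#' one interaction per row, TF name and target gene name in fixed columns.
#' Additional columns (regulation sign, evidence) are parsed past but
#' ignored - the combinatorial objective is sign-agnostic.
#'
#' @param path Path to the file.
#' @param tf_column,gene_column 1-based column indices of the TF and gene
#'   names (defaults 1 and 2).
#' @inheritParams regulatory_network
#' @return A [regulatory_network()].
#' @export
read_regulondb <- function(path, tf_column = 1, gene_column = 2,
                           case_normalize = TRUE) {
  parse_network_file(path, tf_column, gene_column, split_regex = "\t",
                     case_normalize = case_normalize)
}

#' Read a generic two-column edge list
#'
#' Whitespace- or tab-separated, TF identifier then gene identifier; `#`
#' comment lines allowed.
#'
#' @inheritParams read_regulondb
#' @return A [regulatory_network()].
#' @export
read_edge_list <- function(path, case_normalize = TRUE) {
  parse_network_file(path, 1, 2, split_regex = "[ \t]+",
                     case_normalize = case_normalize)
}

#' Write a network as a two-column edge list
#'
#' Round-trips with [read_edge_list()].
#'
#' @param net A [regulatory_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  edges <- tidy(net)
  writeLines(paste(edges$tf, edges$gene, sep = "\t"), path)
  invisible(path)
}

#' TFs targeting at least one differentially expressed gene
#'
#' The "relevant" TFs for a profile are those whose target set intersects
#' the DE set; their count N is the dimensionality of the combination
#' search space (2^N configurations). Returned in lexicographic order so
#' reruns are deterministic.
#'
#' @param net A [regulatory_network()].
#' @param profile A [differential_profile()].
#' @return Character vector of TF identifiers (possibly empty).
#' @export
relevant_tfs <- function(net, profile) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(profile, "differential_profile"))
  de <- profile$de_genes
  hit <- vapply(net$targets_of, function(tg) any(tg %in% de), logical(1))
  net$tf_ids[hit]
}

#' @export
tidy.regulatory_network <- function(x, ...) {
  tibble::tibble(
    tf = rep(x$tf_ids, times = x$out_degree),
    gene = unlist(x$targets_of, use.names = FALSE)
  )
}

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble::tibble(
    n_tfs = length(x$tf_ids),
    n_genes = length(x$gene_ids),
    n_interactions = sum(x$out_degree),
    mean_out_degree = mean(x$out_degree),
    max_out_degree = max(x$out_degree)
  )
}

#' Per-TF out-degree summary
#'
#' @param net A [regulatory_network()].
#' @return Tibble with columns `tf` and `out_degree`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  tibble::tibble(tf = net$tf_ids, out_degree = unname(net$out_degree))
}
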