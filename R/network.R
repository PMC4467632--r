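#' @importFrom methods as new
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table head tail
NULL

#' Read a protein-protein interaction edge list
#'
#' Parses a tab-separated file with at least two columns of protein (or gene)
#' identifiers per line. Lines starting with `#` are skipped. Self-loops are
#' dropped and duplicate pairs (in either orientation) are collapsed; the
#' counts of both are reported as attributes.
#'
#' @param path Path to a TSV file. Identifiers are opaque, case-sensitive
#'   strings; extra columns beyond the first two are ignored.
#' @return A two-column character matrix of unordered protein pairs, each pair
#'   stored once with the lexicographically smaller identifier first.
#'   Attributes `n_self_loops` and `n_duplicates` record dropped lines.
#' @seealso [load_associations()], [build_network()]
#' @export
load_ppi <- function(path) {
  fields <- read_tsv_fields(path, min_fields = 2L)
  if (length(fields) == 0L) {
    out <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("protein_a", "protein_b")))
    attr(out, "n_self_loops") <- 0L
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  dup <- duplicated(key)
  out <- cbind(protein_a = lo[!dup], protein_b = hi[!dup])
  attr(out, "n_self_loops") <- sum(self)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a disease-gene association table
#'
#' Parses a tab-separated file whose non-comment lines carry a disease ID
#' (MeSH/OMIM-style opaque string) and a gene/protein ID. Duplicate
#' (disease, gene) rows are collapsed.
#'
#' @param path Path to a TSV file; extra columns are ignored.
#' @return A named list mapping each disease ID to a character vector of its
#'   associated protein IDs.
#' @export
load_associations <- function(path) {
  fields <- read_tsv_fields(path, min_fields = 2L)
  if (length(fields) == 0L) return(setNames(list(), character(0)))
  d <- vapply(fields, `[`, character(1), 1L)
  g <- vapply(fields, `[`, character(1), 2L)
  keep <- !duplicated(paste(d, g, sep = "\t"))
  split(g[keep], factor(d[keep], levels = unique(d[keep])))
}

read_tsv_fields <- function(path, min_fields = 2L) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < min_fields
  if (any(bad)) {
    stop("parse error in ", path, " at line ", idx[which(bad)[1]],
         ": expected at least ", min_fields, " tab-separated fields",
         call. = FALSE)
  }
  fields
}

#' Build a disease-protein network
#'
#' Assembles the heterogeneous network in which proteins are linked if they
#' interact and each disease is attached to the proteins encoded by its
#' associated genes. PPI edges carry weight `ppi_weight` (default 1) and
#' disease attachment edges carry weight `beta`. Associated proteins absent
#' from the PPI edge list are kept as isolated protein nodes: they still carry
#' information through their disease attachments, so diseases sharing such a
#' gene remain correlated.
#'
#' @param ppi Two-column character matrix of protein pairs, as returned by
#'   [load_ppi()].
#' @param assoc Named list mapping disease IDs to protein ID vectors, as
#'   returned by [load_associations()].
#' @param beta Positive attachment-edge weight (dimensionless, default 1).
#' @param ppi_weight Positive PPI-edge weight (dimensionless, default 1).
#'   Only the ratio `beta / ppi_weight` affects the walk.
#' @return A `disease_network` object: ordered protein and disease ID sets
#'   (lexicographic, fixed for determinism), the deduplicated PPI edge matrix,
#'   the association list, and the edge weights.
#' @export
build_network <- function(ppi, assoc, beta = 1, ppi_weight = 1) {
  if (length(assoc) == 0L) stop("no diseases", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive number", call. = FALSE)
  if (!is.numeric(ppi_weight) || ppi_weight <= 0)
    stop("ppi_weight must be a positive number", call. = FALSE)
  if (is.null(dim(ppi))) ppi <- matrix(ppi, ncol = 2L)
  assoc <- lapply(assoc, function(g) sort(unique(as.character(g))))
  if (any(lengths(assoc) == 0L))
    stop("disease with empty gene set", call. = FALSE)
  proteins <- sort(unique(c(as.character(ppi), unlist(assoc, use.names = FALSE))))
  net <- structure(
    list(proteins = proteins,
         diseases = sort(names(assoc)),
         ppi = canonical_edges(ppi),
         associations = assoc[sort(names(assoc))],
         beta = as.numeric(beta),
         ppi_weight = as.numeric(ppi_weight)),
    class = "disease_network")
  validate_network(net)
  net
}

canonical_edges <- function(ppi) {
  dimnames(ppi) <- NULL
  if (nrow(ppi) == 0L)
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("protein_a", "protein_b"))))
  lo <- pmin(ppi[, 1L], ppi[, 2L])
  hi <- pmax(ppi[, 1L], ppi[, 2L])
  keep <- lo != hi & !duplicated(paste(lo, hi, sep = "\t"))
  ord <- order(lo[keep], hi[keep])
  cbind(protein_a = lo[keep][ord], protein_b = hi[keep][ord])
}

validate_network <- function(net) {
  missing <- setdiff(unlist(net$associations, use.names = FALSE), net$proteins)
  if (length(missing))
    stop("associated proteins missing from node set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(net)
}

#' @export
print.disease_network <- function(x, ...) {
  cat("disease_network:", length(x$proteins), "proteins,",
      length(x$diseases), "diseases,", nrow(x$ppi), "PPI edges,",
      sum(lengths(x$associations)), "attachments (beta =", x$beta, ")\n")
  invisible(x)
}

attached_proteins <- function(net) {
  sort(unique(unlist(net$associations, use.names = FALSE)))
}

ppi_component_membership <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$proteins), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$proteins)
  if (nrow(net$ppi) > 0L)
    g <- igraph::add_edges(g, rbind(match(net$ppi[, 1L], net$proteins),
                                    match(net$ppi[, 2L], net$proteins)))
  setNames(igraph::components(g)$membership, net$proteins)
}

#' Prune proteins unreachable from any disease attachment
#'
#' Removes every protein whose PPI connected component contains no
#' disease-attached protein. After pruning, a walk started at any retained
#' protein reaches an absorbing disease node with probability 1, so expected
#' visit counts are finite.
#'
#' @param net A `disease_network`.
#' @return A list with `network` (the pruned `disease_network`) and `report`
#'   (a data frame with columns `protein_id` and `reason` for each removed
#'   protein).
#' @export
prune_unreachable <- function(net) {
  comp <- ppi_component_membership(net)
  keep_comp <- unique(comp[attached_proteins(net)])
  keep <- names(comp)[comp %in% keep_comp]
  removed <- setdiff(net$proteins, keep)
  if (length(removed)) {
    net$proteins <- sort(keep)
    sel <- net$ppi[, 1L] %in% keep & net$ppi[, 2L] %in% keep
    net$ppi <- net$ppi[sel, , drop = FALSE]
  }
  report <- data.frame(protein_id = sort(removed),
                       reason = rep("unreachable", length(removed)),
                       stringsAsFactors = FALSE)
  list(network = net, report = report)
}
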