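#' Specify a synthetic disease-protein network with planted modules
#'
#' @param n_modules Number of planted protein modules.
#' @param proteins_per_module Proteins per module.
#' @param p_within Probability of each within-module PPI edge (on top of a
#'   random spanning tree that guarantees module connectivity).
#' @param p_between Probability of each between-module PPI edge; must be
#'   strictly below `p_within`.
#' @param diseases_per_module Diseases attached to each module.
#' @param genes_per_disease Genes per disease, drawn without replacement from
#'   the disease's module.
#' @param beta Attachment-edge weight.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_modules = 3L, proteins_per_module = 15L,
                         p_within = 0.3, p_between = 0.01,
                         diseases_per_module = 4L, genes_per_disease = 3L,
                         beta = 1, seed = 1L) {
  stopifnot(n_modules >= 1, proteins_per_module >= 1,
            diseases_per_module >= 1, genes_per_disease >= 1,
            p_within > p_between, p_between >= 0, p_within <= 1, beta > 0)
  if (genes_per_disease > proteins_per_module)
    stop("genes_per_disease cannot exceed proteins_per_module", call. = FALSE)
  structure(list(n_modules = as.integer(n_modules),
                 proteins_per_module = as.integer(proteins_per_module),
                 p_within = p_within, p_between = p_between,
                 diseases_per_module = as.integer(diseases_per_module),
                 genes_per_disease = as.integer(genes_per_disease),
                 beta = beta, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic network with planted disease modules
#'
#' Each module is a random connected protein cluster: a uniform random
#' spanning tree plus independent within-module edges at `p_within`; modules
#' are interlinked by independent edges at `p_between`. Each disease draws its
#' genes without replacement from one module's proteins, so module labels are
#' ground truth for clustering-recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `network` (a pruned `disease_network`), `labels`
#'   (named integer vector, disease ID -> module index), and
#'   `protein_modules` (named integer vector for proteins).
#' @export
generate_fixture <- function(spec) {
  set.seed(spec$seed)
  m <- spec$n_modules; pm <- spec$proteins_per_module
  prot <- sprintf("P%02d_%03d", rep(seq_len(m), each = pm),
                  rep(seq_len(pm), m))
  module_of <- rep(seq_len(m), each = pm)
  edges <- list()
  for (k in seq_len(m)) {
    ids <- prot[module_of == k]
    if (pm > 1L) {
      # random spanning tree: attach node i to a uniform earlier node
      perm <- sample(ids)
      parent <- vapply(seq.int(2L, pm), function(i)
        perm[sample.int(i - 1L, 1L)], character(1))
      edges[[length(edges) + 1L]] <- cbind(parent, perm[-1L])
      extra <- which(upper.tri(diag(pm)), arr.ind = TRUE)
      keep <- runif(nrow(extra)) < spec$p_within
      if (any(keep))
        edges[[length(edges) + 1L]] <- cbind(ids[extra[keep, 1L]],
                                             ids[extra[keep, 2L]])
    }
  }
  if (m > 1L && spec$p_between > 0) {
    for (k1 in seq_len(m - 1L)) for (k2 in seq.int(k1 + 1L, m)) {
      pairs <- expand.grid(a = prot[module_of == k1],
                           b = prot[module_of == k2],
                           stringsAsFactors = FALSE)
      keep <- runif(nrow(pairs)) < spec$p_between
      if (any(keep))
        edges[[length(edges) + 1L]] <- cbind(pairs$a[keep], pairs$b[keep])
    }
  }
  ppi <- canonical_edges(do.call(rbind, c(edges,
    list(matrix(character(0), ncol = 2L)))))
  nd <- m * spec$diseases_per_module
  dis <- sprintf("D%02d_%02d", rep(seq_len(m), each = spec$diseases_per_module),
                 rep(seq_len(spec$diseases_per_module), m))
  labels <- setNames(rep(seq_len(m), each = spec$diseases_per_module), dis)
  assoc <- lapply(seq_len(nd), function(i) {
    ids <- prot[module_of == labels[i]]
    sort(ids[sample.int(pm, spec$genes_per_disease)])
  })
  names(assoc) <- dis
  net <- build_network(ppi, assoc, beta = spec$beta)
  net <- prune_unreachable(net)$network
  list(network = net, labels = labels,
       protein_modules = setNames(module_of, prot))
}

#' Write a network back to the standard TSV inputs
#'
#' Emits the two-column PPI edge list and disease-gene association table so
#' that generated fixtures exercise the same readers as real inputs.
#'
#' @param net A `disease_network`.
#' @param ppi_path,assoc_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_network_tsv <- function(net, ppi_path, assoc_path) {
  writeLines(c("#protein_a\tprotein_b",
               paste(net$ppi[, 1L], net$ppi[, 2L], sep = "\t")), ppi_path)
  assoc <- net$associations
  writeLines(c("#disease_id\tprotein_id",
               paste(rep(names(assoc), lengths(assoc)),
                     unlist(assoc, use.names = FALSE), sep = "\t")), assoc_path)
  invisible(c(ppi_path, assoc_path))
}

#' Catalog of tiny hand-analyzable networks
#'
#' Each entry bundles a network with expected values derived by hand from the
#' absorbing-walk linear system, for use as frozen oracles in tests:
#' \describe{
#'   \item{path2}{D1-P1, P1-P2, P2-D2: weight vectors (4/3, 2/3) and
#'     (2/3, 4/3), correlation 0.8.}
#'   \item{star}{Hub P0 with leaves P1..P3; D1 on the hub, D2 on leaf P1:
#'     weight vectors (8/3, 2/3, 2/3, 2/3) and (4/3, 4/3, 1/3, 1/3),
#'     correlation 44/sqrt(2584).}
#'   \item{two_components}{Two disjoint path2 copies: within-component
#'     correlation 0.8, cross-component correlation exactly 0.}
#' }
#'
#' @return Named list; each element has `network` and `expected` (a list of
#'   hand-derived weight vectors and correlations).
#' @export
tiny_fixtures <- function() {
  path2 <- build_network(rbind(c("P1", "P2")),
                         list(D1 = "P1", D2 = "P2"), beta = 1)
  star <- build_network(rbind(c("P0", "P1"), c("P0", "P2"), c("P0", "P3")),
                        list(D1 = "P0", D2 = "P1"), beta = 1)
  twoc <- build_network(rbind(c("A1", "A2"), c("B1", "B2")),
                        list(DA1 = "A1", DA2 = "A2",
                             DB1 = "B1", DB2 = "B2"), beta = 1)
  list(
    path2 = list(
      network = path2,
      expected = list(
        W = matrix(c(4, 2, 2, 4) / 3, 2, byrow = TRUE,
                   dimnames = list(c("D1", "D2"), c("P1", "P2"))),
        correlation = 0.8)),
    star = list(
      network = star,
      expected = list(
        W = matrix(c(8, 2, 2, 2, 4, 4, 1, 1) / 3, 2, byrow = TRUE,
                   dimnames = list(c("D1", "D2"),
                                   c("P0", "P1", "P2", "P3"))),
        correlation = 44 / sqrt(2584))),
    two_components = list(
      network = twoc,
      expected = list(
        within_correlation = 0.8,
        cross_correlation = 0)))
}
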