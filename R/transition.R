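#' Build the absorbing-walk transition model
#'
#' For each protein i with total incident weight
#' `s_i = ppi_weight * deg_ppi(i) + beta * n_attached(i)`, the walker moves to
#' PPI neighbour j with probability `ppi_weight / s_i` and is absorbed (the
#' walk terminates at a disease node) with probability
#' `a_i = beta * n_attached(i) / s_i`. Every disease node is absorbing. A walk
#' for disease d starts uniformly over d's associated proteins, because all
#' attachment edges share the same weight.
#'
#' @param net A pruned `disease_network` (see [prune_unreachable()]); a
#'   network containing a zero-absorption component is rejected because
#'   expected visit counts would be infinite.
#' @return A `transition_model`: sparse sub-stochastic matrix `Q`
#'   (proteins x proteins), absorption vector `a`, sparse start matrix `S`
#'   (diseases x proteins), node strengths `s`, and the node orderings.
#' @export
build_transition_model <- function(net) {
  comp <- ppi_component_membership(net)
  if (!all(comp %in% comp[attached_proteins(net)]))
    stop("network contains a component with no disease attachment; ",
         "run prune_unreachable() first", call. = FALSE)
  p <- net$proteins
  np <- length(p)
  i <- match(net$ppi[, 1L], p)
  j <- match(net$ppi[, 2L], p)
  ppi_deg <- tabulate(c(i, j), nbins = np)
  n_att <- tabulate(match(unlist(net$associations, use.names = FALSE), p),
                    nbins = np)
  s <- net$ppi_weight * ppi_deg + net$beta * n_att
  stopifnot(all(s > 0))
  Q <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = net$ppi_weight / s[c(i, j)],
                            dims = c(np, np), dimnames = list(p, p))
  a <- net$beta * n_att / s
  di <- rep(seq_along(net$diseases), lengths(net$associations[net$diseases]))
  gj <- match(unlist(net$associations[net$diseases], use.names = FALSE), p)
  S <- Matrix::sparseMatrix(i = di, j = gj,
                            x = 1 / lengths(net$associations[net$diseases])[di],
                            dims = c(length(net$diseases), np),
                            dimnames = list(net$diseases, p))
  structure(list(Q = Q, a = setNames(a, p), S = S, s = setNames(s, p),
                 proteins = p, diseases = net$diseases,
                 beta = net$beta, ppi_weight = net$ppi_weight),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", length(x$proteins), "proteins,",
      length(x$diseases), "diseases\n")
  invisible(x)
}

solve_visits <- function(tm, rhs) {
  # x = (I - Q^T)^{-1} rhs : expected visit counts for start distribution rhs
  M <- Matrix::Diagonal(length(tm$proteins)) - Matrix::t(tm$Q)
  as.matrix(Matrix::solve(M, rhs))
}

#' Compute a disease's weight vector
#'
#' The weight vector of a disease is the expected number of visits the random
#' walker makes to each protein, starting from the disease and terminating on
#' arrival at any disease node. It is obtained exactly by solving the sparse
#' linear system `(I - Q^T) w = S(d)`.
#'
#' @param tm A `transition_model`.
#' @param disease Disease ID present in the model.
#' @return Named numeric vector of expected visit counts over the ordered
#'   protein set. Entries are nonnegative and satisfy the conservation law
#'   `sum(w * a) = 1` (every walk is absorbed exactly once).
#' @export
compute_weight_vector <- function(tm, disease) {
  k <- match(disease, tm$diseases)
  if (is.na(k)) stop("unknown disease: ", disease, call. = FALSE)
  w <- drop(solve_visits(tm, Matrix::t(tm$S[k, , drop = FALSE])))
  setNames(w, tm$proteins)
}

#' Compute the full disease x protein weight matrix
#'
#' Batch version of [compute_weight_vector()]: one sparse factorization is
#' reused across all diseases' start distributions.
#'
#' @param tm A `transition_model`.
#' @return Dense numeric matrix, rows named by disease and columns by protein.
#' @export
compute_all_weight_vectors <- function(tm) {
  W <- t(solve_visits(tm, Matrix::t(tm$S)))
  dimnames(W) <- list(tm$diseases, tm$proteins)
  W
}

#' Simulate random walks as an independent Monte-Carlo check
#'
#' Simulates `n_walks` trajectories of the absorbing walk for one disease and
#' returns empirical mean visit counts with per-protein standard errors. This
#' estimator is independent of the linear-algebra path and is used to validate
#' it.
#'
#' @param net A pruned `disease_network`.
#' @param disease Disease ID.
#' @param n_walks Number of trajectories.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param max_steps Safety valve: walks longer than this are truncated and
#'   counted in `n_truncated` (expected to be 0 in practice).
#' @return A list with `mean` (named empirical weight vector), `se` (named
#'   standard errors of the means), `n_walks`, and `n_truncated`.
#' @export
simulate_walks <- function(net, disease, n_walks, seed = 1L,
                           max_steps = 1e6L) {
  tm <- build_transition_model(net)
  np <- length(tm$proteins)
  zero <- setNames(numeric(np), tm$proteins)
  if (n_walks == 0L) {
    warning("n_walks = 0: returning zero vector")
    return(list(mean = zero, se = zero, n_walks = 0L, n_truncated = 0L))
  }
  genes <- net$associations[[disease]]
  if (is.null(genes)) stop("unknown disease: ", disease, call. = FALSE)
  # conditional move given non-absorption is uniform over PPI neighbours
  # (all PPI edges share one weight); flatten adjacency for vectorized draws
  i <- match(net$ppi[, 1L], tm$proteins)
  j <- match(net$ppi[, 2L], tm$proteins)
  nb <- split(c(j, i), factor(c(i, j), levels = seq_len(np)))
  deg <- lengths(nb)
  nb_flat <- unlist(nb, use.names = FALSE)
  nb_start <- cumsum(c(0L, deg[-np]))
  a <- unname(tm$a)

  set.seed(seed)
  gi <- match(genes, tm$proteins)
  state <- gi[sample.int(length(gi), n_walks, replace = TRUE)]
  walk <- seq_len(n_walks)
  visits <- matrix(0, n_walks, np)
  n_trunc <- 0L
  step <- 0L
  while (length(walk) > 0L) {
    step <- step + 1L
    if (step > max_steps) { n_trunc <- length(walk); break }
    visits[cbind(walk, state)] <- visits[cbind(walk, state)] + 1
    absorbed <- runif(length(walk)) < a[state]
    walk <- walk[!absorbed]
    state <- state[!absorbed]
    if (length(walk) > 0L) {
      pick <- nb_start[state] + 1L + floor(runif(length(walk)) * deg[state])
      state <- nb_flat[pick]
    }
  }
  m <- colMeans(visits)
  v <- colMeans(visits^2) - m^2
  list(mean = setNames(m, tm$proteins),
       se = setNames(sqrt(pmax(v, 0) / n_walks), tm$proteins),
       n_walks = as.integer(n_walks), n_truncated = n_trunc)
}
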