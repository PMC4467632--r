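#' Seed cluster centers by greedy farthest-first traversal
#'
#' The first center is the disease with the largest total weight; each
#' subsequent center is the disease maximizing the minimum cosine distance to
#' the centers already chosen. Exact ties are broken by a seeded draw.
#'
#' @param W Disease x protein weight matrix.
#' @param K Number of clusters, `1 <= K <= nrow(W)`.
#' @param seed Integer seed used only to break exact ties.
#' @return K x protein matrix of unit-normalized initial cluster vectors,
#'   with the seeding diseases' IDs as row names.
#' @export
init_clusters <- function(W, K, seed = 1L) {
  nd <- nrow(W)
  if (!is.numeric(K) || K < 1 || K > nd)
    stop("K must lie in [1, number of diseases]", call. = FALSE)
  K <- as.integer(K)
  set.seed(seed)
  pick_max <- function(x) {
    top <- which(x == max(x))
    if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
    top
  }
  Wn <- W / sqrt(rowSums(W^2))
  chosen <- pick_max(rowSums(W))
  if (K > 1L) {
    mind <- 1 - drop(Wn %*% Wn[chosen, ])
    for (k in seq_len(K - 1L)) {
      mind[chosen] <- -Inf
      nxt <- pick_max(mind)
      chosen <- c(chosen, nxt)
      mind <- pmin(mind, 1 - drop(Wn %*% Wn[nxt, ]))
    }
  }
  V0 <- Wn[chosen, , drop = FALSE]
  rownames(V0) <- rownames(W)[chosen]
  V0
}

#' Fit an overlapping probabilistic clustering of diseases
#'
#' Soft spherical clustering on the unit sphere of weight vectors. The E-step
#' sets each disease's membership in cluster k proportional to
#' `C(w_hat(d), v_k)^gamma`, the cosine between the disease's normalized
#' weight vector and the cluster vector raised to a sharpness exponent; the
#' M-step replaces each cluster vector by the membership-weighted sum of
#' disease vectors, re-normalized. Diseases whose correlations with every
#' cluster are zero get a uniform membership row. After convergence, cluster
#' pairs with mutual cosine above `merge_threshold` are merged (memberships
#' summed) and one final E-step is run, so clusters are distinct.
#'
#' @param W Disease x protein weight matrix.
#' @param K Number of clusters; default `ceiling(sqrt(nrow(W)))`.
#' @param gamma Sharpness exponent >= 1 (default 5). At `gamma = 1`
#'   memberships are directly proportional to correlations, but on
#'   low-dimensional networks, where between-module cosines are far from
#'   zero, the E/M iteration then has an attractive fixed point with every
#'   cluster vector at the global centroid; a moderate sharpness keeps
#'   cluster vectors apart while leaving memberships soft.
#' @param tol Convergence threshold on the maximum membership change.
#' @param max_iter Iteration cap; non-convergence returns the model with
#'   `converged = FALSE` and a warning.
#' @param seed Seed for tie-breaking in initialization.
#' @param V0 Optional initial cluster vectors (rows unit-normalized); used to
#'   warm-start a refit. Overrides `K` and `seed`.
#' @param merge_threshold Cosine above which two clusters are merged.
#' @return A `cluster_model`: `V` (K x protein unit cluster vectors, rows
#'   named `C1..CK`), `P` (disease x cluster membership matrix, rows sum
#'   to 1), `gamma`, `converged`, `n_iter`.
#' @export
fit_clusters <- function(W, K = ceiling(sqrt(nrow(W))), gamma = 5,
                         tol = 1e-6, max_iter = 500L, seed = 1L,
                         V0 = NULL, merge_threshold = 0.999) {
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  Wn <- W / sqrt(rowSums(W^2))
  V <- if (is.null(V0)) init_clusters(W, K, seed) else V0 / sqrt(rowSums(V0^2))
  P_old <- NULL
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    P <- e_step(Wn, V, gamma)
    if (!is.null(P_old) && ncol(P) == ncol(P_old) &&
        max(abs(P - P_old)) < tol) { converged <- TRUE; break }
    P_old <- P
    V <- m_step(Wn, P, V)
  }
  if (!converged)
    warning("clustering did not converge in ", max_iter, " iterations")
  merged <- merge_close_clusters(P, V, merge_threshold)
  V <- merged$V
  P <- e_step(Wn, V, gamma)
  rownames(V) <- colnames(P) <- paste0("C", seq_len(nrow(V)))
  structure(list(V = V, P = P, gamma = gamma, converged = converged,
                 n_iter = n_iter, merge_threshold = merge_threshold),
            class = "cluster_model")
}

e_step <- function(Wn, V, gamma) {
  C <- pmin(pmax(Wn %*% t(V), 0), 1)^gamma
  rs <- rowSums(C)
  zero <- rs == 0
  C[zero, ] <- 1 / ncol(C)
  rs[zero] <- 1
  C / rs
}

m_step <- function(Wn, P, V_prev) {
  V <- t(P) %*% Wn
  nrm <- sqrt(rowSums(V^2))
  dead <- nrm == 0
  if (any(dead)) V[dead, ] <- V_prev[dead, , drop = FALSE]
  nrm[dead] <- 1
  V / nrm
}

merge_close_clusters <- function(P, V, threshold) {
  repeat {
    if (nrow(V) == 1L) break
    CC <- V %*% t(V)
    diag(CC) <- 0
    hit <- which(CC > threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) break
    i <- min(hit[1L, ]); j <- max(hit[1L, ])
    P[, i] <- P[, i] + P[, j]
    P <- P[, -j, drop = FALSE]
    V[i, ] <- V[i, ] + V[j, ]
    V <- V[-j, , drop = FALSE]
    V[i, ] <- V[i, ] / sqrt(sum(V[i, ]^2))
  }
  list(P = P, V = V)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", nrow(x$V), "clusters,", nrow(x$P), "diseases, gamma =",
      x$gamma, if (x$converged) "(converged" else "(not converged",
      "in", x$n_iter, "iterations)\n")
  invisible(x)
}

#' List the clusters containing a disease
#'
#' Membership probabilities of one disease over clusters, ranked
#' non-increasing, cut off by lowest rank (ties expand the list) or by a
#' minimum membership probability.
#'
#' @param model A `cluster_model`.
#' @param disease Disease ID.
#' @param rank Lowest acceptable rank; exactly one of `rank`/`min_prob`.
#' @param min_prob Minimum membership probability in `[0, 1]`.
#' @return Data frame with columns `rank`, `cluster_id`, `probability`.
#' @export
membership_query <- function(model, disease, rank = NULL, min_prob = NULL) {
  k <- match(disease, rownames(model$P))
  if (is.na(k)) stop("unknown disease: ", disease, call. = FALSE)
  if (is.null(rank) == is.null(min_prob))
    stop("provide exactly one of rank and min_prob", call. = FALSE)
  v <- setNames(model$P[k, ], colnames(model$P))
  if (!is.null(rank)) {
    if (!is.numeric(rank) || rank < 1) stop("rank must be >= 1", call. = FALSE)
    idx <- select_by_rank(v, as.integer(rank))
  } else {
    if (!is.numeric(min_prob) || min_prob < 0 || min_prob > 1)
      stop("min_prob must lie in [0, 1]", call. = FALSE)
    ord <- order(v, decreasing = TRUE)
    idx <- ord[v[ord] >= min_prob]
  }
  data.frame(rank = seq_along(idx),
             cluster_id = colnames(model$P)[idx],
             probability = unname(v[idx]),
             stringsAsFactors = FALSE)
}

#' List all diseases of a cluster by membership probability
#'
#' @param model A `cluster_model`.
#' @param cluster Cluster ID (e.g. `"C1"`).
#' @return Data frame with columns `disease_id`, `probability`, sorted
#'   non-increasing; one row per disease in the model.
#' @export
cluster_listing <- function(model, cluster) {
  k <- match(cluster, colnames(model$P))
  if (is.na(k)) stop("unknown cluster: ", cluster, call. = FALSE)
  v <- setNames(model$P[, k], rownames(model$P))
  ord <- order(v, decreasing = TRUE)
  data.frame(disease_id = rownames(model$P)[ord],
             probability = unname(v[ord]),
             stringsAsFactors = FALSE)
}
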