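#' Build the full base model for a network
#'
#' Convenience constructor tying the pipeline together: transition model,
#' all weight vectors, the correlation matrix, and the fitted clustering.
#' This is the frozen base model that what-if edits are scored against.
#'
#' @param net A `disease_network` (pruned automatically).
#' @param K Number of clusters (default `ceiling(sqrt(n_diseases))`).
#' @param gamma Clustering sharpness exponent.
#' @param seed Seed for clustering initialization tie-breaks.
#' @param ... Further arguments to [fit_clusters()].
#' @return A `flow_model`: `network`, `tm`, `W`, `C`, `clusters`.
#' @export
build_model <- function(net, K = ceiling(sqrt(length(net$diseases))),
                        gamma = 5, seed = 1L, ...) {
  net <- prune_unreachable(net)$network
  tm <- build_transition_model(net)
  W <- compute_all_weight_vectors(tm)
  structure(list(network = net, tm = tm, W = W,
                 C = correlation_matrix(W),
                 clusters = fit_clusters(W, K = K, gamma = gamma,
                                         seed = seed, ...)),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat("flow_model:", nrow(x$W), "diseases,", ncol(x$W), "proteins,",
      nrow(x$clusters$V), "clusters\n")
  invisible(x)
}

#' Replace or add a disease's gene associations
#'
#' If the disease exists, its association set is replaced by `genes` (the
#' previous associations are discarded); otherwise a new disease is added.
#' Genes absent from the protein set are added as isolated protein nodes.
#' The edited network is re-pruned.
#'
#' @param net A `disease_network`.
#' @param disease Disease ID (existing or new).
#' @param genes Nonempty character vector of protein IDs.
#' @return The edited, pruned `disease_network`.
#' @export
apply_edit <- function(net, disease, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene list must be nonempty", call. = FALSE)
  assoc <- net$associations
  assoc[[disease]] <- sort(genes)
  edited <- build_network(net$ppi, assoc, beta = net$beta,
                          ppi_weight = net$ppi_weight)
  prune_unreachable(edited)$network
}

align_to <- function(w, proteins) {
  out <- setNames(numeric(length(proteins)), proteins)
  common <- intersect(names(w), proteins)
  out[common] <- w[common]
  out
}

total_visit_counts <- function(tm) {
  # t_i = expected total visits of a walk started at protein i (row sums of
  # the fundamental matrix), via one solve of (I - Q) t = 1
  M <- Matrix::Diagonal(length(tm$proteins)) - tm$Q
  setNames(as.numeric(Matrix::solve(M, rep(1, length(tm$proteins)))),
           tm$proteins)
}

#' Certified error bounds for a frozen-model what-if approximation
#'
#' An edit replaces a disease's attachments at the protein set A (the
#' symmetric difference of old and new gene sets). A walk started at any
#' unedited disease behaves differently only when it visits A: each visit to
#' p in A diverges with probability at most
#' `eps_p = beta / (min(s_pre, s_post) + beta)` (the total-variation distance
#' between the one-step kernels at p), and a diverged pair of walks differs
#' by at most `1 + L_max` expected visits, with `L_max` the largest total
#' expected visit count started from A in either the base or edited chain.
#' This yields the L1 perturbation bound
#' `Delta1(e) = (sum_p w_p(e) * eps_p) * (1 + L_max)` for every unedited
#' disease e, from which correlation, cluster-drift and membership bounds
#' follow; all bounds are clamped to `[0, 1]`.
#'
#' @param base A `flow_model` built on the unedited network.
#' @param edited_net The edited network from [apply_edit()].
#' @param disease The edited disease ID.
#' @return A list: `A` (edited protein set), `delta1` (named L1 bounds per
#'   unedited disease), `corr_bound` (named correlation bounds), `cluster_drift`
#'   (named per-cluster bounds on the normalized cluster-vector drift).
#' @export
error_bound <- function(base, edited_net, disease) {
  old_genes <- base$network$associations[[disease]]
  new_genes <- edited_net$associations[[disease]]
  A <- union(setdiff(old_genes, new_genes), setdiff(new_genes, old_genes))
  others <- setdiff(base$tm$diseases, disease)
  zero <- setNames(numeric(length(others)), others)
  kz <- setNames(numeric(nrow(base$clusters$V)), rownames(base$clusters$V))
  if (length(A) == 0L)
    return(list(A = character(0), delta1 = zero, corr_bound = zero,
                cluster_drift = kz))

  tm_e <- build_transition_model(edited_net)
  s_pre <- base$tm$s[A]                      # NA where p is new to the network
  s_post <- tm_e$s[A]                        # NA where p was pruned away
  s_min <- pmin(s_pre, s_post, na.rm = TRUE)
  eps <- setNames(base$network$beta / (s_min + base$network$beta), A)
  t_base <- total_visit_counts(base$tm)
  t_edit <- total_visit_counts(tm_e)
  L_max <- max(t_base[intersect(A, base$tm$proteins)],
               t_edit[intersect(A, tm_e$proteins)], 0)

  A_base <- intersect(A, base$tm$proteins)
  w_norm <- sqrt(rowSums(base$W^2))
  delta1 <- zero
  if (length(A_base) > 0L && length(others) > 0L) {
    wA <- base$W[others, A_base, drop = FALSE]
    delta1 <- drop(wA %*% eps[A_base]) * (1 + L_max)
  }
  corr_bound <- setNames(pmin(1, 2 * delta1 / w_norm[others]), others)

  # cluster-vector drift: u_k = sum_e P[e,k] * w_hat(e); a unit-vector drift
  # of 2*B_k/||u_k|| follows from ||x/||x|| - y/||y|||| <= 2||x-y||/||x||
  P <- base$clusters$P
  Wn <- base$W / w_norm
  per_disease_shift <- setNames(numeric(nrow(base$W)), rownames(base$W))
  per_disease_shift[others] <- pmin(2, 2 * delta1 / w_norm[others])
  if (disease %in% rownames(base$W)) {
    w_old <- Wn[disease, ]
    w_new <- compute_weight_vector(tm_e, disease)
    prots <- union(names(w_old), names(w_new))
    d_old <- align_to(w_old, prots)
    d_new <- align_to(w_new / sqrt(sum(w_new^2)), prots)
    per_disease_shift[disease] <- sqrt(sum((d_new - d_old)^2))
    B <- drop(per_disease_shift %*% P)
  } else {
    # a brand-new disease joins the refit M-step with membership <= 1 and a
    # unit vector, so each cluster sum can gain at most norm 1
    B <- drop(per_disease_shift %*% P) + 1
  }
  u_norm <- sqrt(rowSums((t(P) %*% Wn)^2))
  cluster_drift <- pmin(1, 2 * B / pmax(u_norm, .Machine$double.eps))
  names(cluster_drift) <- rownames(base$clusters$V)
  list(A = A, delta1 = delta1, corr_bound = corr_bound,
       cluster_drift = cluster_drift)
}

#' Approximate what-if scoring against a frozen base model
#'
#' Computes the edited disease's weight vector exactly in the edited network,
#' then scores it against the frozen base model: correlations with the
#' unedited diseases' (frozen) weight vectors and membership probabilities
#' against the frozen cluster vectors, each paired with a certified upper
#' bound on the error incurred by not recomputing the rest of the model
#' (see [error_bound()]).
#'
#' @param base A `flow_model` on the unedited network.
#' @param edited_net The edited network from [apply_edit()].
#' @param disease The edited disease ID.
#' @return A `whatif_result`: `disease`, `weight` (the exact edited-network
#'   weight vector), `correlations` (data frame `disease_id`, `correlation`,
#'   `error_bound`), `memberships` (data frame `cluster_id`, `probability`,
#'   `error_bound`), `no_op`, `exact_available = FALSE`.
#' @export
approx_whatif <- function(base, edited_net, disease) {
  bounds <- error_bound(base, edited_net, disease)
  tm_e <- build_transition_model(edited_net)
  w_new <- compute_weight_vector(tm_e, disease)
  others <- setdiff(base$tm$diseases, disease)
  prots <- union(base$tm$proteins, names(w_new))
  wn <- align_to(w_new, prots)

  corr <- vapply(others, function(e)
    correlation(wn, align_to(base$W[e, ], prots)), numeric(1))
  ord <- order(corr, decreasing = TRUE)
  correlations <- data.frame(
    disease_id = others[ord], correlation = unname(corr[ord]),
    error_bound = unname(bounds$corr_bound[others[ord]]),
    stringsAsFactors = FALSE)

  V <- base$clusters$V
  gamma <- base$clusters$gamma
  K <- nrow(V)
  Ck <- vapply(seq_len(K), function(k)
    correlation(wn, align_to(V[k, ], prots)), numeric(1))
  Cg <- Ck^gamma
  S <- sum(Cg)
  prob <- if (S > 0) Cg / S else rep(1 / K, K)
  delta <- gamma * max(bounds$cluster_drift)
  mem_bound <- if (S > K * delta && delta >= 0)
    min(1, delta * (1 + K) / (S - K * delta)) else 1
  if (length(bounds$A) == 0L) mem_bound <- 0
  ordk <- order(prob, decreasing = TRUE)
  memberships <- data.frame(
    cluster_id = rownames(V)[ordk], probability = unname(prob[ordk]),
    error_bound = rep(mem_bound, K), stringsAsFactors = FALSE)

  structure(list(disease = disease, weight = w_new,
                 correlations = correlations, memberships = memberships,
                 no_op = length(bounds$A) == 0L, bounds = bounds,
                 exact_available = FALSE),
            class = "whatif_result")
}

#' @export
print.whatif_result <- function(x, ...) {
  cat("whatif_result for", x$disease,
      if (x$no_op) "(no-op edit)" else
        paste0("(", length(x$bounds$A), " proteins touched)"), "\n")
  cat("top correlations:\n")
  print(head(x$correlations, 5L))
  cat("memberships:\n")
  print(head(x$memberships, 5L))
  invisible(x)
}

#' Exact what-if recomputation
#'
#' Re-runs the full pipeline on the edited network: all weight vectors, the
#' correlation matrix, and the clustering. The clustering is warm-started
#' from the base model's cluster vectors so that cluster identities remain
#' comparable to the base fit; this is the oracle against which
#' [approx_whatif()] and its error bounds are validated.
#'
#' @param edited_net The edited network.
#' @param base Optional `flow_model` whose cluster vectors warm-start the
#'   refit (recommended); if `NULL` the clustering is fit from scratch.
#' @param K,gamma,seed,... Passed to [fit_clusters()] when `base` is `NULL`.
#' @return A `flow_model` on the edited network.
#' @export
exact_whatif <- function(edited_net, base = NULL,
                         K = ceiling(sqrt(length(edited_net$diseases))),
                         gamma = 5, seed = 1L, ...) {
  tm <- build_transition_model(edited_net)
  W <- compute_all_weight_vectors(tm)
  if (is.null(base)) {
    cl <- fit_clusters(W, K = K, gamma = gamma, seed = seed, ...)
  } else {
    V0 <- base$clusters$V
    common <- intersect(colnames(V0), colnames(W))
    V0e <- matrix(0, nrow(V0), ncol(W), dimnames = list(rownames(V0),
                                                        colnames(W)))
    V0e[, common] <- V0[, common]
    cl <- fit_clusters(W, gamma = base$clusters$gamma, seed = seed,
                       V0 = V0e, ...)
  }
  structure(list(network = edited_net, tm = tm, W = W,
                 C = correlation_matrix(W), clusters = cl),
            class = "flow_model")
}
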