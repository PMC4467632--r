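#' Correlation between two diseases
#'
#' The correlation between two diseases is the cosine of the angle between
#' their weight vectors. Because weights are nonnegative expected visit
#' counts, the value lies in `[0, 1]`; it is not a Pearson correlation.
#'
#' @param wa,wb Weight vectors over the same ordered protein set.
#' @return Cosine similarity in `[0, 1]`.
#' @export
correlation <- function(wa, wb) {
  if (length(wa) != length(wb))
    stop("weight vectors must share the protein ordering", call. = FALSE)
  na <- sqrt(sum(wa^2)); nb <- sqrt(sum(wb^2))
  if (na == 0 || nb == 0) stop("zero weight vector", call. = FALSE)
  min(1, sum(wa * wb) / (na * nb))
}

#' Pairwise disease correlation matrix
#'
#' @param W Disease x protein weight matrix with nonzero rows
#'   (see [compute_all_weight_vectors()]).
#' @return Symmetric matrix of cosine correlations with unit diagonal.
#' @export
correlation_matrix <- function(W) {
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) stop("zero weight vector", call. = FALSE)
  Wn <- W / nrm
  C <- Wn %*% t(Wn)
  C <- (C + t(C)) / 2          # exact symmetry
  C[C > 1] <- 1
  diag(C) <- 1
  C
}

# rank-cutoff selection with tie expansion: with rank r, every value tied
# with the r-th largest is included, so the result can exceed r entries
select_by_rank <- function(values, r) {
  if (length(values) == 0L) return(integer(0))
  ord <- order(values, decreasing = TRUE)
  if (r >= length(values)) return(ord)
  thr <- values[ord[r]]
  ord[seq_len(max(which(values[ord] >= thr)))]
}

#' Query diseases similar to a given disease
#'
#' Returns the other diseases ranked by their correlation with the query,
#' cut off either at a lowest acceptable rank (ties at the boundary expand
#' the list) or at a minimum correlation. Each hit is annotated as
#' significant when its correlation exceeds `significance_floor`; the floor
#' is advisory and never filters the list.
#'
#' @param C Correlation matrix from [correlation_matrix()].
#' @param disease Query disease ID.
#' @param rank Lowest acceptable rank (>= 1). Exactly one of `rank` and
#'   `min_corr` must be given.
#' @param min_corr Minimum correlation in `[0, 1]`; all hits with correlation
#'   >= `min_corr` are returned.
#' @param significance_floor Advisory significance threshold (default 1e-6).
#' @return A data frame with columns `rank`, `disease_id`, `correlation`,
#'   `significant`, sorted by non-increasing correlation (self excluded).
#' @export
query_similar <- function(C, disease, rank = NULL, min_corr = NULL,
                          significance_floor = 1e-6) {
  k <- match(disease, rownames(C))
  if (is.na(k)) stop("unknown disease: ", disease, call. = FALSE)
  if (is.null(rank) == is.null(min_corr))
    stop("provide exactly one of rank and min_corr", call. = FALSE)
  v <- setNames(C[k, ], colnames(C))[-k]
  if (!is.null(rank)) {
    if (!is.numeric(rank) || rank < 1) stop("rank must be >= 1", call. = FALSE)
    idx <- select_by_rank(v, as.integer(rank))
  } else {
    if (!is.numeric(min_corr) || min_corr < 0 || min_corr > 1)
      stop("min_corr must lie in [0, 1]", call. = FALSE)
    ord <- order(v, decreasing = TRUE)
    idx <- ord[v[ord] >= min_corr]
  }
  data.frame(rank = seq_along(idx),
             disease_id = names(v)[idx],
             correlation = unname(v[idx]),
             significant = unname(v[idx] > significance_floor),
             stringsAsFactors = FALSE)
}
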