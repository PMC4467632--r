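# Shared test helpers: independent oracles and tiny builders.

# breadth-first reachability over an undirected edge matrix, independent of
# the igraph-based pruning path
bfs_reachable <- function(edges, start) {
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) add(edges[i, 1], edges[i, 2])
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# clustering accuracy under the best label permutation
perm_accuracy <- function(assign, labels) {
  K <- max(labels, assign)
  max(apply(all_perms(K), 1, function(p) mean(p[assign] == labels)))
}

write_tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

path2_network <- function() tiny_fixtures()$path2$network

quiet_fit <- function(...) suppressWarnings(fit_clusters(...))
quiet_model <- function(...) suppressWarnings(build_model(...))
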