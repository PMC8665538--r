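# Shared fixtures and independent oracles.

# 4-node path A-B-C-D
path_network <- function() {
  gene_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
}

# Erdos-Renyi edge sampler built on base R only (generation helper; the
# package never sees this code path)
random_network <- function(n, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    pairs <- t(utils::combn(ids, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample(nrow(pairs), 2L)] <- TRUE
    gene_network(pairs[keep, , drop = FALSE], nodes = ids)
  })
}

# drop isolated nodes so the graph is a valid random-walk substrate
random_walk_graph <- function(n, p = 0.12, seed = 1) {
  net <- random_network(n, p, seed)
  used <- unique(c(net$edges[, 1L], net$edges[, 2L]))
  gene_network(net$edges, nodes = used)
}

# Independent all-pairs shortest-path oracle: Floyd-Warshall on the
# adjacency matrix, no igraph involved.
floyd_warshall <- function(net) {
  ids <- net$nodes
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1L]; j <- net$edges[k, 2L]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Independent RWR oracle: build the degree-biased transition matrix from
# first principles and solve the stationary system directly,
#   p = (1 - alpha) * (I - alpha * T)^{-1} r
oracle_rwr <- function(net, seed_genes, damping = 0.85) {
  ids <- net$nodes
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1L]; j <- net$edges[k, 2L]
    adj[i, j] <- adj[j, i] <- 1
  }
  deg <- rowSums(adj)
  tm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (u in seq_len(n)) {
    w <- adj[, u] * deg
    tm[, u] <- w / sum(w)
  }
  r <- stats::setNames(numeric(n), ids)
  present <- intersect(seed_genes, ids)
  r[present] <- 1 / length(present)
  p <- solve(diag(n) - damping * tm, (1 - damping) * r)
  stats::setNames(drop(p), ids)
}

# small complete expression study for I/O and diffexp fixtures
toy_study <- function(n_genes = 5, n_case = 4, n_control = 4, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(stats::rnorm(n_genes * (n_case + n_control), 8, 0.5),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(n_case + n_control))))
    expression_study(vals, rep(c("case", "control"), c(n_case, n_control)))
  })
}

# write a study as the matrix + design TSV pair read_expression() expects
write_study_tsv <- function(study, matrix_path, design_path) {
  df <- data.frame(gene_id = rownames(study$values), study$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = study$samples,
                                group = study$groups),
                     design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
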