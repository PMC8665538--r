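# Degree-biased random walk with restart (RWR) on a DCN.
#
# Seeds are the known disease genes present in the DCN. At each step the
# walker restarts at a seed with probability 1 - damping, or moves to a
# neighbor with probability proportional to that neighbor's degree:
#   P(u -> v) = deg(v) / sum_{w in N(u)} deg(w),
# encoding the assumption that high-degree genes are more likely transit
# targets from upstream seed nodes. The stationary distribution
#   p = damping * T p + (1 - damping) * r
# is the per-gene walk score; genes scoring high are functionally close to
# the seeds and are the driver candidates.

#' Random-walk configuration
#'
#' @param damping probability of continuing the walk at each step (restart
#'   probability is `1 - damping`), the PageRank damping-factor convention.
#'   Default 0.85.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @param restart_mode `"uniform"` (equal mass on each seed present in the
#'   DCN, the default) or `"expression"` (mass proportional to each seed's
#'   absolute moderated t-statistic; requires an expression study).
#' @return A `walk_config` list.
#' @export
walk_config <- function(damping = 0.85, tol = 1e-10, max_iter = 10000L,
                        restart_mode = c("uniform", "expression")) {
  restart_mode <- match.arg(restart_mode)
  stopifnot(damping > 0, damping < 1, tol > 0, max_iter >= 1L)
  structure(list(damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 restart_mode = restart_mode), class = "walk_config")
}

#' Degree-biased column-stochastic transition matrix
#'
#' Entry `[v, u]` is the probability of stepping from `u` to `v`:
#' `deg(v) / sum of deg over u's neighbors` for `v` adjacent to `u`, 0
#' otherwise. Every column sums to 1. On a regular graph this reduces to the
#' plain uniform random walk.
#'
#' @param dcn a [gene_network()] with no isolated nodes (as produced by
#'   [build_dcn()]).
#' @return Dense numeric matrix with dimnames = node ids.
#' @export
degree_biased_transition <- function(dcn) {
  if (nrow(dcn$edges) == 0L) stop_an("DCN has no edges")
  g <- as_igraph(dcn)
  deg <- igraph::degree(g)
  if (any(deg == 0)) stop_an("DCN contains isolated node(s)")
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  # weight each potential target row v by deg(v), then normalize columns
  w <- adj * deg
  t(t(w) / colSums(w))
}

#' Restart probability vector over DCN nodes
#'
#' @param dcn a [gene_network()].
#' @param seeds a [gene_set()] of known disease genes.
#' @param mode `"uniform"` or `"expression"` (see [walk_config()]).
#' @param study an [expression_study()], required for `"expression"` mode;
#'   seed weights are `|moderated t|` from [run_diffexp()].
#' @return Named probability vector over DCN nodes (sums to 1; zero off the
#'   seeds).
#' @export
restart_vector <- function(dcn, seeds, mode = c("uniform", "expression"),
                           study = NULL) {
  mode <- match.arg(mode)
  present <- intersect(seeds$genes, dcn$nodes)
  if (length(present) == 0L) {
    stop_an("no seed gene is present in the DCN; missing: ",
            paste(utils::head(seeds$genes, 10L), collapse = ", "),
            if (length(seeds$genes) > 10L) ", ...")
  }
  r <- stats::setNames(numeric(length(dcn$nodes)), dcn$nodes)
  if (mode == "uniform") {
    r[present] <- 1 / length(present)
  } else {
    if (is.null(study)) stop_an("expression-weighted restart needs a study")
    deg_tab <- run_diffexp(study)
    w <- abs(deg_tab$t_mod[match(present, deg_tab$gene)])
    if (anyNA(w)) stop_an("seed gene(s) missing from the expression study")
    if (sum(w) == 0) w <- rep(1, length(w))
    r[present] <- w / sum(w)
  }
  r
}

#' Random-walk-with-restart scores and ranking
#'
#' Runs the power iteration `p <- damping * T p + (1 - damping) * r` from
#' `p0 = r` until the L1 change drops below `cfg$tol`. Deterministic; ties in
#' score are broken by lexicographic gene id.
#'
#' @param dcn a [gene_network()] from [build_dcn()].
#' @param seeds a [gene_set()] of known disease genes.
#' @param cfg a [walk_config()].
#' @param study optional [expression_study()] for expression-weighted restart.
#' @param keep_trace logical; if `TRUE`, attach the per-iteration probability
#'   sums as attribute `"trace"` (used to audit score conservation).
#' @return data.frame `(gene, score, rank, is_seed)` sorted by rank; scores
#'   sum to 1.
#' @export
random_walk_scores <- function(dcn, seeds, cfg = walk_config(), study = NULL,
                               keep_trace = FALSE) {
  tm <- degree_biased_transition(dcn)
  r <- restart_vector(dcn, seeds, mode = cfg$restart_mode, study = study)
  alpha <- cfg$damping
  p <- r
  trace <- if (keep_trace) numeric(0) else NULL
  for (it in seq_len(cfg$max_iter)) {
    p_new <- alpha * drop(tm %*% p) + (1 - alpha) * r
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (keep_trace) trace <- c(trace, sum(p))
    if (resid < cfg$tol) {
      ord <- order(-p, names(p))
      out <- data.frame(gene = names(p)[ord], score = unname(p[ord]),
                        rank = seq_along(p),
                        is_seed = names(p)[ord] %in% seeds$genes,
                        stringsAsFactors = FALSE)
      if (keep_trace) attr(out, "trace") <- trace
      return(out)
    }
  }
  stop_an("random walk did not converge in ", cfg$max_iter,
          " iterations (last L1 residual ", signif(resid, 3), ")")
}

#' Top-ranked candidate genes
#'
#' Seeds are not excluded (known disease genes may legitimately rank high);
#' they stay flagged via `is_seed` so callers can filter.
#'
#' @param ranking data.frame from [random_walk_scores()].
#' @param k number of genes to keep (default 100).
#' @return Character vector of the first `min(k, N)` genes by rank.
#' @export
top_candidates <- function(ranking, k = 100L) {
  stopifnot(k >= 1L)
  utils::head(ranking$gene, k)
}
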