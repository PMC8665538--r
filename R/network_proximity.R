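# Separation-score proximity between disease gene sets on the background PPI.
#
# The score for sets A and B is
#   s_AB = <d_AB> - (<d_AA> + <d_BB>) / 2
# where <d_AB> averages, over every gene of A and of B, the minimum
# shortest-path distance (unweighted hops) to the other set, and <d_AA>,
# <d_BB> average each gene's distance to the nearest *other* member of its
# own set. A gene belonging to both sets contributes 0 to <d_AB>. Small or
# negative s_AB means the two sets occupy overlapping network neighborhoods.

#' Restrict a gene set to the nodes of a network
#'
#' @param set a [gene_set()].
#' @param network a [gene_network()].
#' @return A [gene_set()] with the same name containing only genes present in
#'   the network. Errors if no gene survives (such a set has no defined
#'   network distances).
#' @export
restrict_to_network <- function(set, network) {
  keep <- intersect(set$genes, network$nodes)
  removed <- length(set$genes) - length(keep)
  if (length(keep) == 0L) {
    stop_an("gene set '", set$name, "' has no genes in the network")
  }
  if (removed > 0L) {
    an_log("set '", set$name, "': removed ", removed,
           " gene(s) not in the network")
  }
  gene_set(set$name, keep)
}

#' Minimum BFS distance from each source gene to a target set
#'
#' Distances are unweighted shortest-path hop counts (breadth-first search).
#' With `exclude_self = TRUE` a source that is itself a target may not use
#' itself (distance 0) as the target - used for within-set distances.
#'
#' @param network a [gene_network()].
#' @param sources,targets character vectors of gene ids, subsets of the
#'   network's nodes.
#' @param exclude_self logical, see above.
#' @return Named numeric vector over `sources`; `Inf` marks sources with no
#'   reachable permitted target (including the degenerate singleton case
#'   under `exclude_self`).
#' @export
min_distances_to_set <- function(network, sources, targets,
                                 exclude_self = FALSE) {
  stopifnot(all(sources %in% network$nodes), all(targets %in% network$nodes))
  if (length(targets) == 0L) {
    out <- rep(Inf, length(sources))
    names(out) <- sources
    return(out)
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = sources, to = targets, algorithm = "unweighted")
  if (exclude_self) {
    for (i in seq_along(sources)) {
      j <- match(sources[i], targets)
      if (!is.na(j)) d[i, j] <- Inf
    }
  }
  out <- apply(d, 1L, min)
  names(out) <- sources
  out
}

#' Mean cross-set distance \eqn{\langle d_{AB} \rangle}
#'
#' Averages, over all `|A| + |B|` contributions, each gene of A's minimum
#' distance to B and each gene of B's minimum distance to A. Genes shared by
#' both sets contribute 0 on both sides (self is a permitted target).
#' Unreachable contributions are excluded from the mean with a logged count.
#'
#' @param network a [gene_network()].
#' @param a,b [gene_set()] objects already restricted to the network.
#' @return Mean distance in hops.
#' @export
mean_cross_distance <- function(network, a, b) {
  da <- min_distances_to_set(network, a$genes, b$genes, exclude_self = FALSE)
  db <- min_distances_to_set(network, b$genes, a$genes, exclude_self = FALSE)
  contrib <- c(da, db)
  finite <- is.finite(contrib)
  if (!any(finite)) {
    stop_an("no finite cross distances between '", a$name, "' and '", b$name,
            "' (sets in disconnected components)")
  }
  if (any(!finite)) {
    an_log("cross distance ", a$name, "~", b$name, ": excluded ",
           sum(!finite), "/", length(contrib), " unreachable contribution(s)")
  }
  mean(contrib[finite])
}

#' Mean within-set distance \eqn{\langle d_{AA} \rangle}
#'
#' Averages each member gene's minimum distance to another (distinct) member.
#' A singleton set has no other member and is assigned 0 by convention, the
#' established single-gene-disease convention that keeps s_AB finite.
#' Unreachable members are excluded with a logged count.
#'
#' @param network a [gene_network()].
#' @param a a [gene_set()] restricted to the network.
#' @return Mean distance in hops.
#' @export
mean_within_distance <- function(network, a) {
  if (length(a$genes) == 1L) return(0)
  d <- min_distances_to_set(network, a$genes, a$genes, exclude_self = TRUE)
  finite <- is.finite(d)
  if (!any(finite)) return(0)
  if (any(!finite)) {
    an_log("within distance ", a$name, ": excluded ", sum(!finite), "/",
           length(d), " unreachable member(s)")
  }
  mean(d[finite])
}

#' Separation score between two disease gene sets
#'
#' @param network the background [gene_network()].
#' @param a,b [gene_set()] objects; genes outside the network are dropped via
#'   [restrict_to_network()].
#' @return A `separation_result` list: `set_a`, `set_b`, `d_ab`, `d_aa`,
#'   `d_bb`, `s_ab`, `n_a_in_network`, `n_b_in_network`, `n_shared`.
#' @examples
#' net <- gene_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
#' res <- separation_score(net, gene_set("X", c("A", "B")),
#'                         gene_set("Y", c("C", "D")))
#' res$s_ab # 1.5 - (1 + 1)/2 = 0.5
#' @export
separation_score <- function(network, a, b) {
  a <- restrict_to_network(a, network)
  b <- restrict_to_network(b, network)
  d_ab <- mean_cross_distance(network, a, b)
  d_aa <- mean_within_distance(network, a)
  d_bb <- mean_within_distance(network, b)
  structure(list(
    set_a = a$name, set_b = b$name,
    d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
    s_ab = d_ab - (d_aa + d_bb) / 2,
    n_a_in_network = length(a$genes),
    n_b_in_network = length(b$genes),
    n_shared = length(intersect(a$genes, b$genes))
  ), class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("s_AB(%s, %s) = %.4g  (d_AB=%.4g, d_AA=%.4g, d_BB=%.4g, shared=%d)\n",
              x$set_a, x$set_b, x$s_ab, x$d_ab, x$d_aa, x$d_bb, x$n_shared))
  invisible(x)
}

#' All-pairs separation scores for a collection of gene sets
#'
#' @param network the background [gene_network()].
#' @param sets list of [gene_set()] objects (at least 2).
#' @return A `proximity_matrix` list: `names` (set names in input order), `s`
#'   (symmetric matrix of s_AB; diagonal holds the self-score -<d_AA>),
#'   `mean_s` (per-set mean of off-diagonal s_AB), `pairs` (long-format
#'   data.frame of all unordered pairs with distance components and counts).
#' @export
proximity_matrix <- function(network, sets) {
  if (length(sets) < 2L) stop_an("need at least 2 gene sets")
  nms <- vapply(sets, function(s) s$name, "")
  if (anyDuplicated(nms)) stop_an("duplicate set names in collection")
  k <- length(sets)
  s <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      res <- tryCatch(
        separation_score(network, sets[[i]], sets[[j]]),
        error = function(e) stop_an("pair (", nms[i], ", ", nms[j], "): ",
                                    conditionMessage(e))
      )
      s[i, j] <- s[j, i] <- res$s_ab
      if (j > i) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_a = res$set_a, set_b = res$set_b, d_ab = res$d_ab,
          d_aa = res$d_aa, d_bb = res$d_bb, s_ab = res$s_ab,
          n_a = res$n_a_in_network, n_b = res$n_b_in_network,
          n_shared = res$n_shared, stringsAsFactors = FALSE)
      }
    }
  }
  mean_s <- vapply(seq_len(k), function(i) mean(s[i, -i]), 0)
  names(mean_s) <- nms
  structure(list(names = nms, s = s, mean_s = mean_s,
                 pairs = do.call(rbind, rows)),
            class = "proximity_matrix")
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat("proximity_matrix over", length(x$names), "sets\n")
  print(round(x$s, 4))
  invisible(x)
}
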