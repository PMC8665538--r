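# Ground-truth-bearing synthetic inputs.
#
# Emulates, at desk scale, the shape of the real inputs the analysis was
# designed for: a scale-free background PPI network, per-disease gene sets
# that are topologically localized modules with controllable pairwise
# overlap, and case/control expression with planted differential
# co-expression and planted differentially expressed driver genes. Every
# stage of the pipeline therefore has a recovery benchmark with known truth.
# All randomness flows from explicit seeds; the caller's RNG state is never
# disturbed.

#' Generate a scale-free background network by preferential attachment
#'
#' Barabasi-Albert-style growth: `edges_per_node` initial nodes, the first
#' added node links to all of them, every later node attaches
#' `edges_per_node` edges to distinct existing nodes sampled with
#' probability proportional to current degree. The result is connected with
#' exactly `(n_nodes - edges_per_node) * edges_per_node` edges.
#'
#' @param n_nodes number of genes (ids `G000001`, ...).
#' @param edges_per_node attachment parameter m.
#' @param seed integer RNG seed.
#' @return A [gene_network()].
#' @export
generate_ppi <- function(n_nodes, edges_per_node = 3L, seed = 1L) {
  m <- as.integer(edges_per_node)
  n <- as.integer(n_nodes)
  stopifnot(n >= m + 1L, m >= 1L)
  ids <- sprintf("G%06d", seq_len(n))
  with_seed(seed, {
    deg <- integer(n)
    from <- integer((n - m) * m)
    to <- integer((n - m) * m)
    k <- 0L
    # first incoming node connects to every initial node
    for (v in seq_len(m)) {
      k <- k + 1L
      from[k] <- m + 1L; to[k] <- v
      deg[v] <- deg[v] + 1L
    }
    deg[m + 1L] <- m
    for (u in seq.int(m + 2L, length.out = n - m - 1L)) {
      existing <- seq_len(u - 1L)
      tgt <- sample(existing, m, replace = FALSE, prob = deg[existing])
      for (v in tgt) {
        k <- k + 1L
        from[k] <- u; to[k] <- v
        deg[v] <- deg[v] + 1L
      }
      deg[u] <- m
    }
    gene_network(cbind(ids[from], ids[to]), nodes = ids)
  })
}

#' Plant topologically localized disease modules
#'
#' Each module is grown by seeded breadth-first expansion from a random
#' anchor, so its genes form a connected neighborhood (as curated disease
#' gene sets tend to). Pairs listed in `overlap_pairs` share exactly
#' `ceiling(overlap_fraction * module_size)` genes (the shared genes seed the
#' second module's growth); all other module pairs are disjoint by
#' construction.
#'
#' @param network a [gene_network()].
#' @param n_diseases number of modules (names `D1`, `D2`, ...).
#' @param module_size genes per module.
#' @param overlap_fraction per-designated-pair shared fraction in `[0, 1)`.
#' @param overlap_pairs two-column matrix of disease indices that overlap;
#'   default: the pair (1, 2) when `overlap_fraction > 0`, none otherwise.
#' @param seed integer RNG seed.
#' @return A `synthetic_truth` list: `modules` (named list of character
#'   vectors), `module_overlaps` (matrix of pairwise shared-gene counts),
#'   `planted_drivers`, `planted_dces`, `planted_degs` (per-disease lists,
#'   empty until [wire_drivers()]), `seed`.
#' @export
plant_modules <- function(network, n_diseases, module_size,
                          overlap_fraction = 0, overlap_pairs = NULL,
                          seed = 1L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  if (is.null(overlap_pairs)) {
    overlap_pairs <- if (overlap_fraction > 0 && n_diseases >= 2L) {
      matrix(c(1L, 2L), ncol = 2L)
    } else {
      matrix(integer(0), ncol = 2L)
    }
  }
  if (n_diseases * module_size > length(network$nodes)) {
    stop_an("modules do not fit in the network")
  }
  nbrs <- .adjacency_list(network)
  dnames <- paste0("D", seq_len(n_diseases))
  with_seed(seed, {
    modules <- vector("list", n_diseases)
    names(modules) <- dnames
    for (d in seq_len(n_diseases)) {
      shared <- character(0)
      partner_idx <- overlap_pairs[overlap_pairs[, 2L] == d, 1L]
      if (length(partner_idx)) {
        k_share <- ceiling(overlap_fraction * module_size)
        shared <- sample(modules[[partner_idx[1L]]], k_share)
      }
      # genes of other modules that are not designated-shared are forbidden,
      # which makes every overlap count exact
      forbidden <- setdiff(unlist(modules[seq_len(d - 1L)]), shared)
      members <- shared
      if (length(members) == 0L) {
        free <- setdiff(network$nodes, forbidden)
        members <- sample(free, 1L)
      }
      frontier <- members
      while (length(members) < module_size) {
        cand <- setdiff(unique(unlist(nbrs[frontier], use.names = FALSE)),
                        c(members, forbidden))
        if (length(cand) == 0L) {
          free <- setdiff(network$nodes, c(members, forbidden))
          if (length(free) == 0L) stop_an("insufficient nodes for modules")
          cand <- sample(free, 1L)
        }
        cand <- sample(cand, min(length(cand), module_size - length(members)))
        members <- c(members, cand)
        frontier <- cand
      }
      modules[[d]] <- members
    }
    ov <- matrix(0L, n_diseases, n_diseases, dimnames = list(dnames, dnames))
    for (i in seq_len(n_diseases)) {
      for (j in seq_len(n_diseases)) {
        ov[i, j] <- length(intersect(modules[[i]], modules[[j]]))
      }
    }
    empty <- stats::setNames(vector("list", n_diseases), dnames)
    structure(list(modules = modules, module_overlaps = ov,
                   planted_drivers = empty, planted_dces = empty,
                   planted_degs = empty, seed = seed),
              class = "synthetic_truth")
  })
}

#' @noRd
.adjacency_list <- function(network) {
  e <- network$edges
  nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
  missing <- setdiff(network$nodes, names(nb))
  if (length(missing)) {
    nb <- c(nb, stats::setNames(replicate(length(missing), character(0),
                                          simplify = FALSE), missing))
  }
  nb
}

#' Wire planted driver genes into each disease module
#'
#' Drivers are non-module genes adjacent to at least 3 module genes
#' (adjacency is created by adding network edges where no such gene exists).
#' Every driver-module edge (up to 10 per driver) is planted as a
#' differential co-expression edge, and each driver is added to the
#' disease's planted differentially expressed genes. The updated network is
#' returned alongside the truth because added edges must exist before
#' expression is generated.
#'
#' @param network a [gene_network()].
#' @param truth a `synthetic_truth` from [plant_modules()].
#' @param n_drivers_per_disease drivers to plant per disease.
#' @param seed integer RNG seed.
#' @return `list(network = updated network, truth = updated truth)`.
#' @export
wire_drivers <- function(network, truth, n_drivers_per_disease, seed = 1L) {
  if (n_drivers_per_disease == 0L) {
    return(list(network = network, truth = truth))
  }
  with_seed(seed, {
    new_edges <- list()
    all_module_genes <- unique(unlist(truth$modules))
    taken <- character(0)
    nbrs <- .adjacency_list(network)
    for (d in names(truth$modules)) {
      mod <- truth$modules[[d]]
      n_need <- n_drivers_per_disease
      # each module gene is claimed by at most one driver so every planted
      # correlation edge has its own target; cap targets per driver so the
      # module is never exhausted before the last driver
      cap <- max(3L, min(10L, length(mod) %/% n_need))
      if (length(mod) < 3L * n_need) stop_an("driver constraint unsatisfiable")
      pool <- setdiff(network$nodes, c(all_module_genes, taken))
      n_mod_nbrs <- vapply(pool, function(g) length(intersect(nbrs[[g]], mod)),
                           0L)
      ready <- pool[n_mod_nbrs >= 3L]
      drivers <- sample(ready, min(length(ready), n_need))
      extra <- n_need - length(drivers)
      if (extra > 0L) {
        # create adjacency by adding 3 module edges per remaining driver
        made <- sample(setdiff(pool, drivers), extra)
        drivers <- c(drivers, made)
      }
      if (length(drivers) < n_need) stop_an("driver constraint unsatisfiable")
      taken <- c(taken, drivers)
      claimed <- character(0)
      dces <- NULL
      for (g in drivers) {
        avail <- setdiff(intersect(nbrs[[g]], mod), claimed)
        avail <- avail[seq_len(min(length(avail), cap))]
        short <- 3L - length(avail)
        if (short > 0L) {
          fresh <- setdiff(mod, c(claimed, nbrs[[g]]))
          if (length(fresh) < short) stop_an("driver constraint unsatisfiable")
          fresh <- sample(fresh, short)
          new_edges[[length(new_edges) + 1L]] <-
            cbind(rep(g, short), fresh)
          nbrs[[g]] <- unique(c(nbrs[[g]], fresh))
          avail <- c(avail, fresh)
        }
        claimed <- c(claimed, avail)
        dces <- rbind(dces, cbind(rep(g, length(avail)), avail))
      }
      truth$planted_drivers[[d]] <- drivers
      truth$planted_dces[[d]] <- dces
      truth$planted_degs[[d]] <- unique(c(truth$planted_degs[[d]], drivers))
    }
    if (length(new_edges)) {
      network <- gene_network(rbind(network$edges, do.call(rbind, new_edges)),
                              nodes = network$nodes)
    }
    list(network = network, truth = truth)
  })
}

#' Generate case/control expression with planted structure
#'
#' Baseline log-intensities are i.i.d. Normal(8, sigma). For each planted
#' differential co-expression edge (source, target) of the chosen disease,
#' the target's case values are regressed onto the source's to achieve
#' expected Pearson correlation `r_signal` in cases only (controls stay
#' null); a target is re-wired at most once. Planted differentially
#' expressed genes (including drivers) receive a `+delta` case-group mean
#' shift, which leaves the planted correlations untouched.
#'
#' @param network a [gene_network()]; its nodes define the gene space.
#' @param truth a `synthetic_truth`.
#' @param disease disease name; defaults to the only/first disease.
#' @param n_case,n_control samples per group (>= 3).
#' @param r_signal planted case-group Pearson correlation, in (-1, 1).
#' @param delta case-minus-control mean shift for planted DEGs (log2 units).
#' @param sigma residual standard deviation (log2 units).
#' @param seed integer RNG seed.
#' @return An [expression_study()].
#' @export
generate_expression <- function(network, truth, disease = NULL,
                                n_case = 10L, n_control = 10L,
                                r_signal = 0.8, delta = 1.5, sigma = 0.5,
                                seed = 1L) {
  stopifnot(n_case >= 3L, n_control >= 3L, sigma > 0)
  if (abs(r_signal) >= 1) stop_an("r_signal must lie in (-1, 1)")
  if (is.null(disease)) disease <- names(truth$modules)[1L]
  genes <- network$nodes
  n <- n_case + n_control
  with_seed(seed, {
    vals <- matrix(stats::rnorm(length(genes) * n, mean = 8, sd = sigma),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    groups <- rep(c("case", "control"), c(n_case, n_control))
    case_cols <- which(groups == "case")
    dces <- truth$planted_dces[[disease]]
    if (!is.null(dces) && nrow(dces) > 0L) {
      planted_targets <- character(0)
      for (k in seq_len(nrow(dces))) {
        src <- dces[k, 1L]; tgt <- dces[k, 2L]
        if (tgt %in% planted_targets) next
        z <- scale(vals[src, case_cols])[, 1L]
        eps <- stats::rnorm(n_case)
        vals[tgt, case_cols] <- 8 + sigma *
          (r_signal * z + sqrt(1 - r_signal^2) * eps)
        planted_targets <- c(planted_targets, tgt)
      }
    }
    degs <- truth$planted_degs[[disease]]
    if (length(degs)) {
      vals[degs, case_cols] <- vals[degs, case_cols] + delta
    }
    expression_study(vals, groups)
  })
}

#' Annotation term sets derived from the planted truth
#'
#' One term per planted module (the module's genes plus `n_noise` random
#' background genes) plus `n_random_terms` terms of random genes, giving the
#' enrichment stage a benchmark where each disease's true term is known.
#'
#' @param truth a `synthetic_truth`.
#' @param network a [gene_network()].
#' @param n_noise random genes appended to each module term.
#' @param n_random_terms number of unrelated random terms.
#' @param random_term_size genes per random term.
#' @param seed integer RNG seed.
#' @return Named list of [gene_set()] objects.
#' @export
make_annotation_terms <- function(truth, network, n_noise = 10L,
                                  n_random_terms = 20L,
                                  random_term_size = 30L, seed = 1L) {
  with_seed(seed, {
    terms <- list()
    for (d in names(truth$modules)) {
      extra <- sample(setdiff(network$nodes, truth$modules[[d]]), n_noise)
      terms[[paste0("term_", d)]] <-
        gene_set(paste0("term_", d), c(truth$modules[[d]], extra))
    }
    for (i in seq_len(n_random_terms)) {
      nm <- sprintf("random_term_%02d", i)
      terms[[nm]] <- gene_set(nm, sample(network$nodes, random_term_size))
    }
    terms
  })
}

#' Full synthetic benchmark instance
#'
#' The default configuration is the package's standard recovery benchmark: a
#' 1000-node scale-free background (m = 3), 6 disease modules of 30 genes
#' with modules 1 and 2 sharing half their genes and all other pairs
#' disjoint, 5 planted drivers per disease, 10 case / 10 control samples per
#' disease, planted case-group correlation 0.8, DEG shift 1.5 log2 units and
#' residual sd 0.5.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param n_nodes,edges_per_node background-network parameters.
#' @param n_diseases,module_size,overlap_fraction module parameters.
#' @param n_drivers drivers per disease.
#' @param n_case,n_control,r_signal,delta,sigma expression parameters.
#' @return list with `network`, `truth`, `sets` (disease [gene_set()]s) and
#'   `studies` (named list of per-disease [expression_study()]s).
#' @export
synthetic_benchmark <- function(seed = 1L, n_nodes = 1000L,
                                edges_per_node = 3L, n_diseases = 6L,
                                module_size = 30L, overlap_fraction = 0.5,
                                n_drivers = 5L, n_case = 10L,
                                n_control = 10L, r_signal = 0.8,
                                delta = 1.5, sigma = 0.5) {
  seed <- as.integer(seed)
  net <- generate_ppi(n_nodes, edges_per_node, seed = seed)
  truth <- plant_modules(net, n_diseases, module_size,
                         overlap_fraction = overlap_fraction,
                         seed = seed + 1L)
  wired <- wire_drivers(net, truth, n_drivers, seed = seed + 2L)
  net <- wired$network
  truth <- wired$truth
  sets <- lapply(names(truth$modules), function(d) {
    gene_set(d, truth$modules[[d]])
  })
  names(sets) <- names(truth$modules)
  studies <- lapply(seq_along(sets), function(i) {
    generate_expression(net, truth, disease = names(sets)[i],
                        n_case = n_case, n_control = n_control,
                        r_signal = r_signal, delta = delta, sigma = sigma,
                        seed = seed + 10L + i)
  })
  names(studies) <- names(sets)
  list(network = net, truth = truth, sets = sets, studies = studies)
}
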