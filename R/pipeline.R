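# End-to-end orchestration: the cross-disease proximity study and the
# per-disease driver-prediction pipeline
#   restrict to network -> DCN -> seeds -> random walk -> top-k
#   -> DEG table -> final candidates = top-k DEGs,
# with every filter logged and every intermediate optionally materialized as
# TSV so stages are independently inspectable and resumable.

#' Pipeline configuration
#'
#' @param min_genes minimum gene-set size; smaller disease sets are excluded
#'   (default 20, inclusive boundary: a size-20 set is retained).
#' @param dce_alpha per-edge significance for DCE selection (default 0.05).
#' @param damping random-walk continuation probability (default 0.85).
#' @param top_k walk-ranking cutoff for preliminary candidates (default 100).
#' @param deg_alpha adjusted-p cutoff for DEGs (default 0.05).
#' @param dce_rule `"either"` or `"and"`, see
#'   [differential_coexpression_edges()].
#' @param restart_mode `"uniform"` or `"expression"`, see [walk_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_genes = 20L, dce_alpha = 0.05,
                            damping = 0.85, top_k = 100L, deg_alpha = 0.05,
                            dce_rule = "either", restart_mode = "uniform") {
  stopifnot(min_genes >= 1L, dce_alpha > 0, dce_alpha < 1,
            damping > 0, damping < 1, top_k >= 1L,
            deg_alpha > 0, deg_alpha < 1)
  structure(list(min_genes = as.integer(min_genes), dce_alpha = dce_alpha,
                 damping = damping, top_k = as.integer(top_k),
                 deg_alpha = deg_alpha, dce_rule = dce_rule,
                 restart_mode = restart_mode),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys are the arguments of [pipeline_config()] plus input paths
#' (`network`, `gene_sets`, `annotations`, and an `expression` map of
#' disease name to `matrix`/`design` paths), which are attached as the
#' `paths` attribute for [run_pipeline()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  cfg <- do.call(pipeline_config, args)
  attr(cfg, "paths") <- y[intersect(names(y), c("network", "gene_sets",
                                                "annotations", "expression"))]
  cfg
}

#' Drop disease gene sets below a size threshold
#'
#' @param sets list of [gene_set()] objects.
#' @param min_genes inclusive minimum size.
#' @return The retained sets, input order preserved.
#' @export
filter_gene_sets <- function(sets, min_genes = 20L) {
  sizes <- vapply(sets, function(s) length(s$genes), 0L)
  keep <- sizes >= min_genes
  if (!any(keep)) stop_an("all gene sets fall below min_genes = ", min_genes)
  if (any(!keep)) {
    an_log("excluded ", sum(!keep), " gene set(s) with fewer than ",
           min_genes, " genes (kept ", sum(keep), ")")
  }
  sets[keep]
}

# TSV writer used for all materialized outputs: 6 significant digits,
# header row, byte-stable ordering left to the caller
#' @noRd
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the driver-prediction pipeline for one disease
#'
#' Stages: restrict the disease set to the background network, build the
#' DCN, take the disease genes present in the DCN as seeds, run the
#' degree-biased random walk, keep the top-k genes, compute the DEG table,
#' and intersect. The subset chain (final candidates within top-k within DCN
#' nodes within network nodes) is asserted on every run. A `NULL` study
#' marks driver prediction "skipped" (a disease with no usable expression
#' series still takes part in the proximity study).
#'
#' @param network the background [gene_network()].
#' @param disease_set the disease [gene_set()].
#' @param study the disease's [expression_study()], or `NULL`.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, the DCN edge list, full
#'   ranking, DEG table and final candidate table are written as TSV.
#' @return A `disease_report` list: `disease`, `status` (`"ok"`/`"skipped"`),
#'   `dcn_nodes`, `dcn_edges`, `n_seeds`, `top_genes`, `n_deg`, `candidates`
#'   (data.frame with per-gene `score`, `rank`, `is_seed`, `t_mod`, `p_adj`),
#'   `ranking`, `deg_table`.
#' @export
run_disease <- function(network, disease_set, study, cfg = pipeline_config(),
                        out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_an("disease '", disease_set$name, "', stage ", name, ": ",
              conditionMessage(e))
    })
  }
  if (is.null(study)) {
    an_log("disease '", disease_set$name,
           "': no expression study; driver prediction skipped")
    return(structure(list(disease = disease_set$name, status = "skipped",
                          dcn_nodes = NA_integer_, dcn_edges = NA_integer_,
                          n_seeds = NA_integer_, top_genes = character(0),
                          n_deg = NA_integer_,
                          candidates = NULL, ranking = NULL,
                          deg_table = NULL),
                     class = "disease_report"))
  }
  restricted <- stage("restrict_to_network",
                      restrict_to_network(disease_set, network))
  dces <- stage("differential_coexpression_edges",
                differential_coexpression_edges(
                  study, network$edges, alpha = cfg$dce_alpha,
                  rule = cfg$dce_rule))
  dcn <- stage("build_dcn", build_dcn(network, dces))
  seed_genes <- intersect(restricted$genes, dcn$nodes)
  an_log("disease '", disease_set$name, "': ", length(seed_genes), " of ",
         length(restricted$genes), " disease genes present in the DCN")
  seeds <- stage("seed_extraction", {
    if (length(seed_genes) == 0L) stop_an("no disease gene in the DCN")
    gene_set(disease_set$name, seed_genes)
  })
  wcfg <- walk_config(damping = cfg$damping, restart_mode = cfg$restart_mode)
  ranking <- stage("random_walk_scores",
                   random_walk_scores(dcn, seeds, wcfg, study = study))
  top <- top_candidates(ranking, cfg$top_k)
  deg_table <- stage("diffexp", run_diffexp(study, threshold = cfg$deg_alpha))
  degs <- deg_table$gene[deg_table$is_deg]
  final <- top[top %in% degs]

  # structural subset chain, asserted on every run
  stopifnot(all(final %in% top), all(top %in% dcn$nodes),
            all(dcn$nodes %in% network$nodes))

  candidates <- data.frame(
    gene = final,
    score = ranking$score[match(final, ranking$gene)],
    rank = ranking$rank[match(final, ranking$gene)],
    is_seed = ranking$is_seed[match(final, ranking$gene)],
    t_mod = deg_table$t_mod[match(final, deg_table$gene)],
    p_adj = deg_table$p_adj[match(final, deg_table$gene)],
    stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$rank), , drop = FALSE]
  rownames(candidates) <- NULL

  report <- structure(list(
    disease = disease_set$name, status = "ok",
    dcn_nodes = length(dcn$nodes), dcn_edges = nrow(dcn$edges),
    n_seeds = length(seed_genes), top_genes = top,
    n_deg = length(degs), candidates = candidates,
    ranking = ranking, deg_table = deg_table), class = "disease_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(out_dir, disease_set$name)
    .write_tsv(attr(dcn, "provenance"), paste0(pre, "_dcn.tsv"))
    .write_tsv(ranking, paste0(pre, "_ranking.tsv"))
    .write_tsv(deg_table, paste0(pre, "_deg.tsv"))
    .write_tsv(candidates, paste0(pre, "_candidates.tsv"))
  }
  report
}

#' @export
print.disease_report <- function(x, ...) {
  cat("disease_report '", x$disease, "' [", x$status, "]\n", sep = "")
  if (x$status == "ok") {
    cat("  DCN:", x$dcn_nodes, "nodes /", x$dcn_edges, "edges;",
        x$n_seeds, "seeds\n")
    cat("  top-ranked genes kept:", length(x$top_genes),
        "; DEGs:", x$n_deg, "; final candidates:", nrow(x$candidates), "\n")
  }
  invisible(x)
}

#' Run the cross-disease proximity study
#'
#' Filters the disease sets by size, restricts each to the network and
#' computes all pairwise separation scores, per-set mean scores and each
#' set's closest partner.
#'
#' @param network the background [gene_network()].
#' @param sets list of disease [gene_set()] objects.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for TSV output (long-format pairs,
#'   square matrix, per-set means).
#' @return A `proximity_matrix` (see [proximity_matrix()]) with an extra
#'   `closest` element: data.frame `(set, partner, s_ab)` of each set's
#'   minimum-s partner.
#' @export
run_proximity_study <- function(network, sets, cfg = pipeline_config(),
                                out_dir = NULL) {
  sets <- filter_gene_sets(sets, cfg$min_genes)
  if (length(sets) < 2L) stop_an("need at least 2 retained sets")
  sets <- lapply(sets, restrict_to_network, network = network)
  pm <- proximity_matrix(network, sets)
  k <- length(pm$names)
  closest <- data.frame(
    set = pm$names,
    partner = vapply(seq_len(k), function(i) {
      off <- stats::setNames(pm$s[i, ], pm$names)[-i]
      names(off)[which.min(off)]
    }, ""),
    s_ab = vapply(seq_len(k), function(i) min(pm$s[i, -i]), 0),
    stringsAsFactors = FALSE)
  pm$closest <- closest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(pm$pairs, file.path(out_dir, "separation_pairs.tsv"))
    sq <- data.frame(set = pm$names, signif(pm$s, 6L),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(sq, file.path(out_dir, "separation_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_tsv(data.frame(set = pm$names, mean_s = pm$mean_s),
               file.path(out_dir, "separation_means.tsv"))
    .write_tsv(closest, file.path(out_dir, "closest_partners.tsv"))
  }
  pm
}

#' Run the full analysis from a YAML configuration
#'
#' Reads the background network, the disease gene sets and each disease's
#' expression study from the paths in the configuration, runs the proximity
#' study across all size-filtered diseases, then the driver-prediction
#' pipeline per disease (diseases without expression entries are skipped),
#' writing all intermediates under `out_dir`.
#'
#' @param config path to a YAML file (see [read_pipeline_config()]) or a
#'   `pipeline_config` carrying a `paths` attribute.
#' @param out_dir output directory.
#' @return list with `proximity` and `reports` (named list of
#'   `disease_report`s).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else {
    read_pipeline_config(config)
  }
  paths <- attr(cfg, "paths")
  if (is.null(paths$network) || is.null(paths$gene_sets)) {
    stop_an("configuration must provide 'network' and 'gene_sets' paths")
  }
  network <- read_edge_list(paths$network)
  sets <- read_gmt(paths$gene_sets)
  sets <- filter_gene_sets(sets, cfg$min_genes)
  proximity <- run_proximity_study(network, sets, cfg, out_dir = out_dir)
  reports <- lapply(names(sets), function(d) {
    ep <- paths$expression[[d]]
    study <- if (is.null(ep)) NULL else read_expression(ep$matrix, ep$design)
    run_disease(network, sets[[d]], study, cfg, out_dir = out_dir)
  })
  names(reports) <- names(sets)
  list(proximity = proximity, reports = reports)
}
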