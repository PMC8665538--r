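# Domain containers and the plain-text formats every other module consumes.
#
# Gene identifiers are opaque, case-sensitive strings throughout: no
# symbol/probe/Entrez mapping is attempted, identifier harmonization belongs
# to data preparation upstream of this package.

#' Construct an undirected, unweighted gene network
#'
#' The container used for both the background protein-protein interaction
#' (PPI) network and differential co-expression networks (DCNs). Edges are
#' canonicalized (lexicographically smaller identifier first), self-loops are
#' dropped and duplicate/reversed edges collapsed. All edges carry implicit
#' weight 1.
#'
#' @param edges two-column character matrix or data.frame of edge endpoints.
#' @param nodes optional character vector of node identifiers; node ids
#'   appearing only here (and not in `edges`) are retained as isolated nodes.
#' @return An object of class `gene_network` with elements `nodes` (character
#'   vector) and `edges` (two-column character matrix, canonical orientation,
#'   no duplicates, no self-loops).
#' @examples
#' net <- gene_network(rbind(c("A", "B"), c("B", "A"), c("C", "C")))
#' net$edges # single canonical edge A-B; node C kept isolated
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    if (ncol(edges) < 2L) stop_an("edge table must have at least two columns")
    em <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  }
  endpoint_ids <- unique(as.vector(em))
  keep <- em[, 1L] != em[, 2L]
  n_loops <- sum(!keep)
  em <- em[keep, , drop = FALSE]
  # canonical orientation, then dedupe
  a <- pmin(em[, 1L], em[, 2L])
  b <- pmax(em[, 1L], em[, 2L])
  key <- paste(a, b, sep = "\t")
  dup <- duplicated(key)
  em <- cbind(a[!dup], b[!dup])
  if (n_loops > 0L || any(dup)) {
    an_log("dropped ", n_loops, " self-loop(s) and ", sum(dup),
           " duplicate edge record(s)")
  }
  all_nodes <- unique(c(as.character(nodes), endpoint_ids))
  structure(list(nodes = all_nodes, edges = em), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges in a gene network
#' @param network a [gene_network()].
#' @return Integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Convert a gene network to an igraph object
#'
#' Isolated nodes are preserved as degree-0 vertices.
#'
#' @param network a [gene_network()].
#' @return An undirected `igraph` graph whose vertex names are gene ids.
#' @export
as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges) > 0L) {
    g <- igraph::add_edges(g, t(network$edges))
  }
  g
}

#' Construct a named gene set
#'
#' @param name set label (e.g. a disease subtype).
#' @param genes character vector of gene identifiers; duplicates collapsed.
#' @return An object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop_an("gene set '", name, "' is empty")
  structure(list(name = as.character(name)[1L], genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Construct a case/control expression study
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Assumed log-scale after normalization
#'   (see [maybe_log2()]).
#' @param groups character/factor of per-sample labels, values in
#'   `c("case", "control")`, same length/order as `ncol(values)`.
#' @return An object of class `expression_study` with elements `values`,
#'   `genes`, `samples`, `groups`.
#' @export
expression_study <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_an("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_an("duplicate gene ids in matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop_an("one group label per sample required")
  }
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad)) {
    stop_an("group labels must be 'case'/'control'; found: ",
            paste(bad, collapse = ", "))
  }
  tab <- table(factor(groups, levels = c("case", "control")))
  if (any(tab < 3L)) {
    stop_an("need at least 3 samples per group (have case=", tab[["case"]],
            ", control=", tab[["control"]], ")")
  }
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values), groups = groups),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control )\n")
  invisible(x)
}

#' Read an undirected edge list from TSV
#'
#' First two tab-separated columns are gene identifiers; extra columns are
#' ignored. Lines starting with `#` and blank lines are skipped. Self-loops
#' and duplicate/reversed edges are collapsed with a logged count.
#'
#' @param path file path.
#' @param header logical; if `TRUE` the first (non-comment) line is skipped.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (length(lines) == 0L) stop_an("edge list '", path, "' has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_an("edge list '", path, "' line ", line_no[which(nf < 2L)[1L]],
            ": fewer than 2 columns")
  }
  em <- cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
  gene_network(em)
}

#' Write a gene network as a two-column TSV edge list
#'
#' Edges are written in canonical orientation and lexicographic order, so
#' output is byte-stable across runs. Isolated nodes are not representable in
#' an edge list and are omitted.
#'
#' @param network a [gene_network()].
#' @param path output file path.
#' @param header logical; write a `gene_a<TAB>gene_b` header line.
#' @export
write_edge_list <- function(network, path, header = TRUE) {
  em <- network$edges
  ord <- order(em[, 1L], em[, 2L])
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("gene_a\tgene_b", con)
  if (nrow(em)) {
    writeLines(paste(em[ord, 1L], em[ord, 2L], sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path file path.
#' @return Named list of [gene_set()] objects (names = set names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_an("GMT file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_an("GMT file '", path, "' line ", which(nf < 3L)[1L],
            ": fewer than 3 fields")
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop_an("GMT file '", path, "': duplicate set name '",
            nms[duplicated(nms)][1L], "'")
  }
  sets <- lapply(fields, function(f) gene_set(f[[1L]], f[-(1:2)]))
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to `"."`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep(".", length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s$name, d, s$genes), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix and its case/control design
#'
#' The matrix TSV has a header row of sample ids and gene ids in the first
#' column. The design TSV has columns `sample_id` and `group` with group in
#' `c("case", "control")`. Samples keep the matrix column order. Genes with
#' any missing value are dropped (logged); duplicate gene ids are collapsed
#' by keeping the row with the highest mean intensity (the common
#' probe-collapse convention).
#'
#' @param matrix_path path to the expression TSV.
#' @param design_path path to the two-column design TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, design_path) {
  mat <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop_an("expression matrix needs gene + sample columns")
  gene_ids <- as.character(mat[[1L]])
  values <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  design <- utils::read.delim(design_path, header = TRUE,
                              stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop_an("design file needs columns 'sample_id' and 'group'")
  }
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing)) {
    stop_an("sample(s) in matrix missing from design: ",
            paste(missing, collapse = ", "))
  }
  groups <- design$group[match(colnames(values), design$sample_id)]

  ok <- stats::complete.cases(values)
  if (any(!ok)) {
    an_log("dropped ", sum(!ok), " gene(s) with missing values")
    values <- values[ok, , drop = FALSE]
    gene_ids <- gene_ids[ok]
  }
  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(values)
    ord <- order(gene_ids, -means)
    keep <- ord[!duplicated(gene_ids[ord])]
    keep <- sort(keep)
    an_log("collapsed ", length(gene_ids) - length(keep),
           " duplicate gene row(s) (kept highest-mean row)")
    values <- values[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  rownames(values) <- gene_ids
  expression_study(values, groups)
}
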