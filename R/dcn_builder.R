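# Differential co-expression network (DCN) construction.
#
# For one disease, Pearson correlations of candidate gene pairs are computed
# separately in case and control samples; pairs with p < alpha in either
# group are differential co-expression edges (DCEs), and the DCN is the
# intersection of the DCEs with the background PPI edges, all weights 1.
# Correlations are computed only for PPI candidate edges, never all pairs:
# since the DCN is the intersection with the PPI anyway, restricting first is
# mathematically equivalent and reduces cost from O(G^2) to O(|E|).

#' Pearson correlation with a two-sided t-test p-value
#'
#' p is the two-sided tail probability of `t = r * sqrt((n-2)/(1-r^2))` under
#' a t distribution with n-2 degrees of freedom; `|r| = 1` gives p = 0 by
#' convention. A constant vector has no defined correlation and returns the
#' `NA` sentinel (the pair is then treated as not significant rather than
#' aborting a run on one flat probe).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return Named numeric vector `c(r = , p = )`; both `NA` for a constant
#'   input vector.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  c(r = r, p = .cor_pval(r, n))
}

# vectorized two-sided p for Pearson r at sample size n
#' @noRd
.cor_pval <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  exact <- ok & abs(r) >= 1
  p[exact] <- 0
  mid <- ok & !exact
  tstat <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

# Pearson r for many row pairs of a matrix at once (rows = genes).
# Returns NA for pairs involving a constant gene.
#' @noRd
.row_pair_cor <- function(mat, i, j) {
  n <- ncol(mat)
  ctr <- mat - rowMeans(mat)
  ss <- sqrt(rowSums(ctr^2))
  num <- rowSums(ctr[i, , drop = FALSE] * ctr[j, , drop = FALSE])
  den <- ss[i] * ss[j]
  r <- ifelse(den > 0, num / den, NA_real_)
  # numerical guard: clamp to [-1, 1]
  pmin(1, pmax(-1, r))
}

#' Select differential co-expression edges
#'
#' For each candidate edge, Pearson r and p are computed separately within
#' case and control samples; an edge is selected when `p_case < alpha` OR
#' `p_control < alpha` (significant in at least one condition). Set
#' `rule = "and"` to require significance in both conditions instead (a
#' sensitivity-analysis option; "either" is the default behavior).
#'
#' @param study an [expression_study()].
#' @param candidate_edges two-column character matrix of gene pairs (normally
#'   the background PPI edges). Pairs with a gene absent from the study are
#'   skipped with a logged count.
#' @param alpha per-edge significance level (default 0.05, uncorrected: one
#'   raw threshold per group, no multiple-testing adjustment).
#' @param rule `"either"` (default) or `"and"`.
#' @return A data.frame of selected edges with columns `gene_i`, `gene_j`
#'   (canonical orientation, gene_i < gene_j), `r_case`, `p_case`,
#'   `r_control`, `p_control`.
#' @export
differential_coexpression_edges <- function(study, candidate_edges,
                                            alpha = 0.05,
                                            rule = c("either", "and")) {
  rule <- match.arg(rule)
  em <- candidate_edges
  if (is.data.frame(em)) em <- as.matrix(em)
  a <- pmin(em[, 1L], em[, 2L])
  b <- pmax(em[, 1L], em[, 2L])
  present <- a %in% study$genes & b %in% study$genes
  if (!any(present)) {
    stop_an("no candidate edge has both genes measured in the study")
  }
  if (any(!present)) {
    an_log("skipped ", sum(!present),
           " candidate edge(s) with unmeasured gene(s)")
  }
  a <- a[present]; b <- b[present]
  i <- match(a, study$genes)
  j <- match(b, study$genes)
  case <- study$values[, study$groups == "case", drop = FALSE]
  ctrl <- study$values[, study$groups == "control", drop = FALSE]
  r_case <- .row_pair_cor(case, i, j)
  r_ctrl <- .row_pair_cor(ctrl, i, j)
  p_case <- .cor_pval(r_case, ncol(case))
  p_ctrl <- .cor_pval(r_ctrl, ncol(ctrl))
  sig_case <- !is.na(p_case) & p_case < alpha
  sig_ctrl <- !is.na(p_ctrl) & p_ctrl < alpha
  sel <- if (rule == "either") sig_case | sig_ctrl else sig_case & sig_ctrl
  data.frame(gene_i = a[sel], gene_j = b[sel],
             r_case = r_case[sel], p_case = p_case[sel],
             r_control = r_ctrl[sel], p_control = p_ctrl[sel],
             stringsAsFactors = FALSE)
}

#' Build the differential co-expression network
#'
#' Intersects selected DCEs with the background PPI edge set; every retained
#' edge gets weight 1. Nodes are the endpoints of retained edges only, so the
#' DCN never carries isolated genes into the random walk.
#'
#' @param ppi the background [gene_network()].
#' @param dces data.frame from [differential_coexpression_edges()] (or any
#'   table whose first two columns are gene pairs).
#' @return A [gene_network()] with a `provenance` attribute holding the
#'   per-edge correlation records of the retained edges.
#' @export
build_dcn <- function(ppi, dces) {
  a <- pmin(dces[[1L]], dces[[2L]])
  b <- pmax(dces[[1L]], dces[[2L]])
  key <- paste(a, b, sep = "\t")
  ppi_key <- paste(ppi$edges[, 1L], ppi$edges[, 2L], sep = "\t")
  keep <- key %in% ppi_key
  if (!any(keep)) stop_an("DCE / PPI edge intersection is empty")
  dcn <- gene_network(cbind(a[keep], b[keep]))
  attr(dcn, "provenance") <- dces[keep, , drop = FALSE]
  dcn
}
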