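#' Min-max normalize an objective matrix
#'
#' Each objective is mapped to `(J - min) / (max - min)` over the supplied
#' front; a degenerate dimension (`min == max`) maps to 0.  Without this
#' step the raw scale of the first objective (pertinency range up to 200)
#' would drown the second (up to 20) in any Euclidean computation.
#'
#' @param J numeric matrix, one row per solution.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_front <- function(J) {
  J <- as.matrix(J)
  if (!nrow(J)) return(J)
  lo <- apply(J, 2, min)
  rng <- apply(J, 2, max) - lo
  Jn <- sweep(J, 2, lo)
  for (j in seq_len(ncol(J)))
    Jn[, j] <- if (rng[j] > 0) Jn[, j] / rng[j] else 0
  Jn
}

#' Agglomerative cluster tree over the Pareto front
#'
#' Hierarchical clustering of the solutions using the Euclidean distance
#' between their normalized objective vectors and weighted-centroid
#' (median/WPGMC) linkage.  Optionally the normalized decision variables
#' can be appended to the feature space.
#'
#' @param front objective matrix (n x 2) or a `pareto_approx`.
#' @param features `"objectives"` (default: the distance is computed on the
#'   attained objective values) or `"both"` (append normalized parameters).
#' @param theta decision matrix, required for `features = "both"`.
#' @return An [stats::hclust] tree (fitted on squared Euclidean distances,
#'   as weighted-centroid linkage requires); the normalized feature matrix
#'   is attached as attribute `features`.
#' @export
cluster_tree <- function(front, features = c("objectives", "both"),
                         theta = NULL) {
  features <- match.arg(features)
  if (inherits(front, "pareto_approx")) {
    theta <- front$theta
    front <- front$J
  }
  front <- as.matrix(front)
  if (nrow(front) < 2)
    stop("cluster_tree(): need at least 2 solutions", call. = FALSE)
  X <- normalize_front(front)
  if (features == "both") {
    if (is.null(theta))
      stop("cluster_tree(): theta required for features = 'both'",
           call. = FALSE)
    X <- cbind(X, normalize_front(as.matrix(theta)))
  }
  tree <- hclust(dist(X)^2, method = "median")
  attr(tree, "features") <- X
  tree
}

#' Kruskal-Wallis rank test of a parameter across clusters
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with k-1 degrees of freedom) with the
#' degenerate all-identical case mapped to `H = 0, p = 1`.
#'
#' @param values per-solution parameter values.
#' @param labels cluster labels (coerced to factor).
#' @return List with `H` and `p`.
#' @export
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))  # H = 3.857
kw_test <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("kw_test(): need at least 2 groups", call. = FALSE)
  if (any(table(labels) == 0))
    stop("kw_test(): empty group", call. = FALSE)
  if (length(values) != length(labels))
    stop("kw_test(): length mismatch", call. = FALSE)
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Select the cluster count by Kruskal-Wallis significance maximization
#'
#' Cuts the tree into k clusters for k from ten (capped at n-1) down to
#' two; at each k a Kruskal-Wallis test per decision variable asks whether
#' that variable's values differ across clusters.  The selected k maximizes
#' the number of significantly associated variables; ties break toward the
#' smallest k (the coarsest clustering that explains as much).
#'
#' @param tree a [cluster_tree()].
#' @param theta decision matrix (n solutions x p variables).
#' @param alpha significance level (default 0.05).
#' @param k_max largest cluster count tried (default 10).
#' @return An object of class `clustering_result`: list with `k`, `labels`,
#'   `tree`, `counts` (significant variables per k) and `kw` (long
#'   data.frame of per-k, per-variable H and p).
#' @export
select_k <- function(tree, theta, alpha = 0.05, k_max = 10) {
  theta <- as.matrix(theta)
  n <- nrow(theta)
  if (n < 3)
    stop("select_k(): need at least 3 solutions", call. = FALSE)
  ks <- 2:min(k_max, n - 1)
  pnames <- colnames(theta) %||% paste0("theta", seq_len(ncol(theta)))
  rows <- list()
  counts <- integer(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    labels <- cutree(tree, k = k)
    res <- lapply(seq_len(ncol(theta)), function(j)
      kw_test(theta[, j], labels))
    p <- vapply(res, `[[`, numeric(1), "p")
    H <- vapply(res, `[[`, numeric(1), "H")
    counts[i] <- sum(p < alpha)
    rows[[i]] <- data.frame(k = k, parameter = pnames, H = H, p = p,
                            stringsAsFactors = FALSE)
  }
  best <- ks[which.max(counts)]   # ties break toward the smallest k
  structure(list(k = best, labels = cutree(tree, k = best), tree = tree,
                 counts = setNames(counts, ks), kw = do.call(rbind, rows),
                 alpha = alpha),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result> k = %d (significant parameters per k: %s)\n",
    x$k, paste(sprintf("%s:%d", names(x$counts), x$counts),
               collapse = ", ")))
  invisible(x)
}

#' Extract wet-lab tuning guidelines from a clustered Pareto set
#'
#' Classifies every decision variable by its behavior over the Pareto set:
#' \describe{
#'   \item{cluster-specific}{Kruskal-Wallis significant at `alpha`: the
#'     variable takes different ranges in different clusters and is a
#'     trade-off tuning knob; per-cluster ranges are reported.}
#'   \item{general}{not significant, but the optimized overall range has
#'     shrunk to at most `shrink` times the initial search interval: the
#'     optimizer found a range required for optimality in all clusters.}
#'   \item{unconstrained}{not significant and not shrunk: the variable has
#'     no apparent effect within its bounds.}
#' }
#'
#' @param clustering a [select_k()] result.
#' @param theta decision matrix aligned with the clustering labels.
#' @param bounds data.frame as [decision_bounds()] (rows matching the
#'   columns of `theta`).
#' @param alpha significance level (default 0.05).
#' @param shrink width ratio below which a non-significant variable counts
#'   as a general guideline (default 0.6).
#' @return An object of class `guideline_report`: a data.frame with one row
#'   per variable (`parameter`, `class`, `p`, `lower0`, `upper0`,
#'   `overall_lo`, `overall_hi`) plus a `cluster_ranges` attribute (list of
#'   per-cluster `lo`/`hi` matrices) and the settings used.
#' @export
extract_guidelines <- function(clustering, theta,
                               bounds = decision_bounds(), alpha = 0.05,
                               shrink = 0.6) {
  theta <- as.matrix(theta)
  labels <- clustering$labels
  if (length(labels) != nrow(theta))
    stop("extract_guidelines(): clustering and theta are inconsistent",
         call. = FALSE)
  pnames <- colnames(theta) %||% bounds$parameter
  stopifnot(length(pnames) == nrow(bounds))
  k <- clustering$k
  cls <- character(length(pnames))
  pval <- numeric(length(pnames))
  olo <- ohi <- numeric(length(pnames))
  clo <- chi <- matrix(NA_real_, length(pnames), k,
                       dimnames = list(pnames, paste0("cluster", 1:k)))
  for (j in seq_along(pnames)) {
    v <- theta[, j]
    pval[j] <- kw_test(v, labels)$p
    olo[j] <- min(v); ohi[j] <- max(v)
    for (g in seq_len(k)) {
      clo[j, g] <- min(v[labels == g])
      chi[j, g] <- max(v[labels == g])
    }
    width0 <- bounds$upper[j] - bounds$lower[j]
    cls[j] <- if (pval[j] < alpha) "cluster-specific"
    else if ((ohi[j] - olo[j]) <= shrink * width0) "general"
    else "unconstrained"
  }
  rep <- data.frame(parameter = pnames, class = cls, p = pval,
                    lower0 = bounds$lower, upper0 = bounds$upper,
                    overall_lo = olo, overall_hi = ohi,
                    stringsAsFactors = FALSE)
  structure(rep, class = c("guideline_report", "data.frame"),
            cluster_ranges = list(lo = clo, hi = chi), k = k,
            alpha = alpha, shrink = shrink)
}

#' @export
print.guideline_report <- function(x, digits = 4, ...) {
  cr <- attr(x, "cluster_ranges")
  k <- attr(x, "k")
  cat(sprintf("<guideline_report> %d parameters, k = %d clusters\n",
              nrow(x), k))
  for (i in seq_len(nrow(x))) {
    extra <- if (x$class[i] == "cluster-specific")
      paste(vapply(seq_len(k), function(g)
        sprintf("C%d [%.4g, %.4g]", g, cr$lo[i, g], cr$hi[i, g]),
        character(1)), collapse = "  ")
    else sprintf("[%.4g, %.4g]", x$overall_lo[i], x$overall_hi[i])
    cat(sprintf("  %-9s %-16s %s\n", x$parameter[i], x$class[i], extra))
  }
  invisible(x)
}

#' Flatten a guideline report for CSV export
#'
#' One row per parameter with the initial interval, the general-guideline
#' range (non-significant parameters) and per-cluster ranges (trade-off
#' knobs) rendered as `[lo, hi]` strings, mirroring the usual tabular
#' presentation of design guidelines.
#'
#' @param report a [extract_guidelines()] result.
#' @return A plain data.frame.
#' @export
format_guidelines <- function(report) {
  cr <- attr(report, "cluster_ranges")
  k <- attr(report, "k")
  fmt <- function(lo, hi) sprintf("[%.6g, %.6g]", lo, hi)
  out <- data.frame(
    parameter = report$parameter,
    initial_range = fmt(report$lower0, report$upper0),
    class = report$class,
    p_value = report$p,
    general_guideline = ifelse(report$class == "cluster-specific", "-",
                               fmt(report$overall_lo, report$overall_hi)),
    stringsAsFactors = FALSE)
  for (g in seq_len(k)) {
    col <- ifelse(report$class == "cluster-specific",
                  fmt(cr$lo[, g], cr$hi[, g]), "-")
    out[[paste0("cluster", g)]] <- col
  }
  out
}
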