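#' p-norm scores for Level Diagrams
#'
#' The Level-Diagram score of a solution is the p-norm of its normalized
#' objective vector: the distance to the ideal point of the front.  The
#' same score is used as the Y coordinate in every sub-plot (objective
#' views and decision-variable views), so a solution sits at the same
#' height everywhere.
#'
#' @param Jn normalized objective matrix (entries in `[0, 1]`, see
#'   [normalize_front()]).
#' @param p norm order, `>= 1`; `Inf` gives the maximum coordinate.
#' @return Numeric vector of scores, one per row.
#' @export
#' @examples
#' ld_scores(rbind(c(0, 0), c(1, 1)), p = 2)  # 0, sqrt(2)
ld_scores <- function(Jn, p = 2) {
  Jn <- as.matrix(Jn)
  if (!is.finite(p) && !is.infinite(p)) stop("ld_scores(): bad norm order")
  if (p < 1) stop("ld_scores(): norm order must be >= 1", call. = FALSE)
  if (any(Jn < -1e-12 | Jn > 1 + 1e-12))
    stop("ld_scores(): input must be normalized to [0, 1]", call. = FALSE)
  if (is.infinite(p)) return(apply(Jn, 1, max))
  rowSums(Jn^p)^(1 / p)
}

#' Cluster-annotated Level-Diagram table
#'
#' Builds the data behind a Level-Diagram visualization of a Pareto
#' approximation: per solution its cluster membership, p-norm score, raw and
#' normalized objectives and the decision variables.  Plotting is optional
#' (see [plot_level_diagram()]); the table is the canonical artifact.
#'
#' @param pareto a `pareto_approx`.
#' @param clustering optional [select_k()] result aligned with the front;
#'   without it every solution gets cluster 1.
#' @param p norm order for [ld_scores()] (default 2).
#' @return An object of class `level_diagram` (a data.frame): columns
#'   `solution`, `cluster`, `score`, `J1`, `J2`, `J1_norm`, `J2_norm`, then
#'   one column per decision variable.
#' @export
level_diagram <- function(pareto, clustering = NULL, p = 2) {
  n <- nrow(pareto$J)
  cl <- if (is.null(clustering)) rep(1L, n) else clustering$labels
  if (length(cl) != n)
    stop("level_diagram(): clustering is inconsistent with the front",
         call. = FALSE)
  Jn <- normalize_front(pareto$J)
  out <- cbind(
    data.frame(solution = seq_len(n), cluster = as.integer(cl),
               score = ld_scores(Jn, p = p),
               J1 = pareto$J[, 1], J2 = pareto$J[, 2],
               J1_norm = Jn[, 1], J2_norm = Jn[, 2]),
    as.data.frame(pareto$theta))
  structure(out, class = c("level_diagram", "data.frame"), p = p)
}

#' Write / read a Level-Diagram table
#'
#' CSV round trip for [level_diagram()] tables.
#'
#' @param ld a `level_diagram` table.
#' @param path CSV file path.
#' @return `write_level_diagram()` returns `path` invisibly;
#'   `read_level_diagram()` returns the table.
#' @export
write_level_diagram <- function(ld, path) {
  write.csv(as.data.frame(ld), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_level_diagram
#' @export
read_level_diagram <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  structure(out, class = c("level_diagram", "data.frame"))
}

#' Plot a Level Diagram
#'
#' One panel per requested column (objective or decision variable), X axis
#' the raw value, Y axis the shared p-norm score, points colored by
#' cluster.
#'
#' @param ld a [level_diagram()] table.
#' @param columns columns to plot (default: `J1`, `J2`).
#' @param ... passed to [graphics::plot()].
#' @return `ld`, invisibly.
#' @export
plot_level_diagram <- function(ld, columns = c("J1", "J2"), ...) {
  cols <- grDevices::hcl.colors(max(ld$cluster), "Dark 3")
  old <- graphics::par(mfrow = c(1, length(columns)))
  on.exit(graphics::par(old))
  for (cn in columns) {
    graphics::plot(ld[[cn]], ld$score, col = cols[ld$cluster], pch = 19,
                   xlab = cn, ylab = sprintf("||J||_%s", attr(ld, "p")),
                   ...)
  }
  invisible(ld)
}
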