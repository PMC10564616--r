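# Link-percolation robustness analysis: edges are removed uniformly at random
# in fixed-size steps while the size of the largest connected component (the
# giant component) is monitored. "Completeness" is the fraction of the
# network's ORIGINAL edges remaining; the relative LCC size is normalized by
# the LCC size at the start of percolation, so every curve starts at exactly
# 1.0. The completeness at which the curve collapses is the percolation
# threshold.

#' Percolation configuration
#'
#' @param step_fraction Fraction of edges removed per iteration, in (0, 1].
#'   Default 0.1 (ten steps from complete to empty).
#' @param repetitions Number of independent percolation runs aggregated into
#'   a curve. Default 20.
#' @param seed Integer seed; all randomness of a curve flows from it
#'   (per-repetition seeds are derived deterministically).
#' @param quantum `"original"` (default): each step removes
#'   `floor(step_fraction * E0)` of the original edge count, so the procedure
#'   terminates in `ceiling(1/step_fraction)` steps. `"remaining"`: each step
#'   removes `floor(step_fraction * E_remaining)` (at least one edge), the
#'   alternative reading of iterative 10% removal.
#' @return An object of class `"percolation_config"`.
#' @export
percolation_config <- function(step_fraction = 0.1, repetitions = 20L,
                               seed = 1L,
                               quantum = c("original", "remaining")) {
  quantum <- match.arg(quantum)
  stopifnot(is.numeric(step_fraction), length(step_fraction) == 1L,
            step_fraction > 0, step_fraction <= 1,
            repetitions >= 1L)
  structure(list(step_fraction = step_fraction,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), quantum = quantum),
            class = "percolation_config")
}

removal_schedule <- function(E0, step_fraction, quantum) {
  if (quantum == "original") {
    q <- max(1L, as.integer(floor(step_fraction * E0)))
    b <- seq.int(q, E0, by = q)
    if (b[length(b)] != E0) b <- c(b, E0)
  } else {
    b <- integer(0)
    e <- E0
    while (e > 0L) {
      q <- max(1L, as.integer(floor(step_fraction * e)))
      e <- e - q
      b <- c(b, E0 - e)
    }
  }
  b
}

percolation_graph <- function(net) {
  if (inherits(net, "interactome")) as_igraph(net)
  else if (igraph::is_igraph(net)) net
  else stop("'net' must be an interactome or an igraph graph")
}

#' One percolation repetition
#'
#' Removes distinct edges uniformly at random according to the removal
#' schedule, recomputing the LCC node count after each step until no edge
#' remains. The node set is fixed throughout; self-interaction flags are not
#' part of the removable edge pool (they carry no connectivity).
#'
#' @param net An `"interactome"` (or igraph graph) with at least one edge.
#' @param config A [percolation_config()].
#' @param rep_seed Seed for this repetition (defaults to `config$seed`).
#' @return Data frame with columns `step`, `edges_removed`, `completeness`,
#'   `lcc_size`, `rel_lcc`; the first row is the intact network
#'   (completeness 1, relative LCC 1).
#' @export
percolate_once <- function(net, config = percolation_config(),
                           rep_seed = config$seed) {
  stopifnot(inherits(config, "percolation_config"))
  g <- percolation_graph(net)
  E0 <- igraph::ecount(g)
  if (E0 == 0L) stop("cannot percolate an edgeless network")
  bounds <- removal_schedule(E0, config$step_fraction, config$quantum)
  set.seed(rep_seed)
  perm <- sample.int(E0)
  lcc0 <- max(igraph::components(g)$csize)
  k <- length(bounds)
  lcc <- integer(k)
  for (i in seq_len(k)) {
    b <- bounds[i]
    keep <- if (b < E0) perm[(b + 1L):E0] else integer(0)
    gg <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    lcc[i] <- max(igraph::components(gg)$csize)
  }
  data.frame(step = 0:k,
             edges_removed = c(0L, bounds),
             completeness = c(1, (E0 - bounds) / E0),
             lcc_size = c(lcc0, lcc),
             rel_lcc = c(1, lcc / lcc0))
}

#' Percolation curves with percentile ribbon
#'
#' Runs `config$repetitions` independent percolations (seeds derived
#' deterministically from `config$seed`) and aggregates, at each completeness
#' grid point, the median and the 20th/80th percentiles of the relative LCC
#' size. The percolation threshold is estimated as the completeness at which
#' the largest single-step drop of the median curve lands — the grid point
#' where the collapsed state is first observed.
#'
#' @param net An `"interactome"` (or igraph graph) with at least one edge.
#' @param config A [percolation_config()].
#' @return An object of class `"percolation_curve"`: `grid` (data frame
#'   `completeness`, `median`, `p20`, `p80`), `reps` (grid-points x
#'   repetitions matrix of relative LCC sizes), `threshold`, `n_nodes`,
#'   `n_edges`, `lcc0`, `config`.
#' @export
percolation_curves <- function(net, config = percolation_config()) {
  stopifnot(inherits(config, "percolation_config"))
  g <- percolation_graph(net)
  E0 <- igraph::ecount(g)
  if (E0 == 0L) stop("cannot percolate an edgeless network")
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$repetitions)
  runs <- lapply(rep_seeds, function(s) percolate_once(g, config, s))
  grid <- runs[[1]]$completeness
  mat <- vapply(runs, `[[`, numeric(length(grid)), "rel_lcc")
  mat <- matrix(mat, nrow = length(grid),
                dimnames = list(NULL, paste0("rep", seq_along(runs))))
  med <- apply(mat, 1, stats::median)
  p20 <- apply(mat, 1, stats::quantile, probs = 0.2, names = FALSE)
  p80 <- apply(mat, 1, stats::quantile, probs = 0.8, names = FALSE)
  drops <- -diff(med)
  threshold <- if (length(drops)) grid[which.max(drops) + 1L] else NA_real_
  structure(list(
    grid = data.frame(completeness = grid, median = med, p20 = p20, p80 = p80),
    reps = mat,
    threshold = threshold,
    n_nodes = igraph::vcount(g),
    n_edges = E0,
    lcc0 = max(igraph::components(g)$csize),
    config = config
  ), class = "percolation_curve")
}

#' @export
print.percolation_curve <- function(x, ...) {
  cat(sprintf("<percolation_curve> %d nodes, %d edges, %d repetitions (step %.0f%% of %s edges)\n",
              x$n_nodes, x$n_edges, ncol(x$reps),
              100 * x$config$step_fraction, x$config$quantum))
  cat(sprintf("  estimated percolation threshold: completeness %.2f\n",
              x$threshold))
  invisible(x)
}

#' Plot a percolation curve
#'
#' Median relative LCC size against completeness, with the 20th-80th
#' percentile ribbon.
#'
#' @param x A `"percolation_curve"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.percolation_curve <- function(x, ...) {
  gr <- x$grid
  graphics::plot(gr$completeness, gr$median, type = "n",
                 xlim = c(1, 0), ylim = c(0, 1),
                 xlab = "completeness (fraction of edges remaining)",
                 ylab = "relative LCC size", ...)
  graphics::polygon(c(gr$completeness, rev(gr$completeness)),
                    c(gr$p20, rev(gr$p80)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(gr$completeness, gr$median, lwd = 2, col = "steelblue4")
  graphics::abline(v = x$threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Write percolation results as TSV
#'
#' @param curve A `"percolation_curve"`.
#' @param file Path for the aggregated curve (completeness, median, p20, p80).
#' @param long_file Optional path for the per-repetition long-format table
#'   (completeness, repetition, rel_lcc).
#' @export
write_percolation_tsv <- function(curve, file, long_file = NULL) {
  stopifnot(inherits(curve, "percolation_curve"))
  utils::write.table(curve$grid, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  if (!is.null(long_file)) {
    long <- data.frame(
      completeness = rep(curve$grid$completeness, ncol(curve$reps)),
      repetition = rep(seq_len(ncol(curve$reps)),
                       each = nrow(curve$grid)),
      rel_lcc = as.vector(curve$reps))
    utils::write.table(long, long_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
  }
  invisible(file)
}
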