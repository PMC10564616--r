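# Topological metric battery: connected components, isolated nodes,
# articulation points, bridges, class-stratified shares, proteoform-family
# specificity, and small-molecule dependence of accessioned nodes.

#' Connected components, largest component and isolated nodes
#'
#' Components are computed on the simple graph (self-interaction flags carry
#' no connectivity). An isolated node has zero non-self edges, whether or not
#' it is flagged self-interacting — a protein that only interacts with itself
#' is isolated. The largest connected component (LCC) is the component with
#' most nodes; ties are broken deterministically by the lexicographically
#' smallest member.
#'
#' @param net An `"interactome"`.
#' @return An object of class `"component_summary"`: `n_components`,
#'   `membership` (named integer vector), `sizes`, `lcc_nodes`, `lcc_size`,
#'   `lcc_rel_size` (LCC nodes / all nodes) and `isolated` (sorted keys).
#' @export
component_summary <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(structure(list(n_components = 0L, membership = integer(0),
                          sizes = integer(0), lcc_nodes = character(0),
                          lcc_size = 0L, lcc_rel_size = NA_real_,
                          isolated = character(0)),
                     class = "component_summary"))
  }
  comp <- igraph::components(g)
  memb <- comp$membership
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  reps <- vapply(cand, function(ci) min(names(memb)[memb == ci]), character(1))
  lcc_id <- cand[order(reps)][1]
  structure(list(
    n_components = as.integer(comp$no),
    membership = memb,
    sizes = as.integer(comp$csize),
    lcc_nodes = sort(names(memb)[memb == lcc_id]),
    lcc_size = as.integer(mx),
    lcc_rel_size = mx / n,
    isolated = sort(names(which(igraph::degree(g) == 0)))
  ), class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf("<component_summary> %d components; LCC %d nodes (%.2f%% of network); %d isolated\n",
              x$n_components, x$lcc_size, 100 * x$lcc_rel_size,
              length(x$isolated)))
  invisible(x)
}

#' Isolated nodes of a network
#'
#' @param net An `"interactome"`.
#' @return Sorted keys of nodes with no incident edge (self-interaction flags
#'   do not count as connectivity).
#' @export
isolated_nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  sort(setdiff(net$nodes$key, c(net$edges$from, net$edges$to)))
}

#' Articulation points and bridges
#'
#' Articulation points (bridges) are nodes (edges) whose removal disconnects a
#' connected component into two or more components. They mark the fragile,
#' irreplaceable connectors of an interactome.
#'
#' @param net An `"interactome"`.
#' @return List with `articulation` (sorted node keys) and `bridges` (data
#'   frame `from`/`to` with each pair sorted, rows in deterministic order).
#' @export
articulation_and_bridges <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L || igraph::ecount(g) == 0L) {
    return(list(articulation = character(0),
                bridges = data.frame(from = character(0), to = character(0),
                                     stringsAsFactors = FALSE)))
  }
  ap <- sort(igraph::as_ids(igraph::articulation_points(g)))
  br <- igraph::bridges(g)
  if (length(br)) {
    en <- igraph::ends(g, br, names = TRUE)
    lo <- pmin(en[, 1], en[, 2])
    hi <- pmax(en[, 1], en[, 2])
    o <- order(lo, hi, method = "radix")
    bridges <- data.frame(from = lo[o], to = hi[o], stringsAsFactors = FALSE)
  } else {
    bridges <- data.frame(from = character(0), to = character(0),
                          stringsAsFactors = FALSE)
  }
  list(articulation = ap, bridges = bridges)
}

#' Class-stratified shares of articulation points and bridges
#'
#' Answers questions of the form "what fraction of articulation points are
#' small molecules?" and "what fraction of bridges connect two accessioned
#' entities?". Shares sum to 1 within each classification (and are all zero
#' for empty sets). Percentages are computed on exact integer counts.
#'
#' @param ab Result of [articulation_and_bridges()] for `net`.
#' @param net The `"interactome"` the sets came from.
#' @return List with `articulation_share` (by node class),
#'   `pct_class_articulation` (percentage of each class that is an
#'   articulation point), `bridge_share` (by endpoint class pattern) and
#'   `pct_bridges_touching_sm` (percentage of bridges with at least one
#'   small-molecule endpoint).
#' @export
class_shares <- function(ab, net) {
  stopifnot(inherits(net, "interactome"))
  clmap <- stats::setNames(net$nodes$class, net$nodes$key)

  ap_cls <- unname(clmap[ab$articulation])
  n_ap <- length(ap_cls)
  articulation_share <- c(ACCESSIONED = 0, SMALL_MOLECULE = 0)
  if (n_ap) {
    tb <- table(factor(ap_cls, levels = ENTITY_CLASSES))
    articulation_share[] <- as.numeric(tb) / n_ap
  }
  n_class <- table(factor(net$nodes$class, levels = ENTITY_CLASSES))
  n_ap_class <- table(factor(ap_cls, levels = ENTITY_CLASSES))
  pct_class_articulation <- ifelse(n_class > 0,
                                   100 * as.numeric(n_ap_class) / as.numeric(n_class),
                                   0)
  names(pct_class_articulation) <- ENTITY_CLASSES

  patterns <- c("accessioned-accessioned", "accessioned-sm", "sm-sm")
  bridge_share <- stats::setNames(numeric(3), patterns)
  pct_sm <- 0
  nb <- nrow(ab$bridges)
  if (nb) {
    c1 <- unname(clmap[ab$bridges$from])
    c2 <- unname(clmap[ab$bridges$to])
    n_sm_end <- (c1 == "SMALL_MOLECULE") + (c2 == "SMALL_MOLECULE")
    pat <- patterns[n_sm_end + 1L]
    tb <- table(factor(pat, levels = patterns))
    bridge_share[] <- as.numeric(tb) / nb
    pct_sm <- 100 * sum(n_sm_end > 0) / nb
  }
  list(articulation_share = articulation_share,
       pct_class_articulation = pct_class_articulation,
       bridge_share = bridge_share,
       pct_bridges_touching_sm = pct_sm)
}

#' Full topology summary of an interactome
#'
#' One document with the metric battery used throughout the analysis: node
#' and edge counts stratified by class, degree statistics (mean, median, max)
#' per class, component structure, isolated nodes, articulation points and
#' bridges with class shares. `summary()` on an `"interactome"` returns this
#' object.
#'
#' @param net An `"interactome"`.
#' @return An object of class `"topology_summary"`.
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  cls <- net$nodes$class
  deg <- if (igraph::vcount(g)) igraph::degree(g) else
    stats::setNames(numeric(0), character(0))
  deg <- unname(deg[net$nodes$key])

  deg_stats <- function(d) {
    if (!length(d)) return(c(mean = NA_real_, median = NA_real_, max = NA_real_))
    c(mean = mean(d), median = stats::median(d), max = max(d))
  }
  edge_pattern <- stats::setNames(integer(3), c("accessioned-accessioned",
                                                "accessioned-sm", "sm-sm"))
  if (nrow(net$edges)) {
    clmap <- stats::setNames(cls, net$nodes$key)
    n_sm_end <- (clmap[net$edges$from] == "SMALL_MOLECULE") +
      (clmap[net$edges$to] == "SMALL_MOLECULE")
    tb <- table(factor(n_sm_end, levels = 0:2))
    edge_pattern[] <- as.integer(tb)
  }
  comp <- component_summary(net)
  ab <- articulation_and_bridges(net)
  shares <- class_shares(ab, net)
  structure(list(
    n_nodes = nrow(net$nodes),
    n_nodes_accessioned = sum(cls == "ACCESSIONED"),
    n_nodes_sm = sum(cls == "SMALL_MOLECULE"),
    n_edges = nrow(net$edges),
    edge_pattern = edge_pattern,
    n_self_loop = sum(net$nodes$self_loop),
    degree = list(all = deg_stats(deg),
                  accessioned = deg_stats(deg[cls == "ACCESSIONED"]),
                  small_molecule = deg_stats(deg[cls == "SMALL_MOLECULE"])),
    n_components = comp$n_components,
    lcc_size = comp$lcc_size,
    lcc_rel_size = comp$lcc_rel_size,
    n_isolated = length(comp$isolated),
    articulation = ab$articulation,
    bridges = ab$bridges,
    shares = shares,
    config = net$config
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cfg <- if (is.null(x$config)) "" else
    paste0(" [", x$config$entity_level, " level, SM: ", x$config$sm_mode, "]")
  cat(sprintf("<topology_summary>%s\n", cfg))
  cat(sprintf("  nodes: %d (%d accessioned, %d small molecules), edges: %d, self-interacting: %d\n",
              x$n_nodes, x$n_nodes_accessioned, x$n_nodes_sm, x$n_edges,
              x$n_self_loop))
  cat(sprintf("  mean degree: %.2f (accessioned %.2f, small molecules %.2f)\n",
              x$degree$all["mean"], x$degree$accessioned["mean"],
              x$degree$small_molecule["mean"]))
  cat(sprintf("  components: %d, LCC: %d nodes (%.2f%%), isolated: %d\n",
              x$n_components, x$lcc_size, 100 * x$lcc_rel_size, x$n_isolated))
  cat(sprintf("  articulation points: %d (%.2f%% small molecules), bridges: %d\n",
              length(x$articulation),
              100 * x$shares$articulation_share["SMALL_MOLECULE"],
              nrow(x$bridges)))
  invisible(x)
}

#' Per-node annotation table
#'
#' @param net An `"interactome"`.
#' @return Data frame, one row per node (sorted by key): `key`, `class`,
#'   `label`, `self_loop`, `degree`, `component`, `is_articulation`,
#'   `is_isolated`.
#' @export
node_annotation_table <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  comp <- component_summary(net)
  ab <- articulation_and_bridges(net)
  deg <- if (igraph::vcount(g)) igraph::degree(g) else
    stats::setNames(numeric(0), character(0))
  data.frame(
    key = net$nodes$key,
    class = net$nodes$class,
    label = net$nodes$label,
    self_loop = net$nodes$self_loop,
    degree = as.integer(unname(deg[net$nodes$key])),
    component = as.integer(unname(comp$membership[net$nodes$key])),
    is_articulation = net$nodes$key %in% ab$articulation,
    is_isolated = net$nodes$key %in% comp$isolated,
    stringsAsFactors = FALSE)
}

#' Write a topology summary as JSON
#'
#' @param ts A `"topology_summary"`.
#' @param file Output path.
#' @export
write_topology_json <- function(ts, file) {
  stopifnot(inherits(ts, "topology_summary"))
  doc <- list(
    config = if (is.null(ts$config)) NULL else unclass(ts$config),
    nodes = list(total = ts$n_nodes, accessioned = ts$n_nodes_accessioned,
                 small_molecules = ts$n_nodes_sm,
                 self_interacting = ts$n_self_loop,
                 isolated = ts$n_isolated),
    edges = list(total = ts$n_edges, by_class_pattern = as.list(ts$edge_pattern)),
    degree = lapply(ts$degree, as.list),
    components = list(n = ts$n_components, lcc_size = ts$lcc_size,
                      lcc_rel_size = ts$lcc_rel_size),
    articulation_points = list(n = length(ts$articulation),
                               keys = ts$articulation,
                               share_by_class = as.list(ts$shares$articulation_share),
                               pct_of_class = as.list(ts$shares$pct_class_articulation)),
    bridges = list(n = nrow(ts$bridges),
                   share_by_pattern = as.list(ts$shares$bridge_share),
                   pct_touching_sm = ts$shares$pct_bridges_touching_sm))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Proteoform families with reaction-specific members
#'
#' Groups proteoforms by protein accession (a proteoform family) and returns
#' the accessions with at least two distinct family members where some member
#' participates in at least one reaction involving no other member of the
#' family. Identifying such a proteoform in a sample carries pathway-specific
#' information that a gene-centric representation loses.
#'
#' @param records Participant table at proteoform resolution.
#' @return Sorted character vector of protein accessions.
#' @export
family_specificity <- function(records) {
  rec <- validate_participants(records)
  a <- rec[rec$entity_class == "ACCESSIONED", , drop = FALSE]
  if (!nrow(a)) return(character(0))
  pk <- proteoform_key(a$accession, a$isoform, a$ptms)
  d <- unique(data.frame(acc = a$accession, pk = pk, rid = a$reaction_id,
                         stringsAsFactors = FALSE))
  hit <- vapply(split(d, d$acc), function(f) {
    if (length(unique(f$pk)) < 2L) return(FALSE)
    any(vapply(split(f$pk, f$rid), function(k) length(unique(k)) == 1L,
               logical(1)))
  }, logical(1))
  sort(names(hit)[hit])
}

#' Accessioned nodes connected only through small molecules
#'
#' Compares a network built without small molecules against one built from
#' the same records with small molecules included, and returns the
#' accessioned nodes that are isolated in the former but connected in the
#' latter: their only routes into the interactome run through small
#' molecules.
#'
#' @param net_without_sm,net_with_sm `"interactome"`s built from identical
#'   records at the same entity level, with `sm_mode = "none"` and with small
#'   molecules included, respectively. Their accessioned node sets must
#'   coincide.
#' @return Sorted keys of small-molecule-dependent accessioned nodes.
#' @export
sm_dependency <- function(net_without_sm, net_with_sm) {
  stopifnot(inherits(net_without_sm, "interactome"),
            inherits(net_with_sm, "interactome"))
  acc_a <- sort(net_without_sm$nodes$key[net_without_sm$nodes$class == "ACCESSIONED"])
  acc_b <- sort(net_with_sm$nodes$key[net_with_sm$nodes$class == "ACCESSIONED"])
  if (!identical(acc_a, acc_b)) {
    stop("accessioned node sets differ; both networks must be built from the same records at the same entity level")
  }
  iso_a <- isolated_nodes(net_without_sm)
  iso_b <- isolated_nodes(net_with_sm)
  sort(intersect(acc_a, setdiff(iso_a, iso_b)))
}
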