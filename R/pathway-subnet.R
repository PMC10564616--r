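# Pathway-specific subnetworks. A pathway's reaction set is the transitive
# closure through its sub-pathways; its subnetwork is the interactome built
# from exactly those reactions, so a parent pathway's network contains every
# child pathway's network.

#' Transitive reaction closure of a pathway
#'
#' Lists the reactions a pathway consists of, recursing through any chain of
#' sub-pathway containment. A visited set guards against runaway recursion
#' (containment is validated acyclic at hierarchy construction, but the guard
#' makes the walk robust to hand-edited tables).
#'
#' @param pathway_id A pathway id present in `hierarchy`.
#' @param hierarchy A [pathway_hierarchy()].
#' @return Sorted character vector of reaction ids.
#' @export
pathway_closure <- function(pathway_id, hierarchy) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  if (!(pathway_id %in% hierarchy_pathways(hierarchy))) {
    stop("unknown pathway id: ", pathway_id)
  }
  reactions <- character(0)
  visited <- character(0)
  queue <- pathway_id
  while (length(queue)) {
    p <- queue[1]
    queue <- queue[-1]
    if (p %in% visited) next
    visited <- c(visited, p)
    kids <- hierarchy[hierarchy$parent_id == p, , drop = FALSE]
    reactions <- c(reactions, kids$child_id[kids$child_kind == "REACTION"])
    sub <- kids$child_id[kids$child_kind == "PATHWAY"]
    queue <- c(queue, setdiff(sub, visited))
  }
  sort(unique(reactions))
}

#' Build the subnetwork of one pathway
#'
#' Equals [build_network()] restricted to the records whose reaction lies in
#' the pathway's closure.
#'
#' @param pathway_id A pathway id present in `hierarchy`.
#' @param records Participant table.
#' @param hierarchy A [pathway_hierarchy()].
#' @param config A [build_config()].
#' @return An `"interactome"` (possibly empty, e.g. a small-molecule-only
#'   pathway under `sm_mode = "none"`).
#' @export
build_pathway_network <- function(pathway_id, records, hierarchy,
                                  config = build_config()) {
  rx <- pathway_closure(pathway_id, hierarchy)
  rec <- validate_participants(records)
  build_network(rec[rec$reaction_id %in% rx, , drop = FALSE], config)
}

#' Per-pathway topology summary table
#'
#' Builds every pathway's subnetwork independently (no cross-pathway
#' deduplication — nested pathways deliberately repeat their children's nodes
#' and reactions, so per-pathway averages reflect each pathway's own context)
#' and tabulates the metric battery per pathway.
#'
#' @param records Participant table.
#' @param hierarchy A [pathway_hierarchy()].
#' @param config A [build_config()].
#' @param annotated_only If `TRUE`, restrict to pathways whose closure
#'   contains at least one participant with isoform or PTM annotation (the
#'   filter used when studying proteoform-driven degree changes). Default
#'   `FALSE`: the filter is a flag, never hard-coded.
#' @return Data frame, one row per pathway, in stable column order.
#' @export
per_pathway_summary <- function(records, hierarchy, config = build_config(),
                                annotated_only = FALSE) {
  rec <- validate_participants(records)
  pids <- hierarchy_pathways(hierarchy)
  annotated_rx <- unique(rec$reaction_id[nzchar(rec$isoform) | nzchar(rec$ptms)])
  rows <- lapply(pids, function(p) {
    rx <- pathway_closure(p, hierarchy)
    has_annot <- any(rx %in% annotated_rx)
    if (annotated_only && !has_annot) return(NULL)
    net <- build_network(rec[rec$reaction_id %in% rx, , drop = FALSE], config)
    ts <- topology_summary(net)
    data.frame(
      pathway_id = p,
      n_reactions = length(rx),
      has_proteoform_annotation = has_annot,
      n_nodes = ts$n_nodes,
      n_nodes_accessioned = ts$n_nodes_accessioned,
      n_nodes_sm = ts$n_nodes_sm,
      n_edges = ts$n_edges,
      mean_degree = unname(ts$degree$all["mean"]),
      mean_degree_accessioned = unname(ts$degree$accessioned["mean"]),
      mean_degree_sm = unname(ts$degree$small_molecule["mean"]),
      n_isolated = ts$n_isolated,
      n_components = ts$n_components,
      lcc_rel_size = ts$lcc_rel_size,
      n_articulation = length(ts$articulation),
      articulation_share_accessioned = unname(ts$shares$articulation_share["ACCESSIONED"]),
      articulation_share_sm = unname(ts$shares$articulation_share["SMALL_MOLECULE"]),
      pct_accessioned_articulation = unname(ts$shares$pct_class_articulation["ACCESSIONED"]),
      pct_sm_articulation = unname(ts$shares$pct_class_articulation["SMALL_MOLECULE"]),
      n_bridges = nrow(ts$bridges),
      bridge_share_acc_acc = unname(ts$shares$bridge_share["accessioned-accessioned"]),
      bridge_share_acc_sm = unname(ts$shares$bridge_share["accessioned-sm"]),
      bridge_share_sm_sm = unname(ts$shares$bridge_share["sm-sm"]),
      pct_bridges_touching_sm = ts$shares$pct_bridges_touching_sm,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(pathway_id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
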