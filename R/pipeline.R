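# End-to-end orchestration: from a participant table to all six network
# variants, topology summaries, per-pathway tables, percolation curves and a
# cross-variant comparison table. All outputs are deterministic for fixed
# inputs and seed, and carry a provenance header (input/config hashes, seed,
# package version).

#' The six default network variants
#'
#' @return List of [build_config()]s: each small-molecule mode (none, global,
#'   reaction-unique) at each entity level (gene, proteoform), named by
#'   variant id.
#' @export
default_build_configs <- function() {
  out <- list()
  for (sm in c("none", "global", "reaction_unique")) {
    for (lv in c("gene", "proteoform")) {
      cfg <- build_config(lv, sm)
      out[[variant_id(cfg)]] <- cfg
    }
  }
  out
}

#' Build several interactome variants from one record table
#'
#' @param records Participant table.
#' @param configs List of [build_config()]s (default: all six variants).
#' @return Named list of `"interactome"`s.
#' @export
build_all_variants <- function(records, configs = default_build_configs()) {
  rec <- validate_participants(records)
  nets <- lapply(configs, function(cf) build_network(rec, cf))
  names(nets) <- vapply(configs, variant_id, character(1))
  nets
}

#' Cross-variant size table
#'
#' One row per variant (small-molecule mode crossed with entity level):
#' number of interactions (edges), nodes, accessioned entities and
#' small-molecule nodes.
#'
#' @param nets Named list of `"interactome"`s (see [build_all_variants()]).
#' @return Data frame of class `"variant_sizes"`.
#' @export
variant_size_table <- function(nets) {
  rows <- lapply(nets, function(net) {
    cfg <- net$config
    data.frame(
      small_molecules = if (is.null(cfg)) NA_character_ else cfg$sm_mode,
      entity_level = if (is.null(cfg)) NA_character_ else cfg$entity_level,
      interactions = nrow(net$edges),
      nodes = nrow(net$nodes),
      accessioned_entities = sum(net$nodes$class == "ACCESSIONED"),
      small_molecule_nodes = sum(net$nodes$class == "SMALL_MOLECULE"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sm_order <- match(out$small_molecules, c("none", "global", "reaction_unique"))
  lv_order <- match(out$entity_level, c("gene", "proteoform"))
  out <- out[order(sm_order, lv_order), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_sizes", "data.frame")
  out
}

format_delta <- function(from, to) {
  d <- to - from
  pct <- if (from == 0) NA_real_ else 100 * d / from
  sprintf("%+d (%s)", d,
          if (is.na(pct)) "n/a" else sprintf("%+.1f%%", pct))
}

#' Compare network variants
#'
#' Absolute and percentage deltas of nodes and interactions of each variant
#' against a reference variant, formatted as `"+3214 (+29.1%)"`. Two size
#' tables can be compared only if they carry matching input provenance.
#'
#' @param sizes A `"variant_sizes"` table (see [variant_size_table()]).
#' @param other Optional second `"variant_sizes"` table to append; its
#'   `"input_hash"` attribute (when both are set) must match `sizes`'s.
#' @param reference Row index of the reference variant (default 1).
#' @return Data frame with per-variant deltas and formatted delta strings.
#' @export
compare_variants <- function(sizes, other = NULL, reference = 1L) {
  stopifnot(inherits(sizes, "data.frame"), nrow(sizes) >= 1L)
  if (!is.null(other)) {
    ha <- attr(sizes, "input_hash")
    hb <- attr(other, "input_hash")
    if (!is.null(ha) && !is.null(hb) && !identical(ha, hb)) {
      stop("cannot compare variants built from different records (input hash mismatch)")
    }
    sizes <- rbind(as.data.frame(sizes), as.data.frame(other))
  }
  if (nrow(sizes) < 2L) stop("need at least two variants to compare")
  ref <- sizes[reference, ]
  out <- data.frame(
    small_molecules = sizes$small_molecules,
    entity_level = sizes$entity_level,
    nodes = sizes$nodes,
    interactions = sizes$interactions,
    nodes_delta = sizes$nodes - ref$nodes,
    nodes_pct = if (ref$nodes == 0) NA_real_ else
      100 * (sizes$nodes - ref$nodes) / ref$nodes,
    interactions_delta = sizes$interactions - ref$interactions,
    interactions_pct = if (ref$interactions == 0) NA_real_ else
      100 * (sizes$interactions - ref$interactions) / ref$interactions,
    stringsAsFactors = FALSE)
  out$nodes_vs_ref <- mapply(format_delta, ref$nodes, sizes$nodes)
  out$interactions_vs_ref <- mapply(format_delta, ref$interactions,
                                    sizes$interactions)
  out
}

file_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

provenance_header <- function(input_hash, config_hash, seed) {
  sprintf("# proteoformnet %s input_md5=%s config_md5=%s seed=%d",
          as.character(utils::packageVersion("proteoformnet")),
          input_hash, config_hash, seed)
}

write_tsv_with_header <- function(df, file, header) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Builds every requested network variant from a participant table, then
#' writes, per variant: GraphML and edge-list exports, a topology-summary
#' JSON, a per-node annotation TSV, a per-pathway summary TSV and a
#' percolation-curve TSV; plus the cross-variant size table and the
#' comparison table. Every TSV starts with a provenance comment line (input
#' hash, configuration hash, seed, package version), so a rerun on identical
#' inputs is byte-identical.
#'
#' @param records Participant table.
#' @param hierarchy A [pathway_hierarchy()].
#' @param out_dir Output directory (created if missing).
#' @param configs List of [build_config()]s; default all six variants.
#' @param percolation A [percolation_config()] or `NULL` to skip percolation.
#' @param pathway_summaries Compute per-pathway tables (default `TRUE`).
#' @param annotated_only Passed to [per_pathway_summary()].
#' @return (Invisibly) a list with `networks`, `sizes`, `comparison`,
#'   `summaries`, `pathway_summaries`, `percolation` and `files`.
#' @export
run_pipeline <- function(records, hierarchy, out_dir,
                         configs = default_build_configs(),
                         percolation = percolation_config(),
                         pathway_summaries = TRUE,
                         annotated_only = FALSE) {
  stopifnot(length(configs) >= 1L)
  rec <- validate_participants(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tf <- tempfile()
  write_participant_table(rec, tf)
  input_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  config_hash <- file_md5(paste(
    vapply(configs, variant_id, character(1)), collapse = ","))
  seed <- if (is.null(percolation)) 0L else percolation$seed
  header <- provenance_header(input_hash, config_hash, seed)

  nets <- build_all_variants(rec, configs)
  summaries <- lapply(nets, topology_summary)
  sizes <- variant_size_table(nets)
  attr(sizes, "input_hash") <- input_hash
  comparison <- if (nrow(sizes) >= 2L) compare_variants(sizes) else NULL

  files <- character(0)
  p <- function(...) file.path(out_dir, paste0(...))
  write_tsv_with_header(as.data.frame(sizes), p("variant_sizes.tsv"), header)
  files <- c(files, p("variant_sizes.tsv"))
  if (!is.null(comparison)) {
    write_tsv_with_header(comparison, p("variant_comparison.tsv"), header)
    files <- c(files, p("variant_comparison.tsv"))
  }

  pw <- list()
  perc <- list()
  for (id in names(nets)) {
    net <- nets[[id]]
    write_network_graphml(net, p(id, ".graphml"))
    write_network_edgelist(net, p(id, "_edges.tsv"))
    write_topology_json(summaries[[id]], p(id, "_topology.json"))
    write_tsv_with_header(node_annotation_table(net), p(id, "_nodes.tsv"),
                          header)
    files <- c(files, p(id, ".graphml"), p(id, "_edges.tsv"),
               p(id, "_topology.json"), p(id, "_nodes.tsv"))
    if (pathway_summaries) {
      pw[[id]] <- per_pathway_summary(rec, hierarchy, net$config,
                                      annotated_only = annotated_only)
      write_tsv_with_header(pw[[id]], p("pathways_", id, ".tsv"), header)
      files <- c(files, p("pathways_", id, ".tsv"))
    }
    if (!is.null(percolation) && nrow(net$edges) >= 1L) {
      perc[[id]] <- percolation_curves(net, percolation)
      write_percolation_tsv(perc[[id]], p("percolation_", id, ".tsv"))
      files <- c(files, p("percolation_", id, ".tsv"))
    }
  }
  invisible(list(networks = nets, sizes = sizes, comparison = comparison,
                 summaries = summaries, pathway_summaries = pw,
                 percolation = perc, files = files))
}
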