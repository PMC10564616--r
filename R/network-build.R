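# Co-participation network construction. Nodes are gene symbols or canonical
# proteoform strings (accessioned entities) and ChEBI ids (small molecules);
# every pair of distinct nodes annotated to the same reaction, in any role, is
# connected by an undirected edge. Self-pairs within a reaction are recorded
# as a per-node self-interaction flag, not as edges.

#' Network build configuration
#'
#' One of the six interactome variants: entity level (gene vs proteoform)
#' crossed with the small-molecule representation — `"none"` (small molecules
#' skipped), `"global"` (one node per ChEBI id across the whole interactome)
#' or `"reaction_unique"` (one node per ChEBI id and reaction, confining a
#' small molecule's connectivity to within-reaction context).
#'
#' @param entity_level `"gene"` or `"proteoform"`.
#' @param sm_mode `"none"`, `"global"` or `"reaction_unique"`.
#' @return An object of class `"build_config"`.
#' @export
build_config <- function(entity_level = c("gene", "proteoform"),
                         sm_mode = c("none", "global", "reaction_unique")) {
  structure(list(entity_level = match.arg(entity_level),
                 sm_mode = match.arg(sm_mode)),
            class = "build_config")
}

#' @export
print.build_config <- function(x, ...) {
  cat("<build_config>", x$entity_level, "level, small molecules:",
      x$sm_mode, "\n")
  invisible(x)
}

variant_id <- function(config) paste(config$entity_level, config$sm_mode, sep = "_")

#' Node keys for participant records
#'
#' Maps each participant record to the node it represents under a build
#' configuration. At gene level all proteoforms of a gene collapse onto the
#' gene symbol (falling back to the UniProt accession for proteins without an
#' HGNC symbol); at proteoform level the key is the canonical proteoform
#' string. Small molecules key on their ChEBI id (`"global"`), on the
#' (ChEBI id, reaction) pair rendered `"chebi@reaction"`
#' (`"reaction_unique"`), or are skipped (`"none"`, key `NA`).
#'
#' @param records Participant table.
#' @param config A [build_config()].
#' @return Data frame with columns `key` (`NA` for skipped records), `class`
#'   and `label`, one row per record.
#' @export
node_keys <- function(records, config = build_config()) {
  stopifnot(inherits(config, "build_config"))
  rec <- validate_participants(records)
  acc <- rec$entity_class == "ACCESSIONED"
  key <- rep(NA_character_, nrow(rec))
  label <- key
  if (config$entity_level == "gene") {
    gk <- ifelse(nzchar(rec$gene_name), rec$gene_name, rec$accession)
    key[acc] <- gk[acc]
  } else {
    pk <- proteoform_key(rec$accession, rec$isoform, rec$ptms)
    key[acc] <- pk[acc]
  }
  label[acc] <- key[acc]
  sm <- !acc
  if (config$sm_mode == "global") {
    key[sm] <- rec$accession[sm]
    label[sm] <- rec$accession[sm]
  } else if (config$sm_mode == "reaction_unique") {
    key[sm] <- paste0(rec$accession[sm], "@", rec$reaction_id[sm])
    label[sm] <- rec$accession[sm]
  }
  data.frame(key = key, class = ifelse(acc, "ACCESSIONED", "SMALL_MOLECULE"),
             label = label, stringsAsFactors = FALSE)
}

#' Low-level interaction network constructor
#'
#' Builds an `"interactome"` object from explicit node and edge tables,
#' enforcing the simple-graph invariants: each unordered node pair appears at
#' most once, no self-pairs (self-interactions are per-node flags), every edge
#' endpoint is a known node, and every edge carries non-empty reaction
#' provenance. Most users should call [build_network()] instead; this
#' constructor is useful for assembling test graphs and for percolating
#' arbitrary networks.
#'
#' @param nodes Data frame with columns `key`, `class`, and optionally `label`
#'   and `self_loop`; or a character vector of keys (all `"ACCESSIONED"`).
#' @param edges Data frame with character columns `from`, `to` (order within a
#'   pair is irrelevant; pairs are stored sorted).
#' @param provenance List of character vectors of reaction ids, one per edge
#'   row; defaults to `"unspecified"` for hand-built graphs.
#' @param config Optional [build_config()] recording how the network was built.
#' @return An object of class `"interactome"` with components `nodes`
#'   (`key`, `class`, `label`, `self_loop`), `edges` (`from`, `to`),
#'   `provenance` and `config`, in deterministic (sorted) order.
#' @export
interaction_network <- function(nodes, edges = NULL, provenance = NULL,
                                config = NULL) {
  if (is.character(nodes)) {
    nodes <- data.frame(key = nodes, class = "ACCESSIONED",
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(nodes), "key" %in% names(nodes))
  nodes$key <- as.character(nodes$key)
  if (anyDuplicated(nodes$key)) stop("duplicate node keys")
  if (is.null(nodes$class)) nodes$class <- "ACCESSIONED"
  nodes$class <- as.character(nodes$class)
  if (!all(nodes$class %in% ENTITY_CLASSES)) stop("unknown node class")
  if (is.null(nodes$label)) nodes$label <- nodes$key
  if (is.null(nodes$self_loop)) nodes$self_loop <- logical(nrow(nodes))
  nodes <- nodes[c("key", "class", "label", "self_loop")]

  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
    provenance <- list()
  } else {
    edges <- as.data.frame(edges)
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    if (any(lo == hi)) {
      stop("self-pairs are not edges; record them as self_loop flags")
    }
    if (is.null(provenance)) provenance <- rep(list("unspecified"), length(lo))
    stopifnot(is.list(provenance), length(provenance) == length(lo))
    if (any(lengths(provenance) == 0L)) stop("edge provenance must be non-empty")
    eid <- paste(lo, hi, sep = "\r")
    if (anyDuplicated(eid)) stop("duplicate edges")
    miss <- setdiff(unique(c(lo, hi)), nodes$key)
    if (length(miss)) stop("edge endpoint not in node set: ", miss[1])
    o <- order(lo, hi, method = "radix")
    edges <- data.frame(from = lo[o], to = hi[o], stringsAsFactors = FALSE)
    provenance <- provenance[o]
  }
  o <- order(nodes$key, method = "radix")
  nodes <- nodes[o, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = provenance,
                 config = config),
            class = "interactome")
}

#' Build a co-participation interactome
#'
#' For every reaction in the participant table, all participant nodes (after
#' keying and small-molecule skipping under `config`) are pairwise connected,
#' regardless of role: inputs, outputs, catalysts and regulators are treated
#' identically. Participants of a reaction that map to the same node set that
#' node's self-interaction flag instead of creating an edge. Edges are
#' deduplicated across reactions with their reaction provenance aggregated;
#' nodes with no incident edge are retained (they are the "isolated nodes" of
#' the topology analysis).
#'
#' @param records Participant table (may be empty, giving an empty network).
#' @param config A [build_config()].
#' @return An `"interactome"` object.
#' @export
#' @examples
#' rec <- data.frame(
#'   pathway_id = "PW1", reaction_id = "R1",
#'   role = c("INPUT", "INPUT", "OUTPUT"),
#'   entity_class = c("ACCESSIONED", "SMALL_MOLECULE", "ACCESSIONED"),
#'   accession = c("P1", "CHEBI:30616", "P2"),
#'   gene_name = c("G1", "", "G2"), isoform = "", ptms = "")
#' net <- build_network(rec, build_config("gene", "global"))
#' net
build_network <- function(records, config = build_config()) {
  stopifnot(inherits(config, "build_config"))
  rec <- validate_participants(records)
  nk <- node_keys(rec, config)
  keep <- !is.na(nk$key)
  key <- nk$key[keep]
  cls <- nk$class[keep]
  lab <- nk$label[keep]
  rid <- rec$reaction_id[keep]
  if (!length(key)) {
    return(interaction_network(
      data.frame(key = character(0), class = character(0),
                 stringsAsFactors = FALSE),
      config = config))
  }
  first <- !duplicated(key)
  nodes <- data.frame(key = key[first], class = cls[first], label = lab[first],
                      stringsAsFactors = FALSE)
  rk <- paste(rid, key, sep = "\r")
  nodes$self_loop <- nodes$key %in% unique(key[duplicated(rk)])

  u <- !duplicated(rk)
  per_rxn <- split(key[u], rid[u])
  froms <- vector("list", length(per_rxn))
  tos <- vector("list", length(per_rxn))
  rids <- vector("list", length(per_rxn))
  i <- 0L
  for (r in names(per_rxn)) {
    k <- sort(per_rxn[[r]])
    if (length(k) >= 2L) {
      cb <- utils::combn(k, 2L)
      i <- i + 1L
      froms[[i]] <- cb[1L, ]
      tos[[i]] <- cb[2L, ]
      rids[[i]] <- rep(r, ncol(cb))
    }
  }
  from <- unlist(froms, use.names = FALSE)
  to <- unlist(tos, use.names = FALSE)
  rvec <- unlist(rids, use.names = FALSE)
  if (is.null(from)) {
    return(interaction_network(nodes, config = config))
  }
  eid <- paste(from, to, sep = "\r")
  prov_all <- split(rvec, eid)
  ue <- !duplicated(eid)
  edges <- data.frame(from = from[ue], to = to[ue], stringsAsFactors = FALSE)
  provenance <- lapply(prov_all[eid[ue]], function(x) sort(unique(x)))
  names(provenance) <- NULL
  interaction_network(nodes, edges, provenance, config = config)
}

#' Map proteoform keys to gene keys
#'
#' Derives, from a participant table, the mapping from each proteoform node
#' key to the gene node key of the encoding gene (HGNC symbol, with UniProt
#' accession fallback). Used with [quotient_to_genes()] to validate that
#' collapsing the proteoform network reproduces the gene network.
#'
#' @param records Participant table.
#' @return Named character vector: names are proteoform keys, values gene keys.
#' @export
proteoform_gene_map <- function(records) {
  rec <- validate_participants(records)
  rec <- rec[rec$entity_class == "ACCESSIONED", , drop = FALSE]
  if (!nrow(rec)) return(stats::setNames(character(0), character(0)))
  pk <- proteoform_key(rec$accession, rec$isoform, rec$ptms)
  gk <- ifelse(nzchar(rec$gene_name), rec$gene_name, rec$accession)
  u <- !duplicated(pk)
  stats::setNames(gk[u], pk[u])
}

#' Collapse a proteoform network onto genes
#'
#' Quotient operation: every accessioned (proteoform) node is replaced by its
#' gene key under `mapping`; small-molecule nodes pass through unchanged.
#' Edges whose endpoints collapse onto the same gene become self-interaction
#' flags; duplicate edges are merged with provenance unioned. For records
#' built at proteoform level, the quotient equals the directly built gene
#' network — this identity is the validation oracle for the node semantics.
#'
#' @param net An `"interactome"` built at proteoform level.
#' @param mapping Named character vector covering every accessioned node key
#'   (see [proteoform_gene_map()]).
#' @return The collapsed `"interactome"`.
#' @export
quotient_to_genes <- function(net, mapping) {
  stopifnot(inherits(net, "interactome"))
  acc_keys <- net$nodes$key[net$nodes$class == "ACCESSIONED"]
  unmapped <- setdiff(acc_keys, names(mapping))
  if (length(unmapped)) {
    stop("mapping does not cover accessioned node: ", unmapped[1])
  }
  full_map <- stats::setNames(net$nodes$key, net$nodes$key)
  full_map[acc_keys] <- mapping[acc_keys]

  nk <- unname(full_map[net$nodes$key])
  first <- !duplicated(nk)
  nodes <- data.frame(key = nk[first], class = net$nodes$class[first],
                      label = ifelse(net$nodes$class[first] == "ACCESSIONED",
                                     nk[first], net$nodes$label[first]),
                      stringsAsFactors = FALSE)
  self_loop <- tapply(net$nodes$self_loop, nk, any)

  if (nrow(net$edges)) {
    f <- unname(full_map[net$edges$from])
    t <- unname(full_map[net$edges$to])
    selfp <- f == t
    if (any(selfp)) self_loop[unique(f[selfp])] <- TRUE
    f2 <- f[!selfp]
    t2 <- t[!selfp]
    prov <- net$provenance[!selfp]
    if (length(f2)) {
      lo <- pmin(f2, t2)
      hi <- pmax(f2, t2)
      eid <- paste(lo, hi, sep = "\r")
      grp <- split(seq_along(eid), eid)
      ue <- !duplicated(eid)
      edges <- data.frame(from = lo[ue], to = hi[ue], stringsAsFactors = FALSE)
      provenance <- lapply(grp[eid[ue]], function(ix) {
        sort(unique(unlist(prov[ix], use.names = FALSE)))
      })
      names(provenance) <- NULL
    } else {
      edges <- NULL
      provenance <- NULL
    }
  } else {
    edges <- NULL
    provenance <- NULL
  }
  nodes$self_loop <- as.logical(self_loop[nodes$key])
  cfg <- net$config
  if (!is.null(cfg)) cfg$entity_level <- "gene"
  interaction_network(nodes, edges, provenance, config = cfg)
}

#' Convert an interactome to an igraph graph
#'
#' The igraph graph carries vertex attributes `class`, `label`, `self_loop`
#' and edge attribute `n_reactions` (provenance size). Self-interaction flags
#' are vertex attributes, not loop edges, so igraph's connectivity routines
#' see the simple graph the topology analysis is defined on.
#'
#' @param net An `"interactome"`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  v <- net$nodes
  if (!nrow(v)) return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = v)
  if (nrow(net$edges)) {
    igraph::E(g)$n_reactions <- lengths(net$provenance)
  }
  g
}

#' @export
print.interactome <- function(x, ...) {
  n_acc <- sum(x$nodes$class == "ACCESSIONED")
  n_sm <- sum(x$nodes$class == "SMALL_MOLECULE")
  cfg <- if (is.null(x$config)) {
    ""
  } else {
    paste0(" [", x$config$entity_level, " level, SM: ", x$config$sm_mode, "]")
  }
  cat(sprintf("<interactome>%s %d nodes (%d accessioned, %d small molecules), %d edges, %d self-interacting\n",
              cfg, nrow(x$nodes), n_acc, n_sm, nrow(x$edges),
              sum(x$nodes$self_loop)))
  invisible(x)
}

#' @export
summary.interactome <- function(object, ...) topology_summary(object)

#' Export an interactome
#'
#' `write_network_graphml()` writes GraphML (node attributes `class`, `label`,
#' `self_loop`; edge attribute `n_reactions`); `write_network_edgelist()`
#' writes a TSV edge list with the supporting reaction ids. Node and edge
#' ordering is deterministic, so output is byte-stable.
#'
#' @param net An `"interactome"`.
#' @param file Output path.
#' @name network_export
#' @export
write_network_graphml <- function(net, file) {
  g <- as_igraph(net)
  igraph::V(g)$self_loop <- as.integer(igraph::V(g)$self_loop)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' @rdname network_export
#' @export
write_network_edgelist <- function(net, file) {
  stopifnot(inherits(net, "interactome"))
  df <- data.frame(from = net$edges$from, to = net$edges$to,
                   n_reactions = if (nrow(net$edges)) lengths(net$provenance) else integer(0),
                   reactions = vapply(net$provenance, paste, character(1),
                                      collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(file)
}
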