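# Extraction stage: walks a pathway-knowledgebase event store and emits the
# flattened participant table plus pathway hierarchy, applying the
# inclusion/exclusion rules (drugs, polymers, other entities, unreferenced
# genome-encoded entities and ChEBI-less small molecules are dropped at
# flattening). The store is a narrow read-only interface — events, containment
# edges, and per-reaction role slots holding entity trees — implemented here
# in memory so the stage is fully testable at desk scale. A live graph
# database export can be materialized into the same structure by any client
# and fed through unchanged.

#' In-memory knowledgebase store
#'
#' @param events Data frame with columns `id`, `kind` (`"PATHWAY"` or
#'   `"REACTION"`), `name`, `species`.
#' @param containment Data frame with columns `parent_id`, `child_id`
#'   (pathway-to-pathway and pathway-to-reaction edges).
#' @param participants Named list: for each reaction id, a list of role
#'   slots, each a `list(role = <INPUT|OUTPUT|CATALYST|REGULATOR>,
#'   tree = <entity_tree>)`.
#' @return An object of class `"reactome_store"`.
#' @export
reactome_store <- function(events, containment, participants = list()) {
  stopifnot(is.data.frame(events),
            all(c("id", "kind", "name", "species") %in% names(events)),
            is.data.frame(containment),
            all(c("parent_id", "child_id") %in% names(containment)),
            is.list(participants))
  events <- data.frame(lapply(events[c("id", "kind", "name", "species")],
                              as.character), stringsAsFactors = FALSE)
  if (!all(events$kind %in% c("PATHWAY", "REACTION"))) {
    stop("event kind must be PATHWAY or REACTION")
  }
  if (anyDuplicated(events$id)) stop("duplicate event ids")
  containment <- data.frame(lapply(containment[c("parent_id", "child_id")],
                                   as.character), stringsAsFactors = FALSE)
  structure(list(events = events, containment = unique(containment),
                 participants = participants),
            class = "reactome_store")
}

#' Fetch the pathway hierarchy from a store
#'
#' Returns all pathways and reaction-like events of the given species with
#' their containment/membership edges. Accidental containment cycles are
#' broken with a visited-set depth-first guard; each dropped back edge is
#' reported with a warning. Zero pathways for the species yields an
#' empty-result warning.
#'
#' @param store A [reactome_store()].
#' @param species Species filter (default `"Homo sapiens"`).
#' @return A [pathway_hierarchy()].
#' @export
fetch_pathway_hierarchy <- function(store, species = "Homo sapiens") {
  stopifnot(inherits(store, "reactome_store"))
  ev <- store$events[store$events$species == species, , drop = FALSE]
  pw <- ev$id[ev$kind == "PATHWAY"]
  rx <- ev$id[ev$kind == "REACTION"]
  if (!length(pw)) {
    warning("no pathways found for species '", species, "'")
    return(pathway_hierarchy(data.frame(parent_id = character(0),
                                        child_id = character(0),
                                        child_kind = character(0),
                                        stringsAsFactors = FALSE)))
  }
  cont <- store$containment
  cont <- cont[cont$parent_id %in% pw & cont$child_id %in% c(pw, rx), ,
               drop = FALSE]
  kind <- ifelse(cont$child_id %in% pw, "PATHWAY", "REACTION")

  ## cycle guard on pathway-pathway edges: depth-first walk dropping edges
  ## that close back into the current recursion stack
  pp <- which(kind == "PATHWAY")
  drop <- logical(nrow(cont))
  if (length(pp)) {
    kids <- split(pp, cont$parent_id[pp])
    state <- new.env(parent = emptyenv())
    visit <- function(p, stack) {
      for (e in kids[[p]] %||% integer(0)) {
        ch <- cont$child_id[e]
        if (ch %in% stack) {
          drop[e] <<- TRUE
          warning("pathway containment cycle broken at edge ", p, " -> ", ch)
        } else if (!isTRUE(state[[ch]])) {
          state[[ch]] <- TRUE
          visit(ch, c(stack, ch))
        }
      }
    }
    for (root in sort(unique(cont$parent_id[pp]))) {
      if (!isTRUE(state[[root]])) {
        state[[root]] <- TRUE
        visit(root, root)
      }
    }
  }
  keep <- !drop
  nm <- stats::setNames(ev$name, ev$id)
  pathway_hierarchy(data.frame(parent_id = cont$parent_id[keep],
                               child_id = cont$child_id[keep],
                               child_kind = kind[keep],
                               stringsAsFactors = FALSE),
                    names = nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the flattened participant table from a store
#'
#' For every reaction of the species, each role slot's entity tree is
#' flattened via [flatten_entity_tree()] and emitted as participant records;
#' excluded participant classes never reach the output (a message reports the
#' tally of exclusion reasons). Each reaction's rows are emitted once, under
#' its first containing pathway; full pathway membership lives in the
#' hierarchy.
#'
#' @param store A [reactome_store()].
#' @param species Species filter (default `"Homo sapiens"`).
#' @return List with `records` (validated participant table) and `hierarchy`.
#' @export
extract_participant_table <- function(store, species = "Homo sapiens") {
  stopifnot(inherits(store, "reactome_store"))
  hierarchy <- fetch_pathway_hierarchy(store, species)
  memb <- hierarchy[hierarchy$child_kind == "REACTION", , drop = FALSE]
  first_parent <- tapply(memb$parent_id, memb$child_id, min)
  rxs <- sort(names(first_parent))
  excluded <- character(0)
  rows <- lapply(rxs, function(r) {
    slots <- store$participants[[r]]
    if (is.null(slots)) return(NULL)
    do.call(rbind, lapply(slots, function(sl) {
      stopifnot(sl$role %in% ROLES, inherits(sl$tree, "entity_tree"))
      flat <- flatten_entity_tree(sl$tree)
      excluded <<- c(excluded, attr(flat, "excluded"))
      if (!nrow(flat)) return(NULL)
      data.frame(pathway_id = unname(first_parent[r]), reaction_id = r,
                 role = sl$role, flat, stringsAsFactors = FALSE)
    }))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(excluded)) {
    tb <- table(excluded)
    message("excluded participants: ",
            paste(names(tb), as.integer(tb), sep = "=", collapse = ", "))
  }
  records <- if (length(rows)) {
    validate_participants(do.call(rbind, rows))
  } else {
    validate_participants(
      data.frame(pathway_id = character(0), reaction_id = character(0),
                 role = character(0), entity_class = character(0),
                 accession = character(0), gene_name = character(0),
                 isoform = character(0), ptms = character(0),
                 stringsAsFactors = FALSE))
  }
  list(records = records, hierarchy = hierarchy)
}
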