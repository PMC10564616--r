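# Canonical flattened data model: one row per leaf participant occurrence in a
# biochemical reaction, with role, entity class, and proteoform annotation.
# All other stages (network build, pathway subnetworks, synthetic generation)
# consume and emit this table.

ROLES <- c("INPUT", "OUTPUT", "CATALYST", "REGULATOR")
ENTITY_CLASSES <- c("ACCESSIONED", "SMALL_MOLECULE")
EXCLUSION_REASONS <- c("drug", "polymer", "other-entity",
                       "genome-encoded-without-reference",
                       "small-molecule-without-ChEBI")
PARTICIPANT_COLUMNS <- c("pathway_id", "reaction_id", "role", "entity_class",
                         "accession", "gene_name", "isoform", "ptms")

#' Canonicalize a post-translational modification list
#'
#' A PTM list is a comma-separated multiset of `"mod:pos"` tokens, where `mod`
#' is a PSI-MOD accession (e.g. `"00046"` for O-phospho-L-serine) and `pos` is
#' a 1-based amino-acid position or `"null"` when the position is unknown.
#' The canonical form sorts tokens by modification type, then position, with
#' unknown positions last; multiplicity is preserved (two identical
#' modifications count twice).
#'
#' @param x Character vector of PTM lists (`""` or `NA` mean no PTMs).
#' @return Character vector of canonical PTM lists.
#' @export
#' @examples
#' canonical_ptms("00046:35,00046:12")   # "00046:12,00046:35"
#' canonical_ptms("00046:null,00046:9")  # unknown position sorts last
canonical_ptms <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return("")
    bad <- !grepl("^[^:,;[:space:]]+:(null|[0-9]+)$", parts)
    if (any(bad)) {
      stop("malformed PTM token '", parts[bad][1],
           "' (expected \"mod:pos\" with pos a positive integer or \"null\")",
           call. = FALSE)
    }
    mod <- sub(":[^:]*$", "", parts)
    pos <- sub("^.*:", "", parts)
    posn <- suppressWarnings(as.integer(pos))
    if (any(!is.na(posn) & posn < 1L)) {
      stop("PTM positions are 1-based; got ", min(posn, na.rm = TRUE),
           call. = FALSE)
    }
    ord <- order(mod, is.na(posn), posn, method = "radix")
    paste(parts[ord], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a proteoform identity
#'
#' A proteoform is a specific molecular form of a protein: a UniProt
#' accession, an optional isoform suffix, and a multiset of post-translational
#' modifications. Two proteoforms are equal iff all three agree; the PTM
#' multiset is stored in canonical order so equality is independent of input
#' order. A missing isoform is distinct from an explicitly annotated canonical
#' isoform string (no normalization of `"P30044"` vs `"P30044-1"`).
#'
#' @param accession UniProt accession (non-empty string).
#' @param isoform Optional isoform suffix (e.g. `"2"`); `NULL`, `NA` or `""`
#'   mean no isoform annotation.
#' @param ptms PTM list as for [canonical_ptms()], or a character vector of
#'   `"mod:pos"` tokens.
#' @return An object of class `"proteoform"`.
#' @seealso [format_proteoform()], [parse_proteoform()]
#' @export
proteoform <- function(accession, isoform = NULL, ptms = "") {
  accession <- as.character(accession)
  if (length(accession) != 1L || is.na(accession) || !nzchar(accession)) {
    stop("'accession' must be a single non-empty string")
  }
  iso <- if (is.null(isoform) || length(isoform) == 0L || is.na(isoform[1]) ||
             !nzchar(as.character(isoform[1]))) {
    ""
  } else {
    as.character(isoform[1])
  }
  if (length(ptms) > 1L) ptms <- paste(ptms, collapse = ",")
  structure(list(accession = accession, isoform = iso,
                 ptms = canonical_ptms(ptms)),
            class = "proteoform")
}

#' Serialize a proteoform to its canonical string
#'
#' Format is `"ACCESSION[-ISOFORM];mod:pos,mod:pos,..."` with PTMs in
#' canonical order and unknown positions rendered `"null"`. The string
#' round-trips through [parse_proteoform()] and is the node key used by
#' proteoform-centric networks.
#'
#' @param p A `"proteoform"` object.
#' @return A single string, e.g. `"P30044-2;"` or `"Q99999;00046:12,00046:35"`.
#' @export
format_proteoform <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  proteoform_key(p$accession, p$isoform, p$ptms)
}

#' Vectorized proteoform node key
#'
#' Column-wise version of [format_proteoform()] used when keying whole
#' participant tables.
#'
#' @param accession,isoform,ptms Character vectors (recycled to a common
#'   length); `NA` isoform/ptms are treated as empty.
#' @return Character vector of canonical proteoform strings.
#' @export
proteoform_key <- function(accession, isoform = "", ptms = "") {
  n <- length(accession)
  isoform <- rep_len(as.character(isoform), n)
  ptms <- rep_len(as.character(ptms), n)
  isoform[is.na(isoform)] <- ""
  ptms[is.na(ptms)] <- ""
  nz <- nzchar(ptms)
  if (any(nz)) {
    u <- unique(ptms[nz])
    cu <- canonical_ptms(u)
    ptms[nz] <- cu[match(ptms[nz], u)]
  }
  paste0(accession,
         ifelse(nzchar(isoform), paste0("-", isoform), ""),
         ";", ptms)
}

#' Parse a canonical proteoform string
#'
#' Inverse of [format_proteoform()].
#'
#' @param s A single proteoform string, e.g. `"P30044-2;"`.
#' @return A `"proteoform"` object.
#' @export
parse_proteoform <- function(s) {
  s <- as.character(s)
  stopifnot(length(s) == 1L)
  i <- regexpr(";", s, fixed = TRUE)
  if (i < 0L) stop("not a proteoform string (missing ';'): ", s)
  head <- substr(s, 1L, i - 1L)
  ptms <- substring(s, i + 1L)
  j <- regexpr("-", head, fixed = TRUE)
  if (j > 0L) {
    proteoform(substr(head, 1L, j - 1L), substring(head, j + 1L), ptms)
  } else {
    proteoform(head, NULL, ptms)
  }
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform>", format_proteoform(x), "\n")
  invisible(x)
}

## ---- entity trees ----------------------------------------------------------

new_entity_node <- function(kind, children = list(), payload = list()) {
  structure(list(kind = kind, children = children, payload = payload),
            class = "entity_tree")
}

#' Entity-tree constructors
#'
#' Reaction participants in pathway knowledgebases are trees: complexes and
#' entity sets nest accessioned entities (proteins), small molecules, further
#' complexes/sets, and excluded participant classes (drugs, polymers,
#' `OtherEntity`, genome-encoded entities without a reference identifier,
#' simple entities without a ChEBI accession). These constructors build such
#' trees; [flatten_entity_tree()] reduces them to leaf participants.
#'
#' @param accession UniProt (protein) or ChEBI (small molecule) identifier.
#' @param gene Optional HGNC gene symbol for a protein leaf.
#' @param isoform,ptms Optional proteoform annotation for a protein leaf.
#' @param chebi ChEBI accession of a small molecule.
#' @param ... Child `"entity_tree"` nodes (at least one).
#' @param reason Exclusion reason, one of `"drug"`, `"polymer"`,
#'   `"other-entity"`, `"genome-encoded-without-reference"`,
#'   `"small-molecule-without-ChEBI"`.
#' @return An `"entity_tree"` node.
#' @name entity_tree
NULL

#' @rdname entity_tree
#' @export
entity_protein <- function(accession, gene = "", isoform = "", ptms = "") {
  stopifnot(nzchar(accession))
  new_entity_node("LEAF_ACCESSIONED",
                  payload = list(entity_class = "ACCESSIONED",
                                 accession = as.character(accession),
                                 gene_name = if (is.na(gene)) "" else as.character(gene),
                                 isoform = if (is.na(isoform)) "" else as.character(isoform),
                                 ptms = canonical_ptms(ptms)))
}

#' @rdname entity_tree
#' @export
entity_small_molecule <- function(chebi) {
  stopifnot(nzchar(chebi))
  new_entity_node("LEAF_SMALL_MOLECULE",
                  payload = list(entity_class = "SMALL_MOLECULE",
                                 accession = as.character(chebi),
                                 gene_name = "", isoform = "", ptms = ""))
}

#' @rdname entity_tree
#' @export
entity_complex <- function(...) {
  children <- list(...)
  if (!length(children)) stop("COMPLEX must have at least one child")
  stopifnot(all(vapply(children, inherits, logical(1), "entity_tree")))
  new_entity_node("COMPLEX", children = children)
}

#' @rdname entity_tree
#' @export
entity_set <- function(...) {
  children <- list(...)
  if (!length(children)) stop("ENTITY_SET must have at least one child")
  stopifnot(all(vapply(children, inherits, logical(1), "entity_tree")))
  new_entity_node("ENTITY_SET", children = children)
}

#' @rdname entity_tree
#' @export
entity_excluded <- function(reason) {
  reason <- match.arg(reason, EXCLUSION_REASONS)
  new_entity_node("EXCLUDED", payload = list(reason = reason))
}

#' Flatten an entity tree to its leaf participants
#'
#' Recursively splits complexes and entity sets into the accessioned entities
#' and small molecules they consist of. Excluded leaves (drugs, polymers,
#' other entities, unreferenced genome-encoded entities, small molecules
#' without ChEBI accession) are dropped; their reasons are attached as the
#' `"excluded"` attribute of the result. Duplicate leaves are preserved —
#' deduplication happens later, at node-keying time, where duplicates within a
#' reaction become self-interaction flags.
#'
#' @param tree An `"entity_tree"`.
#' @return A data frame with columns `entity_class`, `accession`, `gene_name`,
#'   `isoform`, `ptms`, one row per included leaf (zero rows if everything was
#'   excluded), with attribute `"excluded"` a character vector of exclusion
#'   reasons encountered.
#' @export
flatten_entity_tree <- function(tree) {
  stopifnot(inherits(tree, "entity_tree"))
  leaves <- list()
  excluded <- character(0)
  walk <- function(node) {
    kind <- node$kind
    if (kind %in% c("COMPLEX", "ENTITY_SET")) {
      if (!length(node$children)) {
        stop("malformed entity tree: ", kind, " node with no children")
      }
      for (ch in node$children) walk(ch)
    } else if (kind == "EXCLUDED") {
      excluded[length(excluded) + 1L] <<- node$payload$reason
    } else if (kind %in% c("LEAF_ACCESSIONED", "LEAF_SMALL_MOLECULE")) {
      if (length(node$children)) {
        stop("malformed entity tree: leaf node with children")
      }
      leaves[[length(leaves) + 1L]] <<- node$payload
    } else {
      stop("unknown entity tree node kind: ", kind)
    }
  }
  walk(tree)
  out <- if (length(leaves)) {
    data.frame(
      entity_class = vapply(leaves, `[[`, character(1), "entity_class"),
      accession    = vapply(leaves, `[[`, character(1), "accession"),
      gene_name    = vapply(leaves, `[[`, character(1), "gene_name"),
      isoform      = vapply(leaves, `[[`, character(1), "isoform"),
      ptms         = vapply(leaves, `[[`, character(1), "ptms"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(entity_class = character(0), accession = character(0),
               gene_name = character(0), isoform = character(0),
               ptms = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "excluded") <- excluded
  out
}

## ---- participant table -----------------------------------------------------

#' Validate (and normalize) a participant table
#'
#' Checks the invariants of the flattened participant model: every record has
#' a reaction id and an accession; roles are one of INPUT, OUTPUT, CATALYST,
#' REGULATOR; small molecules carry no isoform or PTM annotation. PTM lists
#' are rewritten in canonical order and `NA` optional fields become `""`.
#'
#' @param records Data frame with columns `pathway_id`, `reaction_id`, `role`,
#'   `entity_class`, `accession`, `gene_name`, `isoform`, `ptms`.
#' @return The normalized data frame (invisibly usable anywhere a participant
#'   table is expected). Errors mention the first offending row number.
#' @export
validate_participants <- function(records) {
  if (!is.data.frame(records)) stop("participant table must be a data.frame")
  miss <- setdiff(PARTICIPANT_COLUMNS, names(records))
  if (length(miss)) {
    stop("participant table is missing columns: ", paste(miss, collapse = ", "))
  }
  rec <- records[PARTICIPANT_COLUMNS]
  for (cn in PARTICIPANT_COLUMNS) {
    v <- as.character(rec[[cn]])
    v[is.na(v)] <- ""
    rec[[cn]] <- v
  }
  fail <- function(rows, msg) {
    stop(sprintf("participant table row %d: %s", rows[1], msg), call. = FALSE)
  }
  bad <- !nzchar(rec$reaction_id)
  if (any(bad)) fail(which(bad), "missing reaction_id")
  bad <- !(rec$role %in% ROLES)
  if (any(bad)) {
    fail(which(bad), paste0("unknown role token '", rec$role[bad][1], "'"))
  }
  bad <- !(rec$entity_class %in% ENTITY_CLASSES)
  if (any(bad)) {
    fail(which(bad), paste0("unknown entity_class '", rec$entity_class[bad][1], "'"))
  }
  bad <- !nzchar(rec$accession)
  if (any(bad)) fail(which(bad), "missing accession")
  sm <- rec$entity_class == "SMALL_MOLECULE"
  bad <- sm & (nzchar(rec$ptms) | nzchar(rec$isoform))
  if (any(bad)) {
    fail(which(bad), "small molecules cannot carry isoform or PTM annotation")
  }
  nz <- nzchar(rec$ptms)
  if (any(nz)) {
    u <- unique(rec$ptms[nz])
    cu <- vapply(u, function(s) {
      tryCatch(canonical_ptms(s), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    if (anyNA(cu)) {
      badval <- u[is.na(cu)][1]
      fail(which(rec$ptms == badval), paste0("malformed PTM list '", badval, "'"))
    }
    rec$ptms[nz] <- cu[match(rec$ptms[nz], u)]
  }
  rownames(rec) <- NULL
  rec
}

#' Read / write the participant table TSV
#'
#' The canonical serialization is UTF-8, tab-delimited, with a header row and
#' columns `pathway_id`, `reaction_id`, `role`, `entity_class`, `accession`,
#' `gene_name`, `isoform`, `ptms`. Writing is byte-stable for a fixed input:
#' rows are sorted by (pathway, reaction, role, entity class, accession,
#' isoform, PTMs) regardless of input order. Lines starting with `#` are
#' treated as comments on input.
#'
#' @param file Path to a TSV file.
#' @param records A participant table (validated on the way in and out).
#' @return `read_participant_table()` returns the validated table;
#'   `write_participant_table()` returns `file` invisibly.
#' @name participant_table_io
#' @export
read_participant_table <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_participants(df)
}

#' @rdname participant_table_io
#' @export
write_participant_table <- function(records, file) {
  rec <- validate_participants(records)
  o <- order(rec$pathway_id, rec$reaction_id, rec$role, rec$entity_class,
             rec$accession, rec$isoform, rec$ptms, method = "radix")
  utils::write.table(rec[o, , drop = FALSE], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(file)
}

## ---- pathway hierarchy -----------------------------------------------------

#' Construct a pathway hierarchy
#'
#' A pathway hierarchy is the containment structure of a pathway
#' knowledgebase: edges from a pathway to the sub-pathways and reactions it
#' contains. Containment among pathways must be acyclic (a cycle guard is
#' enforced at construction); reaction membership edges are unrestricted.
#'
#' @param edges Data frame with columns `parent_id`, `child_id`, `child_kind`
#'   (`"PATHWAY"` or `"REACTION"`).
#' @param names Optional named character vector of display names keyed by id.
#' @return A data frame of class `"pathway_hierarchy"`.
#' @export
pathway_hierarchy <- function(edges, names = NULL) {
  stopifnot(is.data.frame(edges))
  req <- c("parent_id", "child_id", "child_kind")
  miss <- setdiff(req, base::names(edges))
  if (length(miss)) stop("hierarchy is missing columns: ", paste(miss, collapse = ", "))
  h <- edges[req]
  for (cn in req) h[[cn]] <- as.character(h[[cn]])
  bad <- !(h$child_kind %in% c("PATHWAY", "REACTION"))
  if (any(bad)) stop("unknown child_kind '", h$child_kind[bad][1], "'")
  if (any(!nzchar(h$parent_id) | !nzchar(h$child_id))) {
    stop("hierarchy ids must be non-empty")
  }
  h <- unique(h)
  cont <- h[h$child_kind == "PATHWAY", c("parent_id", "child_id"), drop = FALSE]
  if (nrow(cont)) {
    g <- igraph::graph_from_data_frame(cont, directed = TRUE)
    if (!igraph::is_dag(g)) {
      stop("pathway containment contains a cycle; refusing to build hierarchy")
    }
  }
  o <- order(h$parent_id, h$child_kind, h$child_id, method = "radix")
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "display_names") <- names
  class(h) <- c("pathway_hierarchy", "data.frame")
  h
}

#' Hierarchy accessors
#'
#' @param hierarchy A `"pathway_hierarchy"`.
#' @return Sorted character vector of pathway ids (all ids that appear as a
#'   parent or as a PATHWAY child) or reaction ids.
#' @name hierarchy_accessors
#' @export
hierarchy_pathways <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  sort(unique(c(hierarchy$parent_id,
                hierarchy$child_id[hierarchy$child_kind == "PATHWAY"])))
}

#' @rdname hierarchy_accessors
#' @export
hierarchy_reactions <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  sort(unique(hierarchy$child_id[hierarchy$child_kind == "REACTION"]))
}

#' Read / write the pathway hierarchy TSV
#'
#' Columns `parent_id`, `child_id`, `child_kind`; same conventions as the
#' participant table (tab-delimited, header, byte-stable canonical order).
#'
#' @param file Path to a TSV file.
#' @param hierarchy A `"pathway_hierarchy"`.
#' @name hierarchy_io
#' @export
read_pathway_hierarchy <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  pathway_hierarchy(df)
}

#' @rdname hierarchy_io
#' @export
write_pathway_hierarchy <- function(hierarchy, file) {
  h <- pathway_hierarchy(as.data.frame(hierarchy))
  utils::write.table(h, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a participant table together with its hierarchy
#'
#' @param table_file,hierarchy_file TSV paths as written by
#'   [write_participant_table()] and [write_pathway_hierarchy()].
#' @return A list with elements `records` and `hierarchy`.
#' @export
parse_participant_table <- function(table_file, hierarchy_file) {
  list(records = read_participant_table(table_file),
       hierarchy = read_pathway_hierarchy(hierarchy_file))
}
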