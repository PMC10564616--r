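# Synthetic pathway-knowledgebase generator. Emulates the event structure of
# a curated reaction database: nested pathways containing reactions,
# participants with roles, nested complexes and entity sets (flattened
# through the same code path as real extraction), proteoform annotation of
# configurable sparsity, and a small set of ubiquitous small molecules
# (ATP/H2O-like) that join a large fraction of reactions. Optional planted
# motifs carry exact ground truth for validating the downstream analyses.

#' Synthetic generator configuration
#'
#' Defaults describe a mid-sized knowledgebase: ~200 pathways with ~10
#' reactions each, 1000 proteins averaging 1.3 distinct proteoforms per
#' protein, and 5 ubiquitous small molecules joining 35% of reactions each.
#' Background reactions draw at least `min_accessioned` distinct proteins
#' (without replacement), so every background protein keeps at least one
#' protein-protein edge; self-interactions still arise through homodimeric
#' complexes and planted motifs. All randomness flows from `seed`; identical
#' config + seed gives a byte-identical table.
#'
#' @param seed Integer seed.
#' @param n_pathways Total number of pathways (nesting included).
#' @param p_subpathway Probability a pathway is attached under an existing
#'   pathway rather than at top level.
#' @param max_depth Maximum pathway nesting depth.
#' @param lambda_reactions Reactions per pathway are `1 + Poisson(lambda)`.
#' @param n_proteins Size of the protein pool.
#' @param mean_proteoforms Target mean number of distinct proteoforms per
#'   protein (`>= 1`); per-protein repertoire size is
#'   `1 + Poisson(mean_proteoforms - 1)`.
#' @param p_isoform_state Probability a non-canonical proteoform state gets an
#'   isoform suffix (it always gets a PTM set).
#' @param lambda_ptms PTMs per modified proteoform are `1 + Poisson(lambda)`.
#' @param p_unknown_pos Probability a PTM position is unknown (`"null"`).
#' @param n_small_molecules Size of the small-molecule (ChEBI) pool; 0
#'   disables small molecules entirely.
#' @param n_ubiquitous Number of ubiquitous small molecules (must not exceed
#'   `n_small_molecules`).
#' @param p_ubiquitous Per-reaction inclusion probability of each ubiquitous
#'   small molecule.
#' @param lambda_extra_sm Non-ubiquitous small molecules per reaction are
#'   `Poisson(lambda)`.
#' @param min_accessioned,lambda_accessioned Distinct proteins per background
#'   reaction are `min_accessioned + Poisson(lambda_accessioned)`.
#' @param locality_fraction Fraction of the (non-loner) protein pool available
#'   to each pathway: pathways draw their participants from a contiguous
#'   block of this size, giving the modular community structure of a curated
#'   knowledgebase (articulation points and bridges live on the sparse
#'   cross-pathway overlap).
#' @param p_crosstalk Probability an accessioned slot is drawn from the global
#'   pool instead of the pathway's own block.
#' @param p_self_reaction Probability a reaction contains a single protein
#'   performing multiple roles (input and output) and no other accessioned
#'   entity — the mechanism behind isolated self-interacting nodes, which
#'   small molecules may then rescue into the connected network.
#' @param loner_fraction Fraction of the protein pool reserved for self-role
#'   reactions, so those proteins never co-occur with another protein.
#' @param p_complex Probability the participants of one role slot are wrapped
#'   in a complex.
#' @param p_entity_set Probability a complex nests an entity set.
#' @param p_homodimer Probability a complex duplicates its first subunit
#'   (yielding a within-reaction self-interaction).
#' @param p_drug_leaf Probability an excluded drug leaf is attached (dropped
#'   at flattening, exercising the exclusion path).
#' @param role_probs Named probabilities for INPUT/OUTPUT/CATALYST/REGULATOR.
#' @param plant_sm_dependent Plant a thiamin-style pathway with this many
#'   proteins connected only through small molecules (0 = none).
#' @param plant_family_specific Plant this many proteoform families whose
#'   members participate in disjoint reactions.
#' @param plant_articulation Plant a star motif with this many leaves around
#'   one hub protein (>= 2 makes the hub an articulation point).
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_pathways = 200L,
                         p_subpathway = 0.25,
                         max_depth = 3L,
                         lambda_reactions = 9,
                         n_proteins = 1000L,
                         mean_proteoforms = 1.3,
                         p_isoform_state = 0.5,
                         lambda_ptms = 0.7,
                         p_unknown_pos = 0.1,
                         n_small_molecules = 150L,
                         n_ubiquitous = 5L,
                         p_ubiquitous = 0.35,
                         lambda_extra_sm = 0.8,
                         min_accessioned = 2L,
                         lambda_accessioned = 2,
                         locality_fraction = 0.05,
                         p_crosstalk = 0.05,
                         p_self_reaction = 0.1,
                         loner_fraction = 0.05,
                         p_complex = 0.25,
                         p_entity_set = 0.15,
                         p_homodimer = 0.05,
                         p_drug_leaf = 0.02,
                         role_probs = c(INPUT = 0.4, OUTPUT = 0.4,
                                        CATALYST = 0.15, REGULATOR = 0.05),
                         plant_sm_dependent = 0L,
                         plant_family_specific = 0L,
                         plant_articulation = 0L) {
  cfg <- list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
              p_subpathway = p_subpathway, max_depth = as.integer(max_depth),
              lambda_reactions = lambda_reactions,
              n_proteins = as.integer(n_proteins),
              mean_proteoforms = mean_proteoforms,
              p_isoform_state = p_isoform_state, lambda_ptms = lambda_ptms,
              p_unknown_pos = p_unknown_pos,
              n_small_molecules = as.integer(n_small_molecules),
              n_ubiquitous = as.integer(n_ubiquitous),
              p_ubiquitous = p_ubiquitous, lambda_extra_sm = lambda_extra_sm,
              min_accessioned = as.integer(min_accessioned),
              lambda_accessioned = lambda_accessioned,
              locality_fraction = locality_fraction,
              p_crosstalk = p_crosstalk,
              p_self_reaction = p_self_reaction,
              loner_fraction = loner_fraction,
              p_complex = p_complex, p_entity_set = p_entity_set,
              p_homodimer = p_homodimer, p_drug_leaf = p_drug_leaf,
              role_probs = role_probs,
              plant_sm_dependent = as.integer(plant_sm_dependent),
              plant_family_specific = as.integer(plant_family_specific),
              plant_articulation = as.integer(plant_articulation))
  probs <- c(cfg$p_subpathway, cfg$p_isoform_state, cfg$p_unknown_pos,
             cfg$p_ubiquitous, cfg$p_complex, cfg$p_entity_set,
             cfg$p_homodimer, cfg$p_drug_leaf, cfg$role_probs,
             cfg$locality_fraction, cfg$p_crosstalk, cfg$p_self_reaction,
             cfg$loner_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_pathways < 1L) stop("infeasible config: need at least one pathway")
  if (cfg$n_proteins < 1L) stop("infeasible config: need at least one protein")
  if (cfg$mean_proteoforms < 1) stop("mean_proteoforms must be >= 1")
  if (cfg$min_accessioned < 1L) stop("min_accessioned must be >= 1")
  if (cfg$min_accessioned > cfg$n_proteins) {
    stop("min_accessioned cannot exceed n_proteins")
  }
  if (cfg$n_small_molecules < 0L || cfg$n_ubiquitous < 0L) {
    stop("counts must be >= 0")
  }
  if (cfg$n_ubiquitous > cfg$n_small_molecules) {
    stop("n_ubiquitous cannot exceed n_small_molecules")
  }
  if (!setequal(names(cfg$role_probs), ROLES)) {
    stop("role_probs must be named INPUT/OUTPUT/CATALYST/REGULATOR")
  }
  if (cfg$plant_articulation == 1L) {
    stop("plant_articulation needs >= 2 leaves to create an articulation point")
  }
  structure(cfg, class = "synth_config")
}

SYNTH_MOD_TYPES <- c("00046", "00047", "00048", "01148", "00134")

participant_row <- function(pathway_id, reaction_id, role, leaf_df) {
  if (!nrow(leaf_df)) return(NULL)
  data.frame(pathway_id = pathway_id, reaction_id = reaction_id, role = role,
             leaf_df, stringsAsFactors = FALSE)
}

# wrap role-slot leaves into complexes / entity sets per config, then flatten
# through the shared entity-tree code path
assemble_role_leaves <- function(leaves, cfg) {
  if (length(leaves) >= 2L && stats::runif(1) < cfg$p_complex) {
    kids <- leaves
    if (length(kids) >= 3L && stats::runif(1) < cfg$p_entity_set) {
      kids <- c(list(do.call(entity_set, kids[1:2])), kids[-(1:2)])
    }
    if (stats::runif(1) < cfg$p_homodimer) kids <- c(kids, kids[1])
    if (stats::runif(1) < cfg$p_drug_leaf) {
      kids <- c(kids, list(entity_excluded("drug")))
    }
    trees <- list(do.call(entity_complex, kids))
  } else {
    trees <- leaves
    if (stats::runif(1) < cfg$p_drug_leaf) {
      trees <- c(trees, list(entity_excluded("drug")))
    }
  }
  do.call(rbind, lapply(trees, flatten_entity_tree))
}

#' Generate a synthetic participant table with ground truth
#'
#' Emits a schema-valid participant table plus pathway hierarchy, with all
#' nested complexes and entity sets flattened through the same
#' [flatten_entity_tree()] code path used by extraction, and a ground-truth
#' record of quantities the pipeline should recover: distinct node counts per
#' network variant (from independent enumeration of the emitted rows), the
#' realized mean number of proteoforms per protein, the full expected
#' family-specific accession set, and the planted motif structures.
#'
#' @param config A [synth_config()].
#' @return List with elements `records` (participant table), `hierarchy`
#'   ([pathway_hierarchy()]), `truth` (ground-truth list) and `config`.
#' @export
simulate_reactome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  cfg <- config
  np <- cfg$n_proteins

  ## protein pool and per-protein proteoform repertoires
  prot_acc <- sprintf("P%05d", seq_len(np))
  gene <- sprintf("GENE%04d", seq_len(np))
  k_states <- 1L + stats::rpois(np, cfg$mean_proteoforms - 1)
  states <- vector("list", np)
  for (i in seq_len(np)) {
    st <- list(list(isoform = "", ptms = ""))
    if (k_states[i] > 1L) {
      sigs <- ";"
      for (j in 2:k_states[i]) {
        repeat {
          iso <- if (stats::runif(1) < cfg$p_isoform_state) as.character(j) else ""
          nptm <- 1L + stats::rpois(1, cfg$lambda_ptms)
          mods <- sample(SYNTH_MOD_TYPES, nptm, replace = TRUE)
          pos <- ifelse(stats::runif(nptm) < cfg$p_unknown_pos, "null",
                        as.character(sample.int(800L, nptm, replace = TRUE)))
          ptms <- canonical_ptms(paste(paste0(mods, ":", pos), collapse = ","))
          sig <- paste0(iso, ";", ptms)
          if (!(sig %in% sigs)) break
        }
        sigs <- c(sigs, sig)
        st[[j]] <- list(isoform = iso, ptms = ptms)
      }
    }
    states[[i]] <- st
  }

  ## small-molecule pool
  n_sm <- cfg$n_small_molecules
  sm_ids <- if (n_sm > 0L) sprintf("CHEBI:%05d", seq_len(n_sm)) else character(0)
  ubiq <- if (cfg$n_ubiquitous > 0L) sm_ids[seq_len(cfg$n_ubiquitous)] else character(0)
  other_sm <- setdiff(sm_ids, ubiq)

  ## pathway tree
  n_pw <- cfg$n_pathways
  pw_id <- sprintf("PW%05d", seq_len(n_pw))
  pw_parent <- rep(NA_character_, n_pw)
  depth <- rep(1L, n_pw)
  if (n_pw > 1L) {
    for (i in 2:n_pw) {
      if (stats::runif(1) < cfg$p_subpathway) {
        cand <- which(depth[seq_len(i - 1L)] < cfg$max_depth)
        if (length(cand)) {
          p <- cand[sample.int(length(cand), 1L)]
          pw_parent[i] <- pw_id[p]
          depth[i] <- depth[p] + 1L
        }
      }
    }
  }
  n_rx_per <- 1L + stats::rpois(n_pw, cfg$lambda_reactions)
  rx_pathway <- rep(pw_id, n_rx_per)
  rx_id <- sprintf("RX%06d", seq_along(rx_pathway))

  ## community structure: loner proteins appear only in self-role reactions;
  ## every pathway draws the rest of its participants from its own
  ## contiguous block of the main pool, with occasional cross-talk
  n_loner <- min(round(np * cfg$loner_fraction), np - cfg$min_accessioned)
  n_main <- np - n_loner
  loner_pool <- if (n_loner > 0L) (n_main + 1L):np else integer(0)
  block_size <- max(cfg$min_accessioned + 2L,
                    round(n_main * cfg$locality_fraction))
  block_size <- min(block_size, n_main)
  pw_block <- lapply(seq_len(n_pw), function(i) {
    start <- sample.int(n_main, 1L)
    1L + (start + 0:(block_size - 1L) - 1L) %% n_main
  })
  names(pw_block) <- pw_id

  ## background reactions
  rows <- vector("list", length(rx_id) + 3L)
  ri <- 0L
  for (r in seq_along(rx_id)) {
    if (stats::runif(1) < cfg$p_self_reaction) {
      ## one protein in multiple roles, no other accessioned entity
      pool <- if (length(loner_pool)) loner_pool else pw_block[[rx_pathway[r]]]
      s <- pool[sample.int(length(pool), 1L)]
      pidx <- c(s, s)
      roles <- c("INPUT", "OUTPUT")
    } else {
      block <- pw_block[[rx_pathway[r]]]
      n_acc <- min(cfg$min_accessioned + stats::rpois(1, cfg$lambda_accessioned),
                   length(block))
      pidx <- block[sample.int(length(block), n_acc)]
      cross <- stats::runif(n_acc) < cfg$p_crosstalk
      if (any(cross)) {
        repl <- sample.int(n_main, sum(cross))
        ok <- !(repl %in% pidx)
        pidx[cross][ok] <- repl[ok]
      }
      roles <- sample(ROLES, n_acc, replace = TRUE, prob = cfg$role_probs[ROLES])
      roles[1] <- "INPUT"
      if (n_acc >= 2L) roles[2] <- "OUTPUT"
    }
    leaves <- lapply(pidx, function(s) {
      stt <- states[[s]][[sample.int(k_states[s], 1L)]]
      entity_protein(prot_acc[s], gene[s], stt$isoform, stt$ptms)
    })
    sm_here <- character(0)
    if (length(ubiq)) sm_here <- ubiq[stats::runif(length(ubiq)) < cfg$p_ubiquitous]
    if (length(other_sm) && cfg$lambda_extra_sm > 0) {
      nex <- min(stats::rpois(1, cfg$lambda_extra_sm), length(other_sm))
      if (nex > 0L) sm_here <- c(sm_here, sample(other_sm, nex))
    }
    if (length(sm_here)) {
      leaves <- c(leaves, lapply(sm_here, entity_small_molecule))
      roles <- c(roles, sample(ROLES, length(sm_here), replace = TRUE,
                               prob = cfg$role_probs[ROLES]))
    }
    rx_rows <- lapply(unique(roles), function(rl) {
      participant_row(rx_pathway[r], rx_id[r], rl,
                      assemble_role_leaves(leaves[roles == rl], cfg))
    })
    ri <- ri + 1L
    rows[[ri]] <- do.call(rbind, rx_rows)
  }

  hier_edges <- data.frame(parent_id = rx_pathway, child_id = rx_id,
                           child_kind = "REACTION", stringsAsFactors = FALSE)
  has_par <- !is.na(pw_parent)
  if (any(has_par)) {
    hier_edges <- rbind(hier_edges,
                        data.frame(parent_id = pw_parent[has_par],
                                   child_id = pw_id[has_par],
                                   child_kind = "PATHWAY",
                                   stringsAsFactors = FALSE))
  }

  ## planted motifs (reserved deterministic identifiers)
  planted <- list(sm_dependent_genes = character(0),
                  sm_dependent_proteoforms = character(0),
                  family_specific = character(0),
                  articulation_hub = character(0),
                  articulation_leaves = character(0),
                  thiamin = NULL)
  if (cfg$plant_sm_dependent > 0L) {
    thi <- plant_thiamin_motif(cfg$plant_sm_dependent)
    ri <- ri + 1L
    rows[[ri]] <- thi$records
    hier_edges <- rbind(hier_edges, as.data.frame(thi$hierarchy))
    planted$sm_dependent_genes <- thi$truth$genes
    planted$sm_dependent_proteoforms <- thi$truth$proteoforms
    planted$thiamin <- thi$truth
  }
  if (cfg$plant_family_specific > 0L) {
    fam <- plant_family_motif(cfg$plant_family_specific)
    ri <- ri + 1L
    rows[[ri]] <- fam$records
    hier_edges <- rbind(hier_edges, as.data.frame(fam$hierarchy))
    planted$family_specific <- fam$truth$accessions
  }
  if (cfg$plant_articulation > 0L) {
    hub <- plant_articulation_motif(cfg$plant_articulation)
    ri <- ri + 1L
    rows[[ri]] <- hub$records
    hier_edges <- rbind(hier_edges, as.data.frame(hub$hierarchy))
    planted$articulation_hub <- hub$truth$hub
    planted$articulation_leaves <- hub$truth$leaves
  }

  records <- validate_participants(do.call(rbind, rows[seq_len(ri)]))
  hierarchy <- pathway_hierarchy(hier_edges)

  ## ground truth by independent enumeration over the emitted rows
  acc <- records$entity_class == "ACCESSIONED"
  sm_rows <- !acc
  gene_keys <- unique(ifelse(nzchar(records$gene_name[acc]),
                             records$gene_name[acc], records$accession[acc]))
  prot_keys <- unique(proteoform_key(records$accession[acc],
                                     records$isoform[acc], records$ptms[acc]))
  smg <- unique(records$accession[sm_rows])
  smru <- unique(paste(records$accession[sm_rows], records$reaction_id[sm_rows]))
  per_acc <- tapply(proteoform_key(records$accession[acc],
                                   records$isoform[acc], records$ptms[acc]),
                    records$accession[acc],
                    function(k) length(unique(k)))
  nodes_by_variant <- data.frame(
    entity_level = rep(c("gene", "proteoform"), each = 3L),
    sm_mode = rep(c("none", "global", "reaction_unique"), 2L),
    nodes = c(length(gene_keys), length(gene_keys) + length(smg),
              length(gene_keys) + length(smru),
              length(prot_keys), length(prot_keys) + length(smg),
              length(prot_keys) + length(smru)),
    stringsAsFactors = FALSE)

  gene_tally <- independent_isolation_tally(
    records, ifelse(nzchar(records$gene_name), records$gene_name,
                    records$accession))
  prot_tally <- independent_isolation_tally(
    records, proteoform_key(records$accession, records$isoform, records$ptms))

  truth <- list(
    n_pathways = length(hierarchy_pathways(hierarchy)),
    n_reactions = length(unique(records$reaction_id)),
    n_gene_nodes = length(gene_keys),
    n_proteoform_nodes = length(prot_keys),
    n_sm_nodes_global = length(smg),
    n_sm_nodes_reaction_unique = length(smru),
    nodes_by_variant = nodes_by_variant,
    mean_proteoforms_per_protein = mean(per_acc),
    family_specific = independent_family_tally(records),
    isolated_gene_none = gene_tally$isolated,
    sm_dependent_genes = gene_tally$sm_dependent,
    isolated_proteoform_none = prot_tally$isolated,
    sm_dependent_proteoforms = prot_tally$sm_dependent,
    planted = planted)
  list(records = records, hierarchy = hierarchy, truth = truth, config = cfg)
}

# direct per-row tally of which accessioned keys are isolated without small
# molecules and which of those are rescued by them: a key is isolated iff it
# is the only distinct accessioned key in every one of its reactions, and
# SM-dependent iff additionally at least one of its reactions contains a
# small molecule (kept separate from the network-build code path)
independent_isolation_tally <- function(records, acc_key) {
  acc <- records$entity_class == "ACCESSIONED"
  if (!any(acc)) return(list(isolated = character(0),
                             sm_dependent = character(0)))
  d <- unique(data.frame(key = acc_key[acc],
                         rid = records$reaction_id[acc],
                         stringsAsFactors = FALSE))
  keys_per_rxn <- tapply(d$key, d$rid, function(k) length(unique(k)))
  sm_rxns <- unique(records$reaction_id[!acc])
  by_key <- split(d$rid, d$key)
  isolated <- vapply(by_key, function(rids) {
    all(keys_per_rxn[rids] == 1L)
  }, logical(1))
  rescued <- vapply(by_key, function(rids) any(rids %in% sm_rxns), logical(1))
  list(isolated = sort(names(by_key)[isolated]),
       sm_dependent = sort(names(by_key)[isolated & rescued]))
}

# direct tally over table rows (kept separate from family_specificity(),
# which works through the keying machinery)
independent_family_tally <- function(records) {
  a <- records[records$entity_class == "ACCESSIONED", , drop = FALSE]
  if (!nrow(a)) return(character(0))
  form <- paste0(a$isoform, "|", a$ptms)
  d <- unique(data.frame(acc = a$accession, form = form, rid = a$reaction_id,
                         stringsAsFactors = FALSE))
  hits <- vapply(split(d, d$acc), function(f) {
    if (length(unique(f$form)) < 2L) return(FALSE)
    any(vapply(split(f$form, f$rid),
               function(x) length(unique(x)) == 1L, logical(1)))
  }, logical(1))
  sort(names(hits)[hits])
}

#' Plant a thiamin-metabolism-style motif
#'
#' Emits one pathway whose reactions each contain exactly one accessioned
#' entity performing multiple roles, plus small molecules shared across the
#' reactions (one common to all, one rotating partner). Consequences, by
#' construction: without small molecules every variant consists solely of
#' isolated self-interacting protein nodes; global small molecules connect
#' everything into one component; reaction-unique small molecules connect
#' within reactions only, giving exactly one component per reaction.
#'
#' @param n_proteins Number of proteins (= reactions). Default 3.
#' @param n_small_molecules Size of the shared small-molecule pool
#'   (default `n_proteins + 1`; at least 2).
#' @return List with `records`, `hierarchy` and `truth` (`genes`,
#'   `proteoforms`, `n_isolated_no_sm`, `n_components_global`,
#'   `n_components_reaction_unique`).
#' @export
plant_thiamin_motif <- function(n_proteins = 3L,
                                n_small_molecules = n_proteins + 1L) {
  n_proteins <- as.integer(n_proteins)
  n_small_molecules <- as.integer(n_small_molecules)
  stopifnot(n_proteins >= 1L, n_small_molecules >= 2L)
  pw <- "PW_THI"
  prot <- sprintf("THIP%03d", seq_len(n_proteins))
  genes <- sprintf("THIG%03d", seq_len(n_proteins))
  sm <- sprintf("CHEBI:THI%03d", seq_len(n_small_molecules))
  rid <- sprintf("RX_THI%03d", seq_len(n_proteins))
  rows <- lapply(seq_len(n_proteins), function(i) {
    partner <- sm[2L + (i - 1L) %% (n_small_molecules - 1L)]
    data.frame(
      pathway_id = pw, reaction_id = rid[i],
      role = c("INPUT", "OUTPUT", "INPUT", "OUTPUT"),
      entity_class = c("ACCESSIONED", "ACCESSIONED",
                       "SMALL_MOLECULE", "SMALL_MOLECULE"),
      accession = c(prot[i], prot[i], sm[1], partner),
      gene_name = c(genes[i], genes[i], "", ""),
      isoform = "", ptms = "", stringsAsFactors = FALSE)
  })
  records <- validate_participants(do.call(rbind, rows))
  hierarchy <- pathway_hierarchy(data.frame(parent_id = pw, child_id = rid,
                                            child_kind = "REACTION",
                                            stringsAsFactors = FALSE))
  truth <- list(genes = genes,
                proteoforms = proteoform_key(prot),
                n_isolated_no_sm = n_proteins,
                n_components_global = 1L,
                n_components_reaction_unique = n_proteins)
  list(records = records, hierarchy = hierarchy, truth = truth)
}

# m proteoform families, each with two members in disjoint reactions; the
# partner proteins are single-member families
plant_family_motif <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  pw <- "PW_FAM"
  rows <- lapply(seq_len(m), function(j) {
    famp <- sprintf("FAMP%03d", j)
    famg <- sprintf("FAMG%03d", j)
    do.call(rbind, lapply(1:2, function(v) {
      data.frame(
        pathway_id = pw, reaction_id = sprintf("RX_FAM%03d_%d", j, v),
        role = c("INPUT", "OUTPUT"),
        entity_class = "ACCESSIONED",
        accession = c(famp, sprintf("FAMX%03d_%d", j, v)),
        gene_name = c(famg, sprintf("FXG%03d_%d", j, v)),
        isoform = c(as.character(v), ""),
        ptms = "", stringsAsFactors = FALSE)
    }))
  })
  records <- validate_participants(do.call(rbind, rows))
  rid <- unique(records$reaction_id)
  hierarchy <- pathway_hierarchy(data.frame(parent_id = pw, child_id = rid,
                                            child_kind = "REACTION",
                                            stringsAsFactors = FALSE))
  list(records = records, hierarchy = hierarchy,
       truth = list(accessions = sprintf("FAMP%03d", seq_len(m))))
}

# star motif: one hub protein co-participating with k leaf proteins in k
# reactions; the hub is an articulation point in every variant
plant_articulation_motif <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  pw <- "PW_HUB"
  rows <- lapply(seq_len(k), function(i) {
    data.frame(
      pathway_id = pw, reaction_id = sprintf("RX_HUB%03d", i),
      role = c("CATALYST", "INPUT"),
      entity_class = "ACCESSIONED",
      accession = c("HUBP000", sprintf("HUBL%03d", i)),
      gene_name = c("HUBG000", sprintf("HLG%03d", i)),
      isoform = "", ptms = "", stringsAsFactors = FALSE)
  })
  records <- validate_participants(do.call(rbind, rows))
  rid <- unique(records$reaction_id)
  hierarchy <- pathway_hierarchy(data.frame(parent_id = pw, child_id = rid,
                                            child_kind = "REACTION",
                                            stringsAsFactors = FALSE))
  list(records = records, hierarchy = hierarchy,
       truth = list(hub = "HUBG000",
                    leaves = sprintf("HLG%03d", seq_len(k))))
}
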