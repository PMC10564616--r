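# Fixtures built in code: micro-scenarios from the domain and small random
# participant tables.

rec_row <- function(pathway = "PW1", reaction = "R1", role = "INPUT",
                    class = "ACCESSIONED", accession = "P00001",
                    gene = "", isoform = "", ptms = "") {
  data.frame(pathway_id = pathway, reaction_id = reaction, role = role,
             entity_class = class, accession = accession, gene_name = gene,
             isoform = isoform, ptms = ptms, stringsAsFactors = FALSE)
}

# one hydroxylation-style reaction: three unmodified-to-modified proteoform
# states of a single collagen gene as inputs, three more as outputs
collagen_records <- function() {
  ptms_in <- c("", "00037:10", "00037:10,00037:20")
  ptms_out <- c("00038:5", "00037:10,00038:5", "00037:10,00037:20,00038:5")
  rbind(
    do.call(rbind, lapply(ptms_in, function(p)
      rec_row(role = "INPUT", accession = "P12345", gene = "COL7A1", ptms = p))),
    do.call(rbind, lapply(ptms_out, function(p)
      rec_row(role = "OUTPUT", accession = "P12345", gene = "COL7A1", ptms = p))))
}

# two reactions that share only ATP
atp_records <- function() {
  rbind(rec_row(reaction = "R1", accession = "P1", gene = "G1"),
        rec_row(reaction = "R1", class = "SMALL_MOLECULE",
                accession = "CHEBI:30616"),
        rec_row(reaction = "R2", accession = "P2", gene = "G2"),
        rec_row(reaction = "R2", class = "SMALL_MOLECULE",
                accession = "CHEBI:30616"))
}

small_synth <- function(seed, ...) {
  simulate_reactome(synth_config(
    seed = seed, n_pathways = 5L, lambda_reactions = 3, n_proteins = 40L,
    n_small_molecules = 12L, n_ubiquitous = 3L, ...))
}

# hand-built interactome over explicit edges, all-accessioned by default
net_from_edges <- function(edges, nodes = NULL, classes = NULL) {
  keys <- if (is.null(nodes)) sort(unique(c(edges$from, edges$to))) else nodes
  cls <- if (is.null(classes)) "ACCESSIONED" else classes
  interaction_network(data.frame(key = keys, class = cls,
                                 stringsAsFactors = FALSE), edges)
}

path_net <- function(keys) {
  n <- length(keys)
  net_from_edges(data.frame(from = keys[-n], to = keys[-1],
                            stringsAsFactors = FALSE), nodes = keys)
}

er_igraph <- function(n, m, seed) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("V%05d", seq_len(n))
  g
}
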