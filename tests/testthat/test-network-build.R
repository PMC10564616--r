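test_that("node keying follows entity level and small-molecule mode", {
  rec <- rbind(
    rec_row(accession = "P30044", gene = "PRDX5", isoform = "1"),
    rec_row(accession = "P30044", gene = "PRDX5", isoform = "2"),
    rec_row(accession = "Q00001"),  # no gene symbol: accession fallback
    rec_row(class = "SMALL_MOLECULE", accession = "CHEBI:30616"))

  g <- node_keys(rec, build_config("gene", "none"))
  expect_identical(g$key[1:2], c("PRDX5", "PRDX5"))
  expect_identical(g$key[3], "Q00001")
  expect_true(is.na(g$key[4]))  # small molecule skipped under "none"

  p <- node_keys(rec, build_config("proteoform", "global"))
  expect_identical(p$key[1:2], c("P30044-1;", "P30044-2;"))
  expect_false(p$key[1] == p$key[2])  # isoforms are distinct proteoform nodes
  expect_identical(p$key[4], "CHEBI:30616")

  ru <- node_keys(rec, build_config("gene", "reaction_unique"))
  expect_identical(ru$key[4], "CHEBI:30616@R1")
  expect_identical(ru$label[4], "CHEBI:30616")
})

test_that("a multi-proteoform reaction expands at proteoform level and collapses at gene level", {
  rec <- collagen_records()
  pn <- build_network(rec, build_config("proteoform", "none"))
  expect_identical(nrow(pn$nodes), 6L)
  expect_identical(nrow(pn$edges), 15L)  # C(6,2): all co-participants linked
  expect_false(any(pn$nodes$self_loop))

  gn <- build_network(rec, build_config("gene", "none"))
  expect_identical(nrow(gn$nodes), 1L)
  expect_identical(nrow(gn$edges), 0L)
  expect_true(gn$nodes$self_loop)          # the gene interacts with itself
  expect_identical(isolated_nodes(gn), "COL7A1")
})

test_that("global small molecules merge components; reaction-unique ones do not", {
  rec <- atp_records()
  glob <- build_network(rec, build_config("gene", "global"))
  ru <- build_network(rec, build_config("gene", "reaction_unique"))
  expect_identical(component_summary(glob)$n_components, 1L)
  expect_identical(component_summary(ru)$n_components, 2L)
  expect_setequal(ru$nodes$key,
                  c("G1", "G2", "CHEBI:30616@R1", "CHEBI:30616@R2"))
})

test_that("reaction-unique small molecules raise a protein's degree by its reaction count", {
  k <- 5L
  rec <- do.call(rbind, lapply(seq_len(k), function(i) {
    rbind(rec_row(reaction = paste0("R", i), accession = "P1", gene = "G1"),
          rec_row(reaction = paste0("R", i), class = "SMALL_MOLECULE",
                  accession = "CHEBI:30616"))
  }))
  deg_of <- function(net, key) {
    sum(net$edges$from == key) + sum(net$edges$to == key)
  }
  none <- build_network(rec, build_config("gene", "none"))
  glob <- build_network(rec, build_config("gene", "global"))
  ru <- build_network(rec, build_config("gene", "reaction_unique"))
  expect_identical(deg_of(none, "G1"), 0L)
  expect_identical(deg_of(glob, "G1"), 1L)
  expect_identical(deg_of(ru, "G1"), k)
})

test_that("per-reaction edge counts equal C(n',2) over distinct node keys", {
  set.seed(14)
  for (i in 1:10) {
    d <- small_synth(100 + i)
    cfg <- build_config(sample(c("gene", "proteoform"), 1),
                        sample(c("none", "global", "reaction_unique"), 1))
    for (r in sample(unique(d$records$reaction_id), 5)) {
      sub <- d$records[d$records$reaction_id == r, ]
      net <- build_network(sub, cfg)
      nk <- node_keys(sub, cfg)
      nprime <- length(unique(nk$key[!is.na(nk$key)]))
      expect_identical(nrow(net$edges), as.integer(choose(nprime, 2)))
    }
  }
})

test_that("quotienting the proteoform network reproduces the gene network", {
  # the single-gene micro-example: one self-looped node, no edges
  rec <- collagen_records()
  q <- quotient_to_genes(build_network(rec, build_config("proteoform", "none")),
                         proteoform_gene_map(rec))
  gn <- build_network(rec, build_config("gene", "none"))
  expect_identical(q$nodes, gn$nodes)
  expect_identical(q$edges, gn$edges)

  # injective mapping leaves the graph isomorphic (identical up to relabeling)
  rec2 <- rbind(rec_row(accession = "A", gene = "GA"),
                rec_row(accession = "B", gene = "GB", role = "OUTPUT"))
  q2 <- quotient_to_genes(build_network(rec2, build_config("proteoform", "none")),
                          proteoform_gene_map(rec2))
  expect_identical(nrow(q2$edges), 1L)
  expect_false(any(q2$nodes$self_loop))

  # property: on random synthetic data, for every sm_mode
  for (seed in 1:5) {
    d <- small_synth(200 + seed)
    for (sm in c("none", "global", "reaction_unique")) {
      pnet <- build_network(d$records, build_config("proteoform", sm))
      gnet <- build_network(d$records, build_config("gene", sm))
      q <- quotient_to_genes(pnet, proteoform_gene_map(d$records))
      expect_identical(q$nodes, gnet$nodes)
      expect_identical(q$edges, gnet$edges)
      expect_identical(q$provenance, gnet$provenance)
    }
  }

  # unmapped accessioned node is an error
  pnet <- build_network(rec2, build_config("proteoform", "none"))
  expect_error(quotient_to_genes(pnet, c("A;" = "GA")), "cover")
})

test_that("variant inequalities hold: node counts and accessioned degrees", {
  for (seed in 1:5) {
    d <- small_synth(300 + seed)
    nets <- build_all_variants(d$records)
    # gene-level nodes never exceed proteoform-level nodes
    for (sm in c("none", "global", "reaction_unique")) {
      expect_lte(nrow(nets[[paste0("gene_", sm)]]$nodes),
                 nrow(nets[[paste0("proteoform_", sm)]]$nodes))
    }
    # accessioned degree: reaction_unique >= global >= none
    for (lv in c("gene", "proteoform")) {
      deg <- function(net) {
        g <- as_igraph(net)
        d <- igraph::degree(g)
        acc <- net$nodes$key[net$nodes$class == "ACCESSIONED"]
        d[acc]
      }
      dn <- deg(nets[[paste0(lv, "_none")]])
      dg <- deg(nets[[paste0(lv, "_global")]])
      dr <- deg(nets[[paste0(lv, "_reaction_unique")]])
      expect_true(all(dg[names(dn)] >= dn))
      expect_true(all(dr[names(dn)] >= dg[names(dn)]))
    }
  }
})

test_that("interaction_network enforces simple-graph invariants", {
  expect_error(interaction_network(c("A", "B"),
                                   data.frame(from = "A", to = "A")),
               "self-pairs")
  expect_error(interaction_network(c("A", "B"),
                                   data.frame(from = c("A", "B"),
                                              to = c("B", "A"))),
               "duplicate")
  expect_error(interaction_network("A", data.frame(from = "A", to = "Z")),
               "endpoint")
  # empty network is legal
  empty <- build_network(rec_row()[0, ], build_config())
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("network exports are deterministic and igraph sees the simple graph", {
  d <- small_synth(17)
  net <- build_network(d$records, build_config("gene", "global"))
  g <- as_igraph(net)
  expect_identical(as.integer(igraph::vcount(g)), nrow(net$nodes))
  expect_identical(as.integer(igraph::ecount(g)), nrow(net$edges))
  expect_false(igraph::any_loop(g))

  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".graphml")
  write_network_graphml(net, f1)
  write_network_graphml(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  e1 <- tempfile()
  write_network_edgelist(net, e1)
  el <- utils::read.delim(e1, stringsAsFactors = FALSE)
  expect_identical(nrow(el), nrow(net$edges))
})
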