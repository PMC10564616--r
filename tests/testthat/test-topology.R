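test_that("components, LCC and isolated nodes follow the self-loop-free definition", {
  # path A-B-C plus lone node D
  net <- net_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")),
                        nodes = c("A", "B", "C", "D"))
  cs <- component_summary(net)
  expect_identical(cs$n_components, 2L)
  expect_identical(cs$lcc_size, 3L)
  expect_identical(cs$lcc_nodes, c("A", "B", "C"))
  expect_identical(cs$isolated, "D")

  # a node connected only to itself is isolated
  lonely <- interaction_network(
    data.frame(key = "X", class = "ACCESSIONED", self_loop = TRUE))
  expect_identical(component_summary(lonely)$isolated, "X")
  expect_identical(isolated_nodes(lonely), "X")

  # LCC tie-break: lexicographically smallest member wins
  tie <- net_from_edges(data.frame(from = c("B", "A"), to = c("Z", "C")))
  expect_identical(component_summary(tie)$lcc_nodes, c("A", "C"))

  # empty network
  empty <- build_network(rec_row()[0, ], build_config())
  expect_identical(component_summary(empty)$n_components, 0L)
})

test_that("component counts match the union-find oracle on random graphs", {
  set.seed(31)
  for (i in 1:30) {
    net <- random_net(sample(2:80, 1), sample(0:120, 1))
    expect_identical(component_summary(net)$n_components,
                     oracle_components(net$nodes$key, net$edges))
  }
})

test_that("articulation points and bridges match hand-worked micro-cases", {
  path <- path_net(c("A", "B", "C"))
  ab <- articulation_and_bridges(path)
  expect_identical(ab$articulation, "B")
  expect_identical(ab$bridges, data.frame(from = c("A", "B"), to = c("B", "C"),
                                          stringsAsFactors = FALSE))

  cyc <- net_from_edges(data.frame(from = c("A", "B", "A"),
                                   to = c("B", "C", "C")))
  ab2 <- articulation_and_bridges(cyc)
  expect_length(ab2$articulation, 0L)
  expect_identical(nrow(ab2$bridges), 0L)
})

test_that("articulation and bridge sets equal the remove-and-recount oracle", {
  set.seed(77)
  for (i in 1:40) {
    net <- random_net(sample(3:60, 1), sample(2:90, 1))
    ab <- articulation_and_bridges(net)
    expect_identical(ab$articulation,
                     oracle_articulation(net$nodes$key, net$edges))
    expect_identical(ab$bridges, oracle_bridges(net$nodes$key, net$edges))
  }
})

test_that("removing a bridge splits exactly one component", {
  set.seed(5)
  for (i in 1:5) {
    net <- random_net(30, 35)
    ab <- articulation_and_bridges(net)
    c0 <- component_summary(net)$n_components
    if (!nrow(ab$bridges)) next
    for (b in seq_len(min(3L, nrow(ab$bridges)))) {
      keep <- !(net$edges$from == ab$bridges$from[b] &
                  net$edges$to == ab$bridges$to[b])
      cut <- interaction_network(net$nodes, net$edges[keep, ],
                                 net$provenance[keep])
      expect_identical(component_summary(cut)$n_components, c0 + 1L)
    }
  }
})

test_that("class shares are exact fractions of articulation points and bridges", {
  # star with a small-molecule center and three protein leaves
  star <- interaction_network(
    data.frame(key = c("SM", "P1", "P2", "P3"),
               class = c("SMALL_MOLECULE", rep("ACCESSIONED", 3))),
    data.frame(from = rep("SM", 3), to = c("P1", "P2", "P3")))
  ab <- articulation_and_bridges(star)
  sh <- class_shares(ab, star)
  expect_identical(unname(sh$articulation_share["SMALL_MOLECULE"]), 1)
  expect_identical(unname(sh$articulation_share["ACCESSIONED"]), 0)
  expect_identical(unname(sh$pct_class_articulation["SMALL_MOLECULE"]), 100)
  expect_identical(unname(sh$bridge_share["accessioned-sm"]), 1)
  expect_identical(sh$pct_bridges_touching_sm, 100)

  # all-protein path: bridges are 100% accessioned-accessioned
  sh2 <- class_shares(articulation_and_bridges(path_net(c("A", "B", "C"))),
                      path_net(c("A", "B", "C")))
  expect_identical(unname(sh2$bridge_share["accessioned-accessioned"]), 1)
  expect_identical(sh2$pct_bridges_touching_sm, 0)

  # shares sum to one whenever the sets are non-empty; zero otherwise
  set.seed(8)
  for (i in 1:10) {
    net <- random_net(sample(5:50, 1), sample(4:60, 1))
    ab <- articulation_and_bridges(net)
    sh <- class_shares(ab, net)
    if (length(ab$articulation)) {
      expect_equal(sum(sh$articulation_share), 1)
    } else {
      expect_identical(sum(sh$articulation_share), 0)
    }
    if (nrow(ab$bridges)) expect_equal(sum(sh$bridge_share), 1)
  }
})

test_that("topology_summary collects counts consistently", {
  d <- small_synth(23)
  net <- build_network(d$records, build_config("proteoform", "global"))
  ts <- topology_summary(net)
  expect_identical(ts$n_nodes, nrow(net$nodes))
  expect_identical(ts$n_nodes_accessioned + ts$n_nodes_sm, ts$n_nodes)
  expect_identical(sum(ts$edge_pattern), ts$n_edges)
  expect_identical(ts$n_isolated, length(isolated_nodes(net)))
  expect_true(ts$lcc_rel_size > 0 && ts$lcc_rel_size <= 1)
  ann <- node_annotation_table(net)
  expect_identical(nrow(ann), nrow(net$nodes))
  expect_identical(sum(ann$is_articulation), length(ts$articulation))
  expect_identical(sum(ann$degree) / 2, as.numeric(ts$n_edges))
})

test_that("proteoform families with reaction-specific members are detected", {
  # two isoforms in separate reactions (mitochondrial vs cytosolic pattern)
  rec <- rbind(
    rec_row(reaction = "R_mito", accession = "P30044", gene = "PRDX5",
            isoform = "1"),
    rec_row(reaction = "R_mito", accession = "Q1", gene = "TXN2",
            role = "OUTPUT"),
    rec_row(reaction = "R_cyto", accession = "P30044", gene = "PRDX5",
            isoform = "2"),
    rec_row(reaction = "R_cyto", accession = "Q2", gene = "TXN",
            role = "OUTPUT"))
  expect_identical(family_specificity(rec), "P30044")

  # family whose members always co-occur is excluded
  co <- rbind(
    rec_row(reaction = "R1", accession = "P1", isoform = "1"),
    rec_row(reaction = "R1", accession = "P1", isoform = "2"),
    rec_row(reaction = "R2", accession = "P1", isoform = "1"),
    rec_row(reaction = "R2", accession = "P1", isoform = "2"))
  expect_length(family_specificity(co), 0L)

  # single-member family is excluded
  expect_length(family_specificity(rec_row()), 0L)
})

test_that("small-molecule-dependent nodes are exactly the rescued isolates", {
  thi <- plant_thiamin_motif(3)
  none <- build_network(thi$records, build_config("gene", "none"))
  glob <- build_network(thi$records, build_config("gene", "global"))
  expect_identical(sm_dependency(none, glob), sort(thi$truth$genes))

  # a protein-protein edge disqualifies the pair
  rec <- rbind(atp_records(),
               rec_row(reaction = "R1", accession = "P9", gene = "G9"))
  none2 <- build_network(rec, build_config("gene", "none"))
  glob2 <- build_network(rec, build_config("gene", "global"))
  expect_identical(sm_dependency(none2, glob2), "G2")  # only R2's protein

  # mismatched accessioned node sets are rejected
  expect_error(sm_dependency(none, glob2), "node sets differ")
})
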