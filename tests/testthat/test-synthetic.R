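test_that("generation is deterministic and respects pool sizes", {
  cfg <- synth_config(seed = 5, n_pathways = 5, lambda_reactions = 3,
                      n_proteins = 30, n_small_molecules = 8)
  a <- simulate_reactome(cfg)
  b <- simulate_reactome(cfg)
  t1 <- tempfile(); t2 <- tempfile()
  write_participant_table(a$records, t1)
  write_participant_table(b$records, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(a$truth, b$truth)

  # no small molecules at all
  dry <- simulate_reactome(synth_config(seed = 2, n_pathways = 3,
                                        n_proteins = 20,
                                        n_small_molecules = 0,
                                        n_ubiquitous = 0))
  expect_false(any(dry$records$entity_class == "SMALL_MOLECULE"))

  # infeasible configs are rejected up front
  expect_error(synth_config(n_pathways = 0), "pathway")
  expect_error(synth_config(n_ubiquitous = 10, n_small_molecules = 5),
               "n_ubiquitous")
  expect_error(synth_config(p_complex = 1.5), "probabilities")
})

test_that("ground-truth node counts match the built networks for every variant", {
  d <- small_synth(81)
  nets <- build_all_variants(d$records)
  tv <- d$truth$nodes_by_variant
  for (j in seq_len(nrow(tv))) {
    id <- paste(tv$entity_level[j], tv$sm_mode[j], sep = "_")
    expect_identical(nrow(nets[[id]]$nodes), as.integer(tv$nodes[j]))
  }
  expect_identical(sum(nets$proteoform_none$nodes$class == "ACCESSIONED"),
                   as.integer(d$truth$n_proteoform_nodes))
})

test_that("proteoform richness tracks the configured mean at scale", {
  d <- simulate_reactome(synth_config(seed = 9, n_pathways = 60,
                                      lambda_reactions = 9,
                                      n_proteins = 500,
                                      mean_proteoforms = 1.3,
                                      n_small_molecules = 50))
  expect_lt(abs(d$truth$mean_proteoforms_per_protein - 1.3), 0.1)
  # and the pipeline sees the same richness: distinct proteoform nodes per
  # protein accession in the built network
  net <- build_network(d$records, build_config("proteoform", "none"))
  acc <- sub(";.*", "", sub("-.*", "", net$nodes$key))
  expect_lt(abs(mean(table(acc)) - 1.3), 0.1)
})

test_that("the thiamin motif behaves as planted under all three SM modes", {
  thi <- plant_thiamin_motif(3)
  none <- build_network(thi$records, build_config("gene", "none"))
  glob <- build_network(thi$records, build_config("gene", "global"))
  ru <- build_network(thi$records, build_config("gene", "reaction_unique"))
  # only isolated self-interacting nodes without small molecules
  expect_identical(length(isolated_nodes(none)), thi$truth$n_isolated_no_sm)
  expect_identical(nrow(none$edges), 0L)
  expect_true(all(none$nodes$self_loop))
  # proteoform level stays disconnected too
  pnone <- build_network(thi$records, build_config("proteoform", "none"))
  expect_identical(nrow(pnone$edges), 0L)
  # global small molecules connect everything; reaction-unique per reaction
  expect_identical(component_summary(glob)$n_components,
                   thi$truth$n_components_global)
  expect_identical(component_summary(ru)$n_components,
                   thi$truth$n_components_reaction_unique)
})

test_that("planted structures are recovered exactly from a full generation", {
  d <- simulate_reactome(synth_config(
    seed = 13, n_pathways = 8, lambda_reactions = 4, n_proteins = 60,
    n_small_molecules = 15, plant_sm_dependent = 4,
    plant_family_specific = 3, plant_articulation = 4))
  nets <- build_all_variants(d$records)

  expect_identical(sm_dependency(nets$gene_none, nets$gene_global),
                   d$truth$sm_dependent_genes)
  expect_true(all(d$truth$planted$sm_dependent_genes %in%
                    d$truth$sm_dependent_genes))
  expect_identical(sm_dependency(nets$proteoform_none, nets$proteoform_global),
                   d$truth$sm_dependent_proteoforms)
  expect_identical(isolated_nodes(nets$gene_none),
                   d$truth$isolated_gene_none)
  expect_identical(isolated_nodes(nets$proteoform_none),
                   d$truth$isolated_proteoform_none)
  expect_identical(family_specificity(d$records), d$truth$family_specific)
  expect_true(all(d$truth$planted$family_specific %in%
                    d$truth$family_specific))
  ab <- articulation_and_bridges(nets$gene_none)
  expect_true(d$truth$planted$articulation_hub %in% ab$articulation)
  expect_false(any(d$truth$planted$articulation_leaves %in% ab$articulation))
})

test_that("ubiquitous small molecules are pervasive and generated tables are valid", {
  d <- small_synth(91)
  expect_silent(validate_participants(d$records))
  expect_true(all(d$records$reaction_id %in%
                    hierarchy_reactions(d$hierarchy)))
  # the most ubiquitous small molecule joins a large share of reactions
  sm <- d$records[d$records$entity_class == "SMALL_MOLECULE", ]
  n_rx <- length(unique(d$records$reaction_id))
  per_sm <- tapply(sm$reaction_id, sm$accession,
                   function(x) length(unique(x)))
  expect_gt(max(per_sm) / n_rx, 0.2)
})
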