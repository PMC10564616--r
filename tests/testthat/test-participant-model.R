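test_that("proteoform strings are canonical and round-trip", {
  # isoform without PTMs, bare accession, forced canonical PTM sort
  expect_identical(format_proteoform(proteoform("P30044", "2")), "P30044-2;")
  expect_identical(format_proteoform(proteoform("Q99999")), "Q99999;")
  expect_identical(format_proteoform(proteoform("Q99999", ptms = "00046:35,00046:12")),
                   "Q99999;00046:12,00046:35")
  # unknown positions render "null" and sort after numbered positions
  expect_identical(canonical_ptms("00046:null,00046:9"), "00046:9,00046:null")
  # multiplicity preserved: repeated identical modifications count twice
  expect_identical(canonical_ptms("01148:null,01148:null"), "01148:null,01148:null")

  cases <- c("P30044-2;", "Q99999;", "Q99999;00046:12,00046:35",
             "P1;00046:null,01148:2,01148:null")
  for (s in cases) {
    expect_identical(format_proteoform(parse_proteoform(s)), s)
  }
})

test_that("proteoform identity is invariant under PTM input order", {
  set.seed(42)
  mods <- c("00046", "00047", "01148")
  for (i in 1:25) {
    k <- sample(2:6, 1)
    toks <- paste0(sample(mods, k, replace = TRUE), ":",
                   ifelse(runif(k) < 0.2, "null", sample(500, k, replace = TRUE)))
    a <- proteoform("P1", ptms = paste(toks, collapse = ","))
    b <- proteoform("P1", ptms = paste(sample(toks), collapse = ","))
    expect_identical(a, b)
    expect_identical(format_proteoform(a), format_proteoform(b))
  }
  # strict position identity: UNKNOWN matches only UNKNOWN
  expect_false(identical(proteoform("P1", ptms = "00046:null"),
                         proteoform("P1", ptms = "00046:12")))
  # missing isoform is distinct from an explicit canonical isoform
  expect_false(identical(format_proteoform(proteoform("P30044")),
                         format_proteoform(proteoform("P30044", "1"))))
})

test_that("entity trees flatten to included leaves, dropping exclusions", {
  a <- entity_protein("A", "GA")
  b <- entity_protein("B", "GB")
  cc <- entity_protein("C", "GC")
  atp <- entity_small_molecule("CHEBI:30616")

  flat <- flatten_entity_tree(entity_complex(a, entity_set(b, cc), atp))
  expect_identical(flat$accession, c("A", "B", "C", "CHEBI:30616"))
  expect_identical(flat$entity_class,
                   c(rep("ACCESSIONED", 3), "SMALL_MOLECULE"))

  # identity case
  expect_identical(flatten_entity_tree(a)$accession, "A")

  # excluded leaves dropped, duplicates preserved
  flat2 <- flatten_entity_tree(
    entity_complex(a, entity_excluded("drug"), entity_complex(a)))
  expect_identical(flat2$accession, c("A", "A"))
  expect_identical(attr(flat2, "excluded"), "drug")

  # malformed trees are rejected
  bad <- entity_protein("A")
  bad$children <- list(entity_protein("B"))
  expect_error(flatten_entity_tree(bad), "leaf")
  expect_error(entity_complex(), "at least one child")
})

test_that("flattened leaf count matches an independent tree walk", {
  set.seed(7)
  count_leaves <- function(node) {
    if (node$kind %in% c("COMPLEX", "ENTITY_SET")) {
      sum(vapply(node$children, count_leaves, numeric(1)))
    } else if (node$kind == "EXCLUDED") 0 else 1
  }
  rand_tree <- function(depth) {
    r <- runif(1)
    if (depth >= 5 || r < 0.5) {
      if (r < 0.1) entity_excluded(sample(c("drug", "polymer", "other-entity"), 1))
      else if (r < 0.3) entity_small_molecule(sprintf("CHEBI:%d", sample(99, 1)))
      else entity_protein(sprintf("P%05d", sample(999, 1)))
    } else {
      kids <- replicate(sample(1:4, 1), rand_tree(depth + 1), simplify = FALSE)
      if (r < 0.75) do.call(entity_complex, kids) else do.call(entity_set, kids)
    }
  }
  for (i in 1:40) {
    tr <- rand_tree(1)
    expect_identical(nrow(flatten_entity_tree(tr)), as.integer(count_leaves(tr)))
  }
})

test_that("participant table validation enforces the record invariants", {
  good <- rec_row()
  expect_silent(validate_participants(good))
  # small molecules carry no proteoform annotation
  expect_error(validate_participants(
    rec_row(class = "SMALL_MOLECULE", accession = "CHEBI:1", ptms = "00046:1")),
    "row 1.*small molecules", ignore.case = TRUE)
  expect_error(validate_participants(rbind(good, rec_row(role = "SUBSTRATE"))),
               "row 2.*unknown role")
  expect_error(validate_participants(rec_row(reaction = "")), "reaction_id")
  expect_error(validate_participants(rec_row(accession = "")), "accession")
  expect_error(validate_participants(rec_row(ptms = "garbage")), "PTM")
})

test_that("participant table writing is canonical and round-trips", {
  d <- small_synth(11)
  tf <- tempfile()
  write_participant_table(d$records, tf)
  back <- read_participant_table(tf)
  o <- order(d$records$pathway_id, d$records$reaction_id, d$records$role,
             d$records$entity_class, d$records$accession, d$records$isoform,
             d$records$ptms, method = "radix")
  sorted <- d$records[o, ]
  rownames(sorted) <- NULL
  expect_identical(back, sorted)

  # byte-stable: same records twice, and shuffled input equals sorted input
  tf2 <- tempfile()
  write_participant_table(d$records, tf2)
  expect_identical(readLines(tf), readLines(tf2))
  set.seed(1)
  shuffled <- d$records[sample(nrow(d$records)), ]
  tf3 <- tempfile()
  write_participant_table(shuffled, tf3)
  expect_identical(readLines(tf), readLines(tf3))

  # empty table -> header-only file
  tf4 <- tempfile()
  write_participant_table(d$records[0, ], tf4)
  expect_length(readLines(tf4), 1L)
})

test_that("pathway hierarchy validates kinds, rejects cycles, round-trips", {
  h <- pathway_hierarchy(data.frame(
    parent_id = c("P1", "P1", "P2"), child_id = c("P2", "R1", "R2"),
    child_kind = c("PATHWAY", "REACTION", "REACTION")))
  expect_setequal(hierarchy_pathways(h), c("P1", "P2"))
  expect_setequal(hierarchy_reactions(h), c("R1", "R2"))

  expect_error(pathway_hierarchy(data.frame(
    parent_id = c("P1", "P2"), child_id = c("P2", "P1"),
    child_kind = "PATHWAY")), "cycle")
  expect_error(pathway_hierarchy(data.frame(
    parent_id = "P1", child_id = "X", child_kind = "THING")), "child_kind")

  tf <- tempfile()
  write_pathway_hierarchy(h, tf)
  expect_identical(as.data.frame(read_pathway_hierarchy(tf)),
                   as.data.frame(h))
})
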