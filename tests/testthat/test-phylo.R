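make_gene_tree <- function(nw) {
  t <- parse_newick(nw)
  assign_species(t, function(n) sub("_.*", "", n))
  t
}

test_that("assign_species applies the naming rule and get_species collects", {
  t <- parse_newick("((HSA_1,MMU_1),DME_1);")
  assign_species(t)  # default rule: first three characters
  expect_identical(get_feature(leaves(t)[[1]], "species"), "HSA")
  expect_identical(get_species(t), c("DME", "HSA", "MMU"))
  t2 <- make_gene_tree("((human_a,mouse_a),fly_b);")
  expect_identical(get_species(t2), c("fly", "human", "mouse"))
  expect_identical(get_species(t2$children[[1]]), c("human", "mouse"))
})

test_that("link_alignment attaches sequences and validates the FASTA", {
  t <- parse_newick("((A,B),C);")
  fa <- ">A\nMKV-A\n>B\nMKV-B\n>C\nMKVCC\n"
  link_alignment(t, fa)
  expect_identical(get_feature(search_nodes(t, name = "B")[[1]], "sequence"),
                   "MKV-B")
  # all sequences must have equal length
  expect_error(link_alignment(parse_newick("(A,B);"), ">A\nMK\n>B\nMKVV\n"),
               "length")
  # strict mode requires every leaf to be covered
  expect_error(link_alignment(parse_newick("(A,B);"), ">A\nMK\n"), "B")
  expect_warning(link_alignment(parse_newick("(A,B);"), ">A\nMK\n",
                                strict = FALSE), "B")
  # identical sequences: pairwise identity is 100%
  t3 <- parse_newick("(A,B);")
  link_alignment(t3, ">A\nMKVR\n>B\nMKVR\n")
  s <- vapply(leaves(t3), get_feature, "", key = "sequence")
  ident <- mean(strsplit(s[1], "")[[1]] == strsplit(s[2], "")[[1]])
  expect_equal(ident, 1)
})

test_that("species-overlap labels duplications exactly when species repeat", {
  t <- make_gene_tree("(((HSA_1,MMU_1),(HSA_2,MMU_2)),DME_1);")
  ev <- species_overlap_events(t)
  types <- vapply(ev, function(e) e$etype, character(1L))
  # two species-clean cherries + their duplication join + the root speciation
  expect_identical(sort(types),
                   c("duplication", "speciation", "speciation", "speciation"))
  dup <- ev[[which(types == "duplication")]]
  expect_equal(dup$overlap_score, 1)
  expect_setequal(dup$in_group, c("HSA_1", "MMU_1"))
  expect_setequal(dup$out_group, c("HSA_2", "MMU_2"))
  # feature annotations are stored on the nodes
  expect_identical(get_feature(dup$node, "event"), "duplication")
  # a higher threshold can veto a partial overlap
  t2 <- make_gene_tree("((HSA_1,MMU_1),(HSA_2,PTR_1));")
  expect_identical(species_overlap_events(t2)[[3]]$etype, "duplication")
  ev2 <- species_overlap_events(t2, threshold = 0.5)
  expect_identical(ev2[[3]]$etype, "speciation")  # overlap 1/3 <= 0.5
  expect_error(species_overlap_events(t2, threshold = 1), "threshold")
  expect_error(species_overlap_events(parse_newick("(A,B);")), "species")
})

test_that("reconcile handles congruent trees with zero events", {
  g <- make_gene_tree("((HSA_1,MMU_1),DME_1);")
  s <- parse_newick("((HSA,MMU),DME);")
  r <- reconcile(g, s)
  expect_s3_class(r, "reconciliation")
  expect_equal(r$n_duplications, 0L)
  expect_equal(r$n_losses, 0L)
  types <- vapply(r$events, function(e) e$etype, character(1L))
  expect_true(all(types == "speciation"))
  # mapping sends the gene root to the species root
  root_map <- r$mapping[[length(r$mapping)]]
  expect_identical(root_map$species_node$id, s$id)
})

test_that("reconcile infers the classic one-duplication-one-loss case", {
  g <- make_gene_tree("(HSA_a,(HSA_b,MMU_b));")
  s <- parse_newick("(HSA,MMU);")
  r <- reconcile(g, s)
  expect_equal(r$n_duplications, 1L)
  expect_equal(r$n_losses, 1L)
  ghosts <- search_nodes(r$reconciled_tree, evoltype = "L")
  expect_length(ghosts, 1L)
  expect_identical(get_feature(ghosts[[1]], "species"), "MMU")
  # removing the losses restores the input topology
  stripped <- remove_loss_leaves(r$reconciled_tree)
  expect_identical(write_newick(stripped, "TOPOLOGY_ONLY"),
                   write_newick(g, "TOPOLOGY_ONLY"))
  # non-binary input is rejected
  g3 <- make_gene_tree("(HSA_a,HSA_b,MMU_b);")
  expect_error(reconcile(g3, s), "binary")
  # unknown species are rejected
  g4 <- make_gene_tree("(HSA_a,PTR_b);")
  expect_error(reconcile(g4, s), "PTR")
})

test_that("reconciliation and species overlap agree on simulated trees", {
  s <- parse_newick("(((HSA,PTR),MMU),(DME,CEL));")
  for (seed in c(3, 17, 42)) {
    g <- simulate_gene_tree(s, n_duplications = 3, seed = seed)
    truth <- sort(vapply(search_nodes(g, dup_truth = TRUE),
                         function(x) x$id, integer(1L)))
    ev_o <- species_overlap_events(g)
    dup_o <- sort(vapply(
      Filter(function(e) e$etype == "duplication", ev_o),
      function(e) e$node$id, integer(1L)))
    expect_identical(dup_o, truth)
    r <- reconcile(g, s)
    expect_equal(r$n_duplications, length(truth))
    expect_equal(r$n_losses, 0L)
  }
})

test_that("duplication dating ranks events along the species ladder", {
  s <- parse_newick("(((HSA,PTR),MMU),DME);")
  ladder <- species_ladder(s, "HSA")
  expect_equal(length(ladder), 4L)
  expect_identical(ladder[[1]], "HSA")
  expect_setequal(ladder[[4]], c("HSA", "PTR", "MMU", "DME"))
  # recent duplication (HSA only) vs ancient one (all species)
  g <- make_gene_tree("(((HSA_1,HSA_2),MMU_1),DME_1);")
  species_overlap_events(g)
  recent <- search_nodes(g, event = "duplication")[[1]]
  expect_equal(date_duplication(recent, ladder), 0L)
  g2 <- make_gene_tree("((HSA_1,DME_1),(HSA_2,DME_2));")
  species_overlap_events(g2)
  old <- search_nodes(g2, event = "duplication")[[1]]
  expect_equal(date_duplication(old, ladder), 3L)
  expect_gt(date_duplication(old, ladder), date_duplication(recent, ladder))
  sp <- search_nodes(g, event = "speciation")[[1]]
  expect_error(date_duplication(sp, ladder), "duplication")
})

test_that("check_monophyly distinguishes mono-, para- and polyphyly", {
  t <- make_gene_tree("(((HSA_1,HSA_2),MMU_1),DME_1);")
  expect_identical(check_monophyly(t, "HSA")$verdict, "monophyletic")
  para <- check_monophyly(t, c("HSA", "DME"))
  expect_identical(para$verdict, "paraphyletic")
  expect_identical(vapply(para$intruders, function(x) x$name, ""), "MMU_1")
  # intruders MMU_1 and CEL_1 do not themselves form a clade
  t2 <- make_gene_tree("((HSA_1,MMU_1),(DME_1,CEL_1));")
  expect_identical(check_monophyly(t2, c("HSA", "DME"))$verdict,
                   "polyphyletic")
  expect_error(check_monophyly(t, "XXX"), "no leaf")
  # works on arbitrary attributes, e.g. names
  expect_identical(
    check_monophyly(t, c("HSA_1", "HSA_2"), attribute = "name")$verdict,
    "monophyletic")
})

test_that("ortholog_pairs partitions cross pairs by event type", {
  t <- make_gene_tree("(((HSA_1,MMU_1),(HSA_2,MMU_2)),DME_1);")
  ev <- species_overlap_events(t)
  pr <- ortholog_pairs(ev)
  expect_true(all(pr$leaf1 < pr$leaf2))
  expect_equal(anyDuplicated(paste(pr$leaf1, pr$leaf2)), 0L)
  # every unordered leaf pair appears exactly once
  expect_equal(nrow(pr), choose(5, 2))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  types <- setNames(pr$type, paste(pr$leaf1, pr$leaf2))
  expect_identical(unname(types[key("HSA_1", "MMU_1")]), "ortholog")
  expect_identical(unname(types[key("HSA_1", "HSA_2")]), "paralog")
  expect_identical(unname(types[key("HSA_1", "MMU_2")]), "paralog")
  expect_identical(unname(types[key("HSA_1", "DME_1")]), "ortholog")
  # the HSA_1 orthologs of MMU genes: exactly MMU_1
  orth <- pr[pr$type == "ortholog" &
               (pr$leaf1 == "HSA_1" | pr$leaf2 == "HSA_1"), ]
  partners <- setdiff(c(orth$leaf1, orth$leaf2), "HSA_1")
  expect_setequal(partners, c("MMU_1", "DME_1"))
})

test_that("simulate_gene_tree produces loss-free trees with marked truth", {
  s <- parse_newick("(((HSA,PTR),MMU),(DME,CEL));")
  g0 <- simulate_gene_tree(s, 0, seed = 1)
  expect_identical(write_newick(g0, "TOPOLOGY_ONLY"),
                   gsub("(\\w+)", "\\1_1", write_newick(s, "TOPOLOGY_ONLY")))
  expect_length(search_nodes(g0, dup_truth = TRUE), 0L)
  g3 <- simulate_gene_tree(s, 3, seed = 9)
  # a duplicated subtree may itself contain marked nodes, so >= 3 marks
  n_truth <- length(search_nodes(g3, dup_truth = TRUE))
  expect_gte(n_truth, 3L)
  expect_equal(reconcile(g3, s)$n_duplications, n_truth)
  expect_equal(anyDuplicated(leaf_names(g3)), 0L)
  # deterministic under a fixed seed
  expect_identical(write_newick(simulate_gene_tree(s, 3, seed = 9)),
                   write_newick(g3))
})
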