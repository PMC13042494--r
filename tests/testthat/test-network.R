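test_that("edge weight is the C-score sum and mean_p the mean over found genes", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "L1->R1", ligand = "L1",
                                receptor = "R1"))
  net <- build_ccc_network(tabs, res)
  ab <- net[net$sender == "A" & net$receiver == "B", ]
  # C(L1 in A) = 2 (p 0.01), C(R1 in B) = -0.5 (p 0.2)
  expect_equal(ab$weight, 1.5)
  expect_equal(ab$mean_p, 0.105)
  expect_equal(ab$n_genes_contributing, 2L)
})

test_that("receptor complexes sum over all found subunits", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "L1->R1_R2", ligand = "L1",
                                receptor = "R1_R2"))
  net <- build_ccc_network(tabs, res)
  ba <- net[net$sender == "B" & net$receiver == "A", ]
  # ligand L1 in B = -0.5; receptors R1, R2 in A = 1, 1
  expect_equal(ba$weight, 1.5)
  expect_equal(ba$receptor_genes[[1]], c("R1", "R2"))
  # the mean aggregation averages within each side before summing
  net_m <- build_ccc_network(tabs, res, subunit_agg = "mean")
  expect_equal(net_m[net_m$sender == "B" & net_m$receiver == "A", ]$weight,
               -0.5 + 1)
})

test_that("edges need a found subunit on both sides; require_all tightens it", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(
    pair_name = c("L9->R1", "L2->R9", "L2->R2_R9"),
    ligand = c("L9", "L2", "L2"),
    receptor = c("R1", "R9", "R2_R9")))
  net <- build_ccc_network(tabs, res)
  # L9 absent everywhere and R9 absent everywhere: only the partial complex
  # pair can form edges
  expect_true(all(net$pair == "L2->R2_R9"))
  expect_true(all(net$n_genes_missing == 1L))
  strict <- build_ccc_network(tabs, res, require_all_subunits = TRUE)
  expect_equal(nrow(strict), 0)
})

test_that("self-edges and the mean_p filter are honoured", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "L1->R1", ligand = "L1",
                                receptor = "R1"))
  net_self <- build_ccc_network(tabs, res, include_self_edges = TRUE)
  expect_true(any(net_self$sender == net_self$receiver))
  expect_equal(nrow(net_self), nrow(build_ccc_network(tabs, res)) + 2)
  filt <- build_ccc_network(tabs, res, max_mean_p = 0.11)
  expect_true(all(filt$mean_p <= 0.11))
})

test_that("split_by_sign partitions edges and drops zero weights", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(
    pair_name = c("L1->R2", "L2->R1", "L1->R3"),
    ligand = c("L1", "L2", "L1"),
    receptor = c("R2", "R1", "R3")))
  net <- build_ccc_network(tabs, res)
  parts <- split_by_sign(net)
  expect_true(all(parts$shared$weight > 0))
  expect_true(all(parts$different$weight < 0))
  expect_equal(nrow(parts$shared) + nrow(parts$different) +
                 parts$n_zero_dropped, nrow(net))
})

test_that("degrees use absolute weights and conserve total weight", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "L2->R1", ligand = "L2",
                                receptor = "R1"))
  net <- build_ccc_network(tabs, res)
  ab <- net[net$sender == "A" & net$receiver == "B", ]
  expect_equal(ab$weight, -1)  # C(L2 in A) = -0.5, C(R1 in B) = -0.5
  deg <- ccc_degrees(net)
  expect_equal(deg$out_degree[deg$cell_type == "A"],
               sum(abs(net$weight[net$sender == "A"])))
  expect_equal(sum(deg$out_degree), sum(abs(net$weight)))
  expect_equal(sum(deg$in_degree), sum(abs(net$weight)))
})

test_that("degree tables of the sign split reconstruct the full network", {
  sim <- simulate_celltype_scores(n_cell_types = 3, n_genes = 60, seed = 5)
  scores <- lapply(sim, `[[`, "scores")
  res <- simulate_lr_resource(sim[[1]]$scores$feature, n_pairs = 15,
                              complex_fraction = 0.4, seed = 8)
  net <- build_ccc_network(scores, res)
  expect_gt(nrow(net), 0)
  parts <- split_by_sign(net)
  deg_full <- ccc_degrees(net)
  deg_sum <- ccc_degrees(parts$shared)[-1] + ccc_degrees(parts$different)[-1]
  nonzero <- structure(net[net$weight != 0, , drop = FALSE],
                       class = class(net),
                       cell_types = attr(net, "cell_types"))
  expect_equal(as.data.frame(deg_sum),
               as.data.frame(ccc_degrees(nonzero)[-1]))
  # conservation on the full network
  expect_equal(sum(deg_full$out_degree), sum(abs(net$weight)))
  expect_equal(sum(deg_full$in_degree), sum(abs(net$weight)))
})

test_that("build_ccc_network is invariant to row order of its inputs", {
  sim <- simulate_celltype_scores(n_cell_types = 2, n_genes = 40, seed = 9)
  scores <- lapply(sim, `[[`, "scores")
  res <- simulate_lr_resource(scores[[1]]$feature, n_pairs = 8, seed = 2)
  net1 <- build_ccc_network(scores, res)
  shuffled_scores <- lapply(scores, function(s) {
    idx <- withr::with_seed(1, sample.int(nrow(s)))
    structure(s[idx, ], class = class(s))
  })
  shuffled_res <- lr_resource(
    as.data.frame(res[withr::with_seed(2, sample.int(nrow(res))),
                      c("pair_name", "ligand", "receptor")]))
  net2 <- build_ccc_network(shuffled_scores, shuffled_res)
  expect_equal(as.data.frame(tidy(net1)), as.data.frame(tidy(net2)))
})

test_that("removing an edge lowers the sender's out-degree by its weight", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(
    pair_name = c("L1->R1", "L2->R2"), ligand = c("L1", "L2"),
    receptor = c("R1", "R2")))
  net <- build_ccc_network(tabs, res)
  drop_i <- 1L
  reduced <- structure(net[-drop_i, ], class = class(net),
                       cell_types = attr(net, "cell_types"))
  d_full <- ccc_degrees(net); d_red <- ccc_degrees(reduced)
  s <- net$sender[drop_i]
  expect_equal(d_full$out_degree[d_full$cell_type == s] -
                 d_red$out_degree[d_red$cell_type == s],
               abs(net$weight[drop_i]))
})

test_that("rank_ccc_genes aggregates |weight| per gene and role", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(
    pair_name = c("L1->R1", "L1->R2", "L2->R1"),
    ligand = c("L1", "L1", "L2"), receptor = c("R1", "R2", "R1")))
  net <- build_ccc_network(tabs, res)
  rk <- rank_ccc_genes(net, role = "ligand")
  # brute-force recount
  manual <- aggregate(abs(net$weight),
                      by = list(cell_type = net$sender,
                                gene = vapply(net$ligand_genes, paste,
                                              character(1), collapse = "_")),
                      FUN = sum)
  for (i in seq_len(nrow(manual))) {
    got <- rk$score[rk$cell_type == manual$cell_type[i] &
                      rk$gene == manual$gene[i]]
    expect_equal(got, manual$x[i])
  }
  expect_true(!is.unsorted(rev(rk$score)))
  expect_false("L9" %in% rank_ccc_genes(net, "ligand")$gene)
})

test_that("network construction validates its inputs", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "p", ligand = "L1",
                                receptor = "R1"))
  expect_error(build_ccc_network(tabs["A"], res),
               class = "cscore_config_error")
  expect_error(build_ccc_network(unname(tabs), res),
               class = "cscore_config_error")
  bad <- tabs
  bad$A <- bad$A[c(1, 1, 2), ]
  expect_error(build_ccc_network(bad, res),
               class = "cscore_validation_error")
})

test_that("an empty network yields empty splits, zero degrees, empty ranks", {
  tabs <- hand_scored_tables()
  res <- lr_resource(data.frame(pair_name = "X->Y", ligand = "X",
                                receptor = "Y"))
  net <- build_ccc_network(tabs, res)
  expect_equal(nrow(net), 0)
  parts <- split_by_sign(net)
  expect_equal(nrow(parts$shared), 0)
  deg <- ccc_degrees(net)
  expect_true(all(deg$out_degree == 0) && all(deg$in_degree == 0))
  expect_equal(nrow(rank_ccc_genes(net, "receptor")), 0)
})
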