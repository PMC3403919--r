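test_that("degree ranking finds hubs first and breaks ties lexicographically", {
  fx <- usecase_seed_toy(1)
  rk <- rank_by_degree(fx$network)
  expect_equal(rk$label[1], "HexP")
  expect_equal(rk$degree[1], 4)
  # within equal degree, labels are sorted
  deg2 <- rk$label[rk$degree == 2]
  expect_equal(deg2, sort(deg2))
})

test_that("splitting a hub makes one clone per reaction and is invertible", {
  fx <- usecase_seed_toy(1)
  net <- split_label(fx$network, "HexP")
  clones <- net$nodes[net$nodes$label == "HexP", ]
  expect_equal(nrow(clones), 4)
  expect_equal(sort(clones$clone_index), 1:4)
  for (cid in clones$id)
    expect_equal(sum(net$edges$from == cid) + sum(net$edges$to == cid), 1)
  expect_equal(nrow(net$edges), nrow(fx$network$edges))
  expect_equal(nrow(net$nodes), nrow(fx$network$nodes) + 3)

  back <- unsplit_label(net, "HexP")
  expect_true(networks_equal(fx$network, back))
})

test_that("clone indices follow ascending reaction-label order", {
  fx <- usecase_seed_toy(1)
  net <- split_label(fx$network, "HexP")
  rxn_of_clone <- vapply(sort(net$nodes$id[net$nodes$label == "HexP"]), function(cid) {
    e <- net$edges
    hit <- c(e$to[e$from == cid], e$from[e$to == cid])
    sub("^rxn:", "", hit[1])
  }, character(1))
  expect_equal(unname(rxn_of_clone), sort(unname(rxn_of_clone)))
})

test_that("degenerate and erroneous splits are handled", {
  fx <- usecase_seed_toy(1)
  # metabolite in exactly one reaction: identity
  expect_true(networks_equal(split_label(fx$network, "starch"), fx$network))
  expect_error(split_label(fx$network, "nope"), class = "fluxmapr_no_such_label")
  once <- split_label(fx$network, "HexP")
  expect_error(split_label(once, "HexP"), class = "fluxmapr_already_split")
  expect_error(unsplit_label(fx$network, "HexP"), class = "fluxmapr_not_split")
  expect_error(unsplit_label(fx$network, "nope"), class = "fluxmapr_no_such_label")
})

test_that("successive splits commute up to isomorphism", {
  fx <- generate_fixture("branched", 8, seed = 61)
  labels <- rank_by_degree(fx$network)$label[1:2]
  ab <- split_label(split_label(fx$network, labels[1]), labels[2])
  ba <- split_label(split_label(fx$network, labels[2]), labels[1])
  expect_true(networks_isomorphic(ab, ba))
  undone <- unsplit_label(unsplit_label(ab, labels[2]), labels[1])
  expect_true(networks_equal(undone, fx$network))
})

test_that("a split metabolite both consumed and produced by one reaction keeps one clone", {
  exp <- flux_experiment(conditions = "c", timepoints = "t",
                         weights = c(A = 1, X = 1, B = 1, C = 1),
                         reactions = list(parse_reaction_equation("A + X -> X + B", "shuttle"),
                                          parse_reaction_equation("B -> X", "mk"),
                                          parse_reaction_equation("X -> C", "use")))
  net <- split_label(network_from_experiment(exp), "X")
  clones <- net$nodes[net$nodes$label == "X", ]
  expect_equal(nrow(clones), 3)   # one per reaction, not one per edge
  shuttle_clone <- clones$id[vapply(clones$id, function(cid)
    any(net$edges$from == cid & net$edges$to == "rxn:shuttle"), logical(1))]
  expect_equal(sum(net$edges$from == shuttle_clone) +
                 sum(net$edges$to == shuttle_clone), 2)
})

test_that("reconnection overlays are counting-correct, disjoint and removable", {
  fx <- usecase_seed_toy(1)
  net <- split_label(split_label(fx$network, "HexP"), "AcCoA")
  ov1 <- reconnect_label(net, "HexP")
  expect_equal(length(ov1$member_ids), 4)
  expect_equal(nrow(ov1$overlay_edges), 4)
  ov2 <- reconnect_label(net, "AcCoA")
  overlays <- list(ov1, ov2)
  expect_length(intersect(ov1$member_ids, ov2$member_ids), 0)
  overlays <- remove_overlay(overlays, "HexP")
  expect_equal(vapply(overlays, `[[`, "", "label"), "AcCoA")
  expect_error(reconnect_label(fx$network, "starch"),
               class = "fluxmapr_nothing_to_connect")
})

test_that("the built-in layered layout is deterministic, finite and monotone on chains", {
  fx <- generate_fixture("chain", 5, seed = 71)
  l1 <- layout_dot(fx$network, engine = "builtin")
  l2 <- layout_dot(fx$network, engine = "builtin")
  expect_identical(l1$coordinates, l2$coordinates)
  expect_true(all(is.finite(l1$coordinates$x)))
  expect_true(all(is.finite(l1$coordinates$y)))
  # a chain's y coordinates strictly increase along the path
  path_ids <- c(rbind(paste0("met:", sprintf("M%02d", 1:5), ":0"),
                      paste0("rxn:", sprintf("r%02d", 1:5))), "met:M06:0")
  ys <- l1$coordinates$y[match(path_ids, l1$coordinates$id)]
  expect_true(all(diff(ys) > 0))
  # orientation swap exchanges the roles of x and y
  lr <- layout_dot(fx$network, orientation = "LR", engine = "builtin")
  xs <- lr$coordinates$x[match(path_ids, lr$coordinates$id)]
  expect_true(all(diff(xs) > 0))
  # bounding box encloses everything
  expect_true(all(l1$coordinates$x <= l1$bounding_box[1]))
  expect_true(all(l1$coordinates$y <= l1$bounding_box[2]))
})

test_that("cycles and all fixture topologies get finite coordinates", {
  for (seed in 72:75) {
    fx <- generate_fixture(c("cycle", "branched")[(seed %% 2) + 1], 6, seed = seed)
    co <- layout_dot(fx$network, engine = "builtin")$coordinates
    expect_equal(nrow(co), nrow(fx$network$nodes))
    expect_true(all(is.finite(co$x) & is.finite(co$y)))
  }
})

test_that("DOT text emission quotes ids and carries the rank direction", {
  fx <- generate_fixture("chain", 3, seed = 76)
  txt <- dot_text(fx$network, "LR")
  expect_match(txt, "rankdir=LR")
  expect_match(txt, '"met:M01:0" -> "rxn:r01"', fixed = TRUE)
})
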