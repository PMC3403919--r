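test_that("the generator is fully deterministic under a fixed seed", {
  a <- generate_fixture("branched", 7, seed = 91, quality_mode = "variability",
                        n_conditions = 2)
  b <- generate_fixture("branched", 7, seed = 91, quality_mode = "variability",
                        n_conditions = 2)
  fa <- tempfile(); fb <- tempfile()
  write_template(a$experiment, fa); write_template(b$experiment, fb)
  expect_identical(readLines(fa), readLines(fb))   # byte-identical templates
  expect_true(networks_equal(a$network, b$network))
  c <- generate_fixture("branched", 7, seed = 92, quality_mode = "variability",
                        n_conditions = 2)
  expect_false(identical(a$experiment$measurements, c$experiment$measurements))
})

test_that("balanced fixtures pass validation at reaction and metabolite level", {
  for (seed in 101:112) {
    topo <- c("chain", "branched", "cycle")[(seed %% 3) + 1]
    fx <- generate_fixture(topo, 3 + seed %% 11, seed = seed,
                           n_conditions = 1 + seed %% 2)
    for (cond in fx$experiment$conditions) {
      s <- map_slice(fx$network, fx$experiment, cond, "T1")
      r <- validate_reactions(s)
      expect_true(all(r$reactions$balanced), info = paste(topo, seed))
      m <- validate_metabolites(s, fx$external_labels)
      expect_true(balanced_labels_ok(m, fx$external_labels), info = paste(topo, seed))
    }
  }
})

test_that("a 3-reaction mass chain flags only the two termini", {
  fx <- generate_fixture("chain", 3, weights_mode = "mass", seed = 113)
  s <- map_slice(fx$network, fx$experiment, "C1", "T1")
  m <- validate_metabolites(s)$metabolites
  expect_setequal(m$label[!m$balanced], c("M01", "M04", "Mby"))
  expect_setequal(fx$external_labels, c("M01", "M04", "Mby"))
})

test_that("each corruption class is detected at exactly the injected reaction", {
  types <- c("misspell_label", "glued_stoichiometry", "wrong_stoichiometry",
             "missing_reactant")
  for (i in seq_along(types)) {
    for (seed in c(121, 122, 123)) {
      fx <- generate_fixture("branched", 6 + seed %% 3, seed = seed,
                             corruption = types[i])
      expect_equal(fx$corruption$type, types[i])
      s <- map_slice(fx$network, fx$experiment, "C1", "T1")
      r <- validate_reactions(s)$reactions
      expect_equal(r$label[!r$balanced], fx$corruption$reaction,
                   info = paste(types[i], seed))
    }
  }
})

test_that("mass-mode fixtures exercise the unbalanceable reaction class", {
  fx <- generate_fixture("chain", 5, weights_mode = "mass", seed = 131)
  counts <- vapply(fx$experiment$reactions,
                   function(r) nrow(r$reactants) - nrow(r$products), numeric(1))
  expect_true(any(counts != 0))
  s <- map_slice(fx$network, fx$experiment, "C1", "T1")
  r <- validate_reactions(s)$reactions
  expect_setequal(r$label[!r$balanced],
                  vapply(fx$experiment$reactions, function(x) x$name,
                         "")[counts != 0])
})

test_that("infeasible topology requests are rejected", {
  expect_error(generate_fixture("cycle", 1, seed = 1), class = "fluxmapr_spec_error")
  expect_error(generate_fixture("branched", 2, seed = 1), class = "fluxmapr_spec_error")
  expect_error(generate_fixture("chain", 3, weights_mode = "mass", seed = 1,
                                corruption = "glued_stoichiometry"),
               class = "fluxmapr_spec_error")
})

test_that("the seed toy routes carbon to opposite sinks in its two conditions", {
  fx <- usecase_seed_toy(5)
  expect_equal(fx$experiment$conditions, c("A", "B"))
  slices <- lapply(c("A", "B"), function(cond)
    map_slice(fx$network, fx$experiment, cond, "t1"))
  for (s in slices) {
    expect_true(all(validate_reactions(s)$reactions$balanced))
    expect_true(balanced_labels_ok(validate_metabolites(s, fx$external_labels),
                                   fx$external_labels))
  }
  starch_key <- "rxn:r_starch->met:starch:0"
  lip_key <- "rxn:r_lip->met:lipids:0"
  # condition A is the starch storer, B the lipid storer
  expect_gt(slices[[1]]$edge_flux[[starch_key]], slices[[2]]$edge_flux[[starch_key]])
  expect_lt(slices[[1]]$edge_flux[[lip_key]], slices[[2]]$edge_flux[[lip_key]])
  # the designed 70/30 hexose-phosphate split is recoverable: starch receives
  # alpha of the 12 C entering, lipids 2/3 of the rest (one C in three leaves
  # as CO2 at pyruvate decarboxylation)
  expect_equal(slices[[1]]$edge_flux[[starch_key]] / 12, 0.7)
  expect_equal(slices[[2]]$edge_flux[[starch_key]] / 12, 0.3)
  expect_equal(slices[[1]]$edge_flux[[lip_key]], 12 * 0.3 * 2 / 3)
})

test_that("the FBA toy reverses its cycle across oxygen conditions", {
  fx <- usecase_fba_toy(5)
  expect_true(all(fx$experiment$weights == 1))
  s_an <- map_slice(fx$network, fx$experiment, "anoxic", "t1")
  s_hy <- map_slice(fx$network, fx$experiment, "hypoxic", "t1")
  s_ae <- map_slice(fx$network, fx$experiment, "aerobic", "t1")
  # anoxic: A -> c1; aerobic: c1 -> A (reversed)
  an <- s_an$edges; ae <- s_ae$edges
  expect_true(any(an$from == "met:A:0" & an$to == "rxn:c1"))
  expect_true(any(ae$from == "rxn:c1" & ae$to == "met:A:0"))
  # hypoxic: the cycle is broken, c3 dashed
  hy <- s_hy$edges
  expect_true(all(hy$zero[hy$base_from == "rxn:c3" | hy$base_to == "rxn:c3"]))
  # internal metabolites balance in every condition given the external list
  for (s in list(s_an, s_hy, s_ae))
    expect_true(balanced_labels_ok(validate_metabolites(s, fx$external_labels),
                                   fx$external_labels))
  # zero flux variability exists and renders black even in red mode
  q0 <- s_an$reaction_quality[["rxn:r_upt"]]
  expect_equal(q0, 0)
  sg <- style_slice(s_an, layout_dot(fx$network, engine = "builtin"),
                    flux_style(quality_mode = "red_graduation", quality_range = c(0, 1.5)))
  upt_edges <- sg$edges$color[sg$edges$from == "rxn:r_upt" | sg$edges$to == "rxn:r_upt"]
  expect_true(all(upt_edges == "#000000"))
})
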