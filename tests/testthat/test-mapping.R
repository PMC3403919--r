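test_that("per-edge flux is |v| * stoichiometry * weight", {
  expect_equal(effective_edge_flux(2, 1, 1), 2)
  expect_equal(effective_edge_flux(1.5, 2, 6), 18)
  expect_equal(effective_edge_flux(-3, 1, 2), 6)
  expect_equal(effective_edge_flux(1, 0.5, 0), 0)   # zero-weight metabolite
  expect_error(effective_edge_flux(Inf, 1, 1), class = "fluxmapr_numeric_error")
  expect_error(effective_edge_flux(1, NaN, 1), class = "fluxmapr_numeric_error")
})

simple_exp <- function(v) {
  flux_experiment(conditions = "c", timepoints = "t",
                  weights = c(A = 1, B = 1),
                  reactions = list(parse_reaction_equation("A -> B", "r")),
                  measurements = data.frame(reaction = "r", condition = "c",
                                            timepoint = "t", value = v,
                                            quality = NA_real_))
}

test_that("a negative flux reverses the reaction's edges within the slice", {
  exp <- simple_exp(-1)
  net <- network_from_experiment(exp)
  s <- map_slice(net, exp, "c", "t")
  e <- s$edges
  expect_equal(e$from[e$base_from == "met:A:0"], "rxn:r")   # A->rxn became rxn->A
  expect_equal(e$to[e$base_from == "met:A:0"], "met:A:0")
  expect_equal(e$from[e$base_to == "met:B:0"], "met:B:0")
  expect_true(all(e$flux == 1))
  # the base network is immutable
  expect_equal(net$edges$from[1], "met:A:0")
})

test_that("zero and unmeasured fluxes keep their edges, dashed", {
  exp <- simple_exp(0)
  net <- network_from_experiment(exp)
  s <- map_slice(net, exp, "c", "t")
  expect_equal(nrow(s$edges), nrow(net$edges))
  expect_true(all(s$edges$zero))
  expect_equal(sort(s$zero_edges), sort(paste0(net$edges$from, "->", net$edges$to)))

  # a reaction measured in no slice at all is zero-flux, not an error
  fx <- usecase_seed_toy(1)
  exp2 <- fx$experiment
  exp2$measurements <- exp2$measurements[exp2$measurements$reaction != "r_lip", ]
  s2 <- map_slice(fx$network, exp2, "A", "t1")
  expect_equal(nrow(s2$edges), nrow(fx$network$edges))
  lip_edges <- s2$edges$zero[s2$edges$from == "rxn:r_lip" | s2$edges$to == "rxn:r_lip"]
  expect_true(all(lip_edges))
})

test_that("mapping errors are typed", {
  exp <- simple_exp(1)
  net <- network_from_experiment(exp)
  expect_error(map_slice(net, exp, "nope", "t"), class = "fluxmapr_cross_reference_error")
  expect_error(map_slice(net, exp, "c", "nope"), class = "fluxmapr_cross_reference_error")
  # measurement for a reaction the network does not contain
  bigger <- flux_experiment(conditions = "c", timepoints = "t",
                            weights = c(A = 1, B = 1, C = 1),
                            reactions = list(parse_reaction_equation("A -> B", "r"),
                                             parse_reaction_equation("B -> C", "r2")),
                            measurements = data.frame(reaction = c("r", "r2"),
                                                      condition = "c", timepoint = "t",
                                                      value = 1, quality = NA_real_))
  expect_error(map_slice(net, bigger, "c", "t"), class = "fluxmapr_unmapped_measurement")
})

test_that("mapping is deterministic, linear in the data, and |v| under unit weights", {
  fx <- generate_fixture("branched", 8, seed = 77, quality_mode = "confidence")
  s1 <- map_slice(fx$network, fx$experiment, "C1", "T1")
  s2 <- map_slice(fx$network, fx$experiment, "C1", "T1")
  expect_identical(s1, s2)

  scaled <- fx$experiment
  scaled$measurements$value <- scaled$measurements$value * 3.5
  s3 <- map_slice(fx$network, scaled, "C1", "T1")
  expect_equal(s3$edge_flux, s1$edge_flux * 3.5)

  # mass-flux degenerate case: every incident edge carries |v|
  fm <- generate_fixture("chain", 5, weights_mode = "mass", seed = 78)
  sm <- map_slice(fm$network, fm$experiment, "C1", "T1")
  v_of <- stats::setNames(fm$experiment$measurements$value,
                          paste0("rxn:", fm$experiment$measurements$reaction))
  for (i in seq_len(nrow(sm$edges))) {
    rid <- if (grepl("^rxn:", sm$edges$from[i])) sm$edges$from[i] else sm$edges$to[i]
    expect_equal(sm$edges$flux[i], abs(v_of[[rid]]))
  }
})

test_that("double negation is the identity; single negation flips orientation only", {
  fx <- generate_fixture("cycle", 6, seed = 79)
  base <- map_slice(fx$network, fx$experiment, "C1", "T1")
  neg <- fx$experiment
  neg$measurements$value <- -neg$measurements$value
  flipped <- map_slice(fx$network, neg, "C1", "T1")
  expect_equal(flipped$edges$from, base$edges$to)
  expect_equal(flipped$edges$to, base$edges$from)
  expect_equal(flipped$edge_flux, base$edge_flux)
  negneg <- neg
  negneg$measurements$value <- -negneg$measurements$value
  expect_identical(map_slice(fx$network, negneg, "C1", "T1"), base)
})

test_that("slices enumerate condition-major in declaration order", {
  exp <- flux_experiment(conditions = c("b_cond", "a_cond"), timepoints = c("t2", "t1", "t0"),
                         weights = c(A = 1, B = 1),
                         reactions = list(parse_reaction_equation("A -> B", "r")))
  sl <- list_slices(exp)
  expect_equal(nrow(sl), 6)
  expect_equal(sl$condition, rep(c("b_cond", "a_cond"), each = 3))
  expect_equal(sl$timepoint[1:3], c("t2", "t1", "t0"))   # declaration order, not sorted
})
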