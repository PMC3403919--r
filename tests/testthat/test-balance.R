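suc_exp <- function(equation, weights, v = 1) {
  flux_experiment(conditions = "c", timepoints = "t", weights = weights,
                  reactions = list(parse_reaction_equation(equation, "inv")),
                  measurements = data.frame(reaction = "inv", condition = "c",
                                            timepoint = "t", value = v,
                                            quality = NA_real_))
}

slice_of <- function(exp) map_slice(network_from_experiment(exp), exp, "c", "t")

test_that("carbon-weighted sucrose cleavage balances by hand-sum", {
  exp <- suc_exp("Suc -> Fru + Glc", c(Suc = 12, Fru = 6, Glc = 6))
  r <- validate_reactions(slice_of(exp))$reactions
  expect_equal(r$inflow, 12)
  expect_equal(r$outflow, 12)
  expect_equal(r$residual, 0)
  expect_true(r$balanced)
})

test_that("the glued-stoichiometry typo class is caught as an imbalance", {
  # "2Suc" parsed as a label of its own weight: reactant side loses a factor 2
  exp <- suc_exp("2Suc -> Fru + Glc", c(`2Suc` = 12, Fru = 6, Glc = 6, Suc = 12))
  r <- validate_reactions(slice_of(exp))$reactions
  expect_equal(r$inflow, 12)    # should have been 2 * 12
  expect_equal(r$outflow, 12)   # products unchanged...
  exp2 <- suc_exp("2Suc -> Fru + Glc + Fum", c(`2Suc` = 12, Fru = 6, Glc = 6, Fum = 12))
  r2 <- validate_reactions(slice_of(exp2))$reactions
  expect_false(r2$balanced)
  expect_equal(r2$residual, 12 - 24)
})

test_that("mass-flux reactions with unequal term counts cannot balance", {
  exp <- suc_exp("A + B -> C", c(A = 1, B = 1, C = 1), v = 2)
  r <- validate_reactions(slice_of(exp))$reactions
  expect_equal(r$inflow, 4)
  expect_equal(r$outflow, 2)
  expect_false(r$balanced)
})

test_that("metabolite balance flags only non-exempt termini of a chain", {
  exp <- flux_experiment(conditions = "c", timepoints = "t",
                         weights = c(A = 1, B = 1, C = 1),
                         reactions = list(parse_reaction_equation("A -> B", "r1"),
                                          parse_reaction_equation("B -> C", "r2")),
                         measurements = data.frame(reaction = c("r1", "r2"),
                                                   condition = "c", timepoint = "t",
                                                   value = 1, quality = NA_real_))
  s <- slice_of(exp)
  m <- validate_metabolites(s)$metabolites
  expect_true(m$balanced[m$label == "B"])
  expect_false(m$balanced[m$label == "A"])
  expect_false(m$balanced[m$label == "C"])
  sm <- summarize_report(validate_metabolites(s, external_labels = c("A", "C")))
  expect_equal(sm$status, 0L)
})

test_that("an unmeasured metabolite is trivially balanced", {
  fx <- usecase_seed_toy(1)
  exp <- fx$experiment
  exp$measurements <- exp$measurements[exp$measurements$reaction != "r_lip", ]
  m <- validate_metabolites(map_slice(fx$network, exp, "A", "t1"))$metabolites
  row <- m[m$label == "lipids", ]
  expect_equal(row$production, 0)
  expect_equal(row$consumption, 0)
  expect_true(row$balanced)
})

test_that("splitting clones changes no per-label or per-reaction sums", {
  fx <- usecase_seed_toy(7)
  hub <- rank_by_degree(fx$network)$label[1]
  unsplit_slice <- map_slice(fx$network, fx$experiment, "B", "t1")
  split_slice <- map_slice(split_label(fx$network, hub), fx$experiment, "B", "t1")
  mu <- validate_metabolites(unsplit_slice)$metabolites
  ms <- validate_metabolites(split_slice)$metabolites
  mu <- mu[order(mu$label), ]; ms <- ms[order(ms$label), ]
  expect_identical(mu$production, ms$production)
  expect_identical(mu$consumption, ms$consumption)
  ru <- validate_reactions(unsplit_slice)$reactions
  rs <- validate_reactions(split_slice)$reactions
  expect_identical(ru$residual, rs$residual)
})

test_that("residuals agree with the brute-force incidence oracle", {
  for (seed in 41:46) {
    fx <- generate_fixture(c("chain", "branched", "cycle")[(seed %% 3) + 1],
                           4 + seed %% 9, seed = seed, n_conditions = 2)
    s <- map_slice(fx$network, fx$experiment, "C2", "T1")
    sums <- oracle_node_sums(s)
    r <- validate_reactions(s)$reactions
    for (i in seq_len(nrow(r))) {
      j <- match(paste0("rxn:", r$label[i]), sums$node)
      expect_equal(r$inflow[i], sums$inflow[j])
      expect_equal(r$outflow[i], sums$outflow[j])
    }
    m <- validate_metabolites(s)$metabolites
    for (i in seq_len(nrow(m))) {
      j <- match(paste0("met:", m$label[i], ":0"), sums$node)
      expect_equal(m$production[i], sums$inflow[j])
      expect_equal(m$consumption[i], sums$outflow[j])
    }
  }
})

test_that("the balanced verdict is invariant under flux rescaling", {
  fx <- generate_fixture("branched", 7, seed = 51)
  verdict <- function(exp) {
    s <- map_slice(fx$network, exp, "C1", "T1")
    c(validate_reactions(s)$reactions$balanced,
      validate_metabolites(s)$metabolites$balanced)
  }
  base <- verdict(fx$experiment)
  for (c_scale in c(1e-6, 1e-3, 1e3, 1e6)) {
    scaled <- fx$experiment
    scaled$measurements$value <- scaled$measurements$value * c_scale
    expect_identical(verdict(scaled), base, info = paste("scale", c_scale))
  }
})

test_that("zero-flux reactions get a structural check with warning severity", {
  # structurally broken reaction, but measured 0: not a failure, a warning
  exp <- suc_exp("Suc -> Fru", c(Suc = 12, Fru = 6), v = 0)
  rep <- validate_reactions(slice_of(exp))
  r <- rep$reactions
  expect_true(r$balanced)          # 0 = 0 numerically
  expect_true(r$zero_flux)
  expect_true(r$structural_warning)
  expect_equal(summarize_report(rep)$status, 0L)
  expect_match(paste(summarize_report(rep)$text, collapse = "\n"), "structurally")
  # structurally sound zero-flux reaction: no warning
  exp2 <- suc_exp("Suc -> Fru + Glc", c(Suc = 12, Fru = 6, Glc = 6), v = 0)
  expect_false(validate_reactions(slice_of(exp2))$reactions$structural_warning)
})

test_that("failures sort by |residual| descending with lexicographic ties", {
  exp <- flux_experiment(conditions = "c", timepoints = "t",
                         weights = c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1),
                         reactions = list(parse_reaction_equation("A + B -> C", "zz"),
                                          parse_reaction_equation("D + E -> F", "aa"),
                                          parse_reaction_equation("A -> F", "mid")),
                         measurements = data.frame(reaction = c("zz", "aa", "mid"),
                                                   condition = "c", timepoint = "t",
                                                   value = c(1, 1, 5), quality = NA_real_))
  s <- slice_of(exp)
  sm <- summarize_report(validate_reactions(s))
  expect_equal(sm$status, 3L)
  fails <- sm$data$unbalanced
  # zz and aa tie at |residual| = 1; mid is balanced (1 in, 1 out, scaled by 5)
  expect_equal(fails$label, c("aa", "zz"))
})
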