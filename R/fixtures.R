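# Deterministic generators of synthetic flux datasets. Balanced fixtures are
# balanced *by construction*: stoichiometries are derived from the substance
# weights (s_product = w_reactant / w_product for a 1-reactant conversion) so
# every reaction conserves the traced atoms exactly, and measurements are
# propagated along the topology so every internal metabolite is at steady
# state. No tolerance games: the only rounding is IEEE double arithmetic.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic flux dataset
#'
#' Builds a network topology (linear chain, branched chain, cycle, or a
#' fixed central-metabolism toy), assigns substance weights, derives
#' stoichiometries that balance every reaction exactly, and propagates flux
#' measurements so every internal metabolite is steady-state balanced.
#' In `weights_mode = "mass"` all weights are 1, all stoichiometries 1, and
#' the terminal reaction gains a byproduct so at least one reaction has
#' unequal substrate/product counts — the class of reactions that can never
#' be balanced in a mass-flux map. An optional corruption injects one
#' template-typo class into one reaction and records the ground truth.
#'
#' @param topology `"chain"`, `"branched"`, `"cycle"` or
#'   `"central_metabolism_toy"`.
#' @param n_reactions Number of reactions (chain >= 1, cycle >= 2,
#'   branched >= 3; ignored by the fixed toy).
#' @param weights_mode `"carbon_like"` (integer weights in 1..12) or
#'   `"mass"` (all 1).
#' @param n_conditions,n_timepoints Numbers of conditions/timepoints.
#' @param quality_mode `"none"`, `"confidence"` (uncertainties in
#'   0.01..0.2) or `"variability"` (FVA-style ranges in 0..2 with exact
#'   zeros).
#' @param seed Integer; fully determines the output.
#' @param corruption `NULL` or one of `"misspell_label"`,
#'   `"glued_stoichiometry"`, `"wrong_stoichiometry"`, `"missing_reactant"`.
#' @param corrupt_target Reaction name to corrupt; default picks one
#'   deterministically.
#' @return List with `network`, `experiment`, `external_labels` (boundary
#'   metabolites that legitimately violate steady state), and `corruption`
#'   (`NULL`, or `list(type, reaction)` ground truth).
#' @export
generate_fixture <- function(topology = c("chain", "branched", "cycle",
                                          "central_metabolism_toy"),
                             n_reactions = 5, weights_mode = c("carbon_like", "mass"),
                             n_conditions = 1, n_timepoints = 1,
                             quality_mode = c("none", "confidence", "variability"),
                             seed = 1, corruption = NULL, corrupt_target = NULL) {
  topology <- match.arg(topology)
  weights_mode <- match.arg(weights_mode)
  quality_mode <- match.arg(quality_mode)
  if (!is.null(corruption))
    corruption <- match.arg(corruption, c("misspell_label", "glued_stoichiometry",
                                          "wrong_stoichiometry", "missing_reactant"))
  if (topology == "chain" && n_reactions < 1) fm_stop("spec_error", "chain needs >= 1 reaction")
  if (topology == "cycle" && n_reactions < 2) fm_stop("spec_error", "cycle needs >= 2 reactions")
  if (topology == "branched" && n_reactions < 3) fm_stop("spec_error", "branched needs >= 3 reactions")
  if (topology == "central_metabolism_toy")
    return(usecase_seed_toy(seed))

  with_seed(seed, {
    n <- n_reactions
    mlab <- sprintf("M%02d", seq_len(n + 1L))
    rlab <- sprintf("r%02d", seq_len(n))

    # segment structure: list of (reactant index, product index) per reaction,
    # plus the atom-flux fraction each reaction carries relative to the trunk
    if (topology == "chain") {
      pairs <- cbind(seq_len(n), seq_len(n) + 1L)
      frac <- rep(1, n)
      external <- mlab[c(1L, n + 1L)]
    } else if (topology == "cycle") {
      mlab <- mlab[seq_len(n)]
      pairs <- cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))
      frac <- rep(1, n)
      external <- character()
    } else { # branched: 1 trunk reaction, then two branches from M2
      b1 <- max(1L, (n - 1L) %/% 2L)
      b2 <- n - 1L - b1
      alpha <- stats::runif(1, 0.25, 0.75)
      branch1 <- 1L + seq_len(b1)           # M2 -> M3 -> ... (reactions 2..)
      pairs <- rbind(c(1L, 2L),
                     cbind(c(2L, 2L + seq_len(b1 - 1L)), 2L + seq_len(b1)),
                     cbind(c(2L, 2L + b1 + seq_len(b2 - 1L)), 2L + b1 + seq_len(b2)))
      frac <- c(1, rep(alpha, b1), rep(1 - alpha, b2))
      external <- mlab[c(1L, 2L + b1, 2L + b1 + b2)]
      mlab <- mlab[seq_len(2L + b1 + b2)]
    }

    if (weights_mode == "mass") {
      w <- stats::setNames(rep(1, length(mlab)), mlab)
    } else {
      w <- stats::setNames(sample(1:12, length(mlab), replace = TRUE), mlab)
    }
    if (identical(corruption, "glued_stoichiometry")) {
      if (weights_mode == "mass")
        fm_stop("spec_error",
                "glued_stoichiometry needs a non-unit stoichiometry; mass mode has none")
      # give the target reaction an exactly-2 product stoichiometry
      ti <- target_index(corruption, corrupt_target, rlab, topology)
      w[mlab[pairs[ti, 1]]] <- 2 * w[mlab[pairs[ti, 2]]]
    }

    equations <- character(n)
    for (i in seq_len(n)) {
      rl <- mlab[pairs[i, 1]]; pl <- mlab[pairs[i, 2]]
      s_p <- if (weights_mode == "mass") 1 else w[[rl]] / w[[pl]]
      equations[i] <- paste0(rl, " -> ", if (s_p == 1) pl else paste(fm_num(s_p), pl))
    }

    byproduct <- NULL
    if (weights_mode == "mass") {
      # terminal reaction gains a byproduct: unequal substrate/product count
      byproduct <- "Mby"
      w <- c(w, Mby = 1)
      equations[n] <- paste0(equations[n], " + ", byproduct)
      external <- unique(c(external, byproduct))
    }

    ti <- if (!is.null(corruption)) target_index(corruption, corrupt_target, rlab, topology) else NA_integer_
    if (identical(corruption, "missing_reactant")) {
      # balanced cofactor couple on the target; corruption will drop ATPc
      w <- c(w, ATPc = 10, ADPc = 10)
      equations[ti] <- sub(" -> ", " + ATPc -> ", equations[ti], fixed = TRUE)
      equations[ti] <- paste0(equations[ti], " + ADPc")
      external <- unique(c(external, "ATPc", "ADPc"))
    }

    conditions <- sprintf("C%d", seq_len(n_conditions))
    timepoints <- sprintf("T%d", seq_len(n_timepoints))
    meas <- NULL
    for (ci in seq_along(conditions)) for (tj in seq_along(timepoints)) {
      trunk_atoms <- stats::runif(1, 2, 20)   # atom flux through the trunk
      v <- trunk_atoms * frac / unname(w[mlab[pairs[, 1]]])
      q <- switch(quality_mode,
                  none = rep(NA_real_, n),
                  confidence = stats::runif(n, 0.01, 0.2),
                  variability = ifelse(stats::runif(n) < 0.2, 0, stats::runif(n, 0, 2)))
      meas <- rbind(meas, data.frame(reaction = rlab, condition = conditions[ci],
                                     timepoint = timepoints[tj], value = v,
                                     quality = q, stringsAsFactors = FALSE))
    }

    corr_info <- NULL
    if (!is.null(corruption)) {
      cr <- corrupt_equation(equations[ti], corruption)
      equations[ti] <- cr$equation
      if (!is.null(cr$new_label)) w[cr$new_label] <- cr$new_weight(w)
      corr_info <- list(type = corruption, reaction = rlab[ti])
    }

    reactions <- lapply(seq_len(n), function(i) parse_reaction_equation(equations[i], rlab[i]))
    exp <- flux_experiment(
      metadata = c(title = sprintf("synthetic %s fixture", topology),
                   seed = as.character(seed)),
      conditions = conditions, timepoints = timepoints,
      weights = w, reactions = reactions, measurements = meas)
    list(network = network_from_experiment(exp), experiment = exp,
         external_labels = external, corruption = corr_info)
  })
}

target_index <- function(corruption, corrupt_target, rlab, topology) {
  if (!is.null(corrupt_target)) {
    ti <- match(corrupt_target, rlab)
    if (is.na(ti)) fm_stop("spec_error", sprintf("no reaction '%s' to corrupt", corrupt_target))
    return(ti)
  }
  # deterministic default: middle reaction (never the mass-byproduct terminal)
  max(1L, (length(rlab) + 1L) %/% 2L)
}

# rewrite one equation according to the corruption class; returns the new
# text plus (for label-changing typos) the weight entry the typo'd template
# would carry
corrupt_equation <- function(text, type) {
  eq <- parse_reaction_equation(text, "tmp")
  if (type == "misspell_label") {
    lbl <- eq$reactants$label[1]
    bad <- paste0(lbl, "r")
    eq$reactants$label[1] <- bad
    list(equation = deparse_eq_sides(eq), new_label = bad,
         new_weight = function(w) unname(w[lbl]) + 1)
  } else if (type == "glued_stoichiometry") {
    i <- which(eq$products$stoichiometry != 1)[1]
    if (is.na(i)) fm_stop("spec_error", "glued_stoichiometry needs a product with stoichiometry != 1")
    glued <- paste0(fm_num(eq$products$stoichiometry[i]), eq$products$label[i])
    orig <- eq$products$label[i]
    eq$products$label[i] <- glued
    eq$products$stoichiometry[i] <- 1
    list(equation = deparse_eq_sides(eq), new_label = glued,
         new_weight = function(w) unname(w[orig]))
  } else if (type == "wrong_stoichiometry") {
    eq$products$stoichiometry[1] <- 2 * eq$products$stoichiometry[1]
    list(equation = deparse_eq_sides(eq), new_label = NULL)
  } else { # missing_reactant
    if (nrow(eq$reactants) < 2L)
      fm_stop("spec_error", "missing_reactant needs >= 2 reactants")
    eq$reactants <- eq$reactants[-match("ATPc", eq$reactants$label), , drop = FALSE]
    list(equation = deparse_eq_sides(eq), new_label = NULL)
  }
}

deparse_eq_sides <- function(eq) deparse_reaction_equation(eq)

#' Two-condition carbon-flux toy (seed metabolism)
#'
#' A fixed toy emulating a 13C seed-metabolism dataset: two conditions
#' (`"A"`, starch-storing, and `"B"`, lipid-storing), one timepoint, carbon
#' substance weights, confidence qualities, and yellow-flagged sink
#' metabolites `starch` and `lipids`. Condition A routes 70% of the hexose
#' phosphate carbon to starch and 30% to lipids; condition B the reverse.
#' Both slices are balanced by construction at reaction and (internal)
#' metabolite level.
#'
#' @param seed Integer seed (drives the quality values).
#' @return Same shape as [generate_fixture()], plus `sinks` naming the two
#'   sink metabolites and `split` with the designed carbon splits.
#' @export
usecase_seed_toy <- function(seed = 1) {
  with_seed(seed, {
    w <- c(Suc = 12, Fru = 6, Glc = 6, HexP = 6, Pyr = 3, AcCoA = 2, CO2 = 1,
           starch = 6, lipids = 6)
    eqs <- c(r_inv    = "Suc -> Fru + Glc",
             r_fru    = "Fru -> HexP",
             r_glc    = "Glc -> HexP",
             r_starch = "HexP -> starch",
             r_gly    = "HexP -> 2 Pyr",
             r_pdh    = "Pyr -> AcCoA + CO2",
             r_lip    = "3 AcCoA -> lipids")
    reactions <- lapply(names(eqs), function(nm) parse_reaction_equation(eqs[[nm]], nm))
    split <- c(A = 0.7, B = 0.3)   # fraction of hexose-phosphate carbon to starch
    meas <- NULL
    for (cond in c("A", "B")) {
      a <- split[[cond]]
      v_gly <- 2 * (1 - a)
      v <- c(r_inv = 1, r_fru = 1, r_glc = 1,
             r_starch = 2 * a, r_gly = v_gly,
             r_pdh = 2 * v_gly, r_lip = 2 * v_gly / 3)
      q <- stats::runif(length(v), 0.02, 0.15)
      meas <- rbind(meas, data.frame(reaction = names(v), condition = cond,
                                     timepoint = "t1", value = unname(v),
                                     quality = q, stringsAsFactors = FALSE))
    }
    exp <- flux_experiment(
      metadata = c(title = "synthetic 13C seed-metabolism toy", seed = as.character(seed)),
      conditions = c("A", "B"), timepoints = "t1",
      weights = w, reactions = reactions, measurements = meas)
    net <- network_from_experiment(exp)
    for (sink in c("starch", "lipids"))
      net$node_attrs[[met_node_id(sink, 0L)]] <- list(fill = "#ffff00")
    list(network = net, experiment = exp,
         external_labels = c("Suc", "starch", "lipids", "CO2"),
         corruption = NULL, sinks = c("starch", "lipids"), split = split)
  })
}

#' Three-condition mass-flux toy (FBA oxygen series)
#'
#' A fixed toy emulating an FBA result series: all substance weights 1
#' (mass fluxes), three oxygen conditions (`"anoxic"`, `"hypoxic"`,
#' `"aerobic"`), flux-variability qualities, and designated uptake/excretion
#' metabolites marked external. Its 3-reaction cycle runs forward under
#' anoxia, is broken (one zero-flux dashed reaction) under hypoxia and runs
#' backward under aerobic conditions, exercising data-driven direction
#' adaptation; the biomass reaction has two substrates and one product, the
#' mass-flux reaction class that can never be balanced. The uptake reaction
#' has quality 0 in every condition (zero flux variability, drawn black).
#'
#' @param seed Integer seed (drives the nonzero quality values).
#' @return Same shape as [generate_fixture()], plus `cycle_reactions`.
#' @export
usecase_fba_toy <- function(seed = 1) {
  with_seed(seed, {
    w <- c(Glc_ext = 1, A = 1, B = 1, C = 1, Biomass = 1, Out = 1)
    eqs <- c(r_upt = "Glc_ext -> A",
             c1 = "A -> B", c2 = "B -> C", c3 = "C -> A",
             r_bio = "A + C -> Biomass",
             r_exc = "C -> Out")
    reactions <- lapply(names(eqs), function(nm) parse_reaction_equation(eqs[[nm]], nm))
    flux <- list(
      anoxic  = c(r_upt = 1.2, c1 = 3, c2 = 3, c3 = 2, r_bio = 0.2, r_exc = 0.8),
      hypoxic = c(r_upt = 1.2, c1 = 1, c2 = 1, c3 = 0, r_bio = 0.2, r_exc = 0.8),
      aerobic = c(r_upt = 1.2, c1 = -1, c2 = -1, c3 = -2, r_bio = 0.2, r_exc = 0.8))
    meas <- NULL
    for (cond in names(flux)) {
      v <- flux[[cond]]
      q <- stats::runif(length(v), 0.1, 1.5)
      q[names(v) == "r_upt"] <- 0       # zero flux variability: drawn black
      meas <- rbind(meas, data.frame(reaction = names(v), condition = cond,
                                     timepoint = "t1", value = unname(v),
                                     quality = q, stringsAsFactors = FALSE))
    }
    exp <- flux_experiment(
      metadata = c(title = "synthetic FBA oxygen-series toy", seed = as.character(seed)),
      conditions = names(flux), timepoints = "t1",
      weights = w, reactions = reactions, measurements = meas)
    net <- network_from_experiment(exp)
    net$node_attrs[[met_node_id("Glc_ext", 0L)]] <- list(fill = "#87cefa")
    net$node_attrs[[met_node_id("Out", 0L)]] <- list(fill = "#87cefa")
    net$node_attrs[[met_node_id("Biomass", 0L)]] <- list(fill = "#ffa500")
    list(network = net, experiment = exp,
         external_labels = c("Glc_ext", "Biomass", "Out"),
         corruption = NULL, cycle_reactions = c("c1", "c2", "c3"))
  })
}
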