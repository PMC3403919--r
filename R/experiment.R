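#' Construct a flux experiment
#'
#' Bundles the six fields of the structured flux-data template: experiment
#' metadata, the measured conditions, the time points/samples, the substance
#' weights (traced atoms per molecule, e.g. carbon counts; all 1 for mass
#' fluxes), the reaction equations and the flux measurements with optional
#' quality values. All cross-references are checked at construction time.
#'
#' @param metadata Named character vector (may be empty) of free-form
#'   experiment annotations.
#' @param conditions Character vector of condition names; order is preserved
#'   everywhere (slice enumeration, output ordering).
#' @param timepoints Character vector of time point/sample names, ordered.
#' @param weights Named numeric vector: metabolite label -> nonnegative
#'   integer substance weight. A weight of 0 (a metabolite carrying none of
#'   the traced element) is allowed but flagged with a warning.
#' @param reactions List of [parse_reaction_equation()] results with unique
#'   names.
#' @param measurements Data frame with columns `reaction`, `condition`,
#'   `timepoint`, `value` (signed flux; sign encodes direction) and `quality`
#'   (numeric, `NA` when absent).
#' @return A `flux_experiment` object.
#' @export
flux_experiment <- function(metadata = character(), conditions, timepoints,
                            weights, reactions, measurements = NULL) {
  if (is.null(measurements))
    measurements <- data.frame(reaction = character(), condition = character(),
                               timepoint = character(), value = numeric(),
                               quality = numeric(), stringsAsFactors = FALSE)
  x <- structure(
    list(metadata = metadata,
         conditions = as.character(conditions),
         timepoints = as.character(timepoints),
         weights = weights,
         reactions = reactions,
         measurements = measurements),
    class = "flux_experiment")
  problems <- experiment_problems(x)
  if (length(problems))
    fm_stop(problems[[1]]$class, problems[[1]]$message,
            details = vapply(problems, `[[`, "", "message"))
  zero <- names(x$weights)[x$weights == 0]
  if (length(zero))
    fm_warn("zero_weight",
            sprintf("substance weight 0 for %s: their edges carry zero substance flux",
                    paste(sQuote(zero), collapse = ", ")))
  x
}

# invariant checks shared by the constructor (first problem, typed) and
# write_template (all problems, as a fail-fast validation_error)
experiment_problems <- function(x) {
  p <- list()
  add <- function(class, message) p[[length(p) + 1L]] <<- list(class = class, message = message)

  if (length(x$conditions) == 0L || any(!nzchar(x$conditions)))
    add("template_format_error", "conditions must be a non-empty list of non-empty names")
  if (length(x$timepoints) == 0L || any(!nzchar(x$timepoints)))
    add("template_format_error", "timepoints must be a non-empty list of non-empty names")
  if (anyDuplicated(x$conditions)) add("template_format_error", "duplicate condition names")
  if (anyDuplicated(x$timepoints)) add("template_format_error", "duplicate timepoint names")

  if (length(x$weights)) {
    if (is.null(names(x$weights)) || any(!nzchar(names(x$weights))))
      add("template_format_error", "all substance weights must be named")
    bad <- !is.finite(x$weights) | x$weights < 0 | x$weights != round(x$weights)
    if (any(bad))
      add("template_format_error",
          sprintf("substance weights must be nonnegative integers (bad: %s)",
                  paste(sQuote(names(x$weights)[bad]), collapse = ", ")))
  }

  rn <- vapply(x$reactions, function(r) r$name, character(1))
  if (anyDuplicated(rn))
    add("template_format_error",
        sprintf("duplicate reaction names: %s",
                paste(sQuote(unique(rn[duplicated(rn)])), collapse = ", ")))
  used <- unique(unlist(lapply(x$reactions, equation_labels)))
  missing_w <- setdiff(used, names(x$weights))
  if (length(missing_w))
    add("missing_weight_error",
        sprintf("no substance weight for metabolite(s): %s",
                paste(sQuote(sort(missing_w)), collapse = ", ")))

  m <- x$measurements
  need <- c("reaction", "condition", "timepoint", "value", "quality")
  if (!all(need %in% names(m))) {
    add("template_format_error",
        sprintf("measurements must have columns %s", paste(need, collapse = ", ")))
    return(p)
  }
  if (nrow(m)) {
    if (any(!m$reaction %in% rn))
      add("cross_reference_error",
          sprintf("measurement(s) for undeclared reaction(s): %s",
                  paste(sQuote(unique(setdiff(m$reaction, rn))), collapse = ", ")))
    if (any(!m$condition %in% x$conditions))
      add("cross_reference_error",
          sprintf("measurement(s) for undeclared condition(s): %s",
                  paste(sQuote(unique(setdiff(m$condition, x$conditions))), collapse = ", ")))
    if (any(!m$timepoint %in% x$timepoints))
      add("cross_reference_error",
          sprintf("measurement(s) for undeclared timepoint(s): %s",
                  paste(sQuote(unique(setdiff(m$timepoint, x$timepoints))), collapse = ", ")))
    key <- paste(m$reaction, m$condition, m$timepoint, sep = "\x1f")
    if (anyDuplicated(key))
      add("template_format_error", "duplicate (reaction, condition, timepoint) measurement")
    if (any(!is.finite(m$value)))
      add("template_format_error", "non-finite flux value in measurements")
    if (any(!is.na(m$quality) & !is.finite(m$quality)))
      add("template_format_error", "non-finite quality value in measurements")
  }
  p
}

#' @export
print.flux_experiment <- function(x, ...) {
  cat("<flux_experiment>\n")
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  %d metabolites (weights %s), %d reactions, %d measurements\n",
              length(x$weights),
              if (length(x$weights) && all(x$weights == 1)) "all 1 (mass flux)"
              else paste0("in [", min(x$weights), ", ", max(x$weights), "]"),
              length(x$reactions), nrow(x$measurements)))
  invisible(x)
}

template_sections <- c("#METADATA", "#CONDITIONS", "#TIMEPOINTS",
                       "#WEIGHTS", "#REACTIONS", "#FLUXES")

#' Parse a structured flux-data template
#'
#' Reads the sectioned template (CSV or single-sheet xlsx) carrying the six
#' template fields. Sections are introduced by header rows `#METADATA`
#' (key, value rows), `#CONDITIONS` and `#TIMEPOINTS` (one name per row),
#' `#WEIGHTS` (label, weight), `#REACTIONS` (name, equation) and `#FLUXES`
#' (reaction, condition, timepoint, value, quality); the quality cell may be
#' empty. All six section headers must be present.
#'
#' @param source Path to a `.csv` or `.xlsx` file.
#' @param dialect `"csv"` or `"xlsx"`; default guesses from the extension.
#' @return A [flux_experiment()].
#' @export
parse_template <- function(source, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx?$", source, ignore.case = TRUE)) "xlsx" else "csv"
  if (!file.exists(source))
    fm_stop("io_failure", sprintf("cannot read template '%s'", source))
  rows <- if (dialect == "xlsx") read_cells_xlsx(source) else read_cells_csv(source)
  experiment_from_rows(rows, source)
}

read_cells_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines, function(l) {
    if (!nzchar(l)) return(character())
    as.character(scan(text = l, what = character(), sep = ",", quote = "\"",
                      quiet = TRUE, strip.white = FALSE))
  })
}

read_cells_xlsx <- function(path) {
  df <- readxl::read_excel(path, col_names = FALSE, col_types = "text",
                           .name_repair = "minimal")
  m <- as.matrix(df)
  lapply(seq_len(nrow(m)), function(i) {
    r <- as.character(m[i, ])
    r[is.na(r)] <- ""
    # trim trailing empty cells so section headers are single-cell rows
    while (length(r) && !nzchar(r[length(r)])) r <- r[-length(r)]
    r
  })
}

experiment_from_rows <- function(rows, source) {
  first <- vapply(rows, function(r) if (length(r)) trimws(r[[1]]) else "", character(1))
  sec_idx <- which(first %in% template_sections)
  found <- first[sec_idx]
  missing <- setdiff(template_sections, found)
  if (length(missing))
    fm_stop("template_format_error",
            sprintf("template '%s': missing section header(s) %s",
                    source, paste(missing, collapse = ", ")),
            sections = missing)
  if (anyDuplicated(found))
    fm_stop("template_format_error",
            sprintf("template '%s': duplicated section header(s)", source))

  body <- function(name) {
    i <- sec_idx[match(name, found)]
    stop_at <- c(sec_idx, length(rows) + 1L)
    j <- min(stop_at[stop_at > i]) - 1L
    if (j < i + 1L) return(list())
    out <- rows[(i + 1L):j]
    out[vapply(out, function(r) any(nzchar(trimws(r))), logical(1))]
  }
  cell <- function(r, k) if (length(r) >= k) trimws(r[[k]]) else ""

  meta_rows <- body("#METADATA")
  metadata <- vapply(meta_rows, cell, "", 2)
  names(metadata) <- vapply(meta_rows, cell, "", 1)

  conditions <- vapply(body("#CONDITIONS"), cell, "", 1)
  timepoints <- vapply(body("#TIMEPOINTS"), cell, "", 1)

  wr <- body("#WEIGHTS")
  weights <- vapply(wr, function(r) parse_cell_number(cell(r, 2), source, "weight"), numeric(1))
  names(weights) <- vapply(wr, cell, "", 1)

  rr <- body("#REACTIONS")
  reactions <- lapply(rr, function(r) parse_reaction_equation(cell(r, 2), cell(r, 1)))

  fr <- body("#FLUXES")
  measurements <- data.frame(
    reaction  = vapply(fr, cell, "", 1),
    condition = vapply(fr, cell, "", 2),
    timepoint = vapply(fr, cell, "", 3),
    value     = vapply(fr, function(r) parse_cell_number(cell(r, 4), source, "flux value"), numeric(1)),
    quality   = vapply(fr, function(r) {
      q <- cell(r, 5)
      if (!nzchar(q)) NA_real_ else parse_cell_number(q, source, "quality")
    }, numeric(1)),
    stringsAsFactors = FALSE)

  flux_experiment(metadata, conditions, timepoints, weights, reactions, measurements)
}

# strict decimal parser: '.' decimals only, no thousands separators
parse_cell_number <- function(s, source, what) {
  if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s))
    fm_stop("template_format_error",
            sprintf("template '%s': cannot parse %s '%s' (use '.' decimals, no grouping)",
                    source, what, s))
  as.numeric(s)
}

#' Write a flux experiment to a sectioned CSV template
#'
#' Emits the template layout read by [parse_template()]; writing then parsing
#' reproduces the experiment exactly (numeric cells use shortest round-trip
#' decimals). The experiment is fully re-validated first and nothing is
#' written if any invariant fails. Only the CSV dialect is written; xlsx
#' templates are read-only.
#'
#' @param experiment A [flux_experiment()].
#' @param destination Output path.
#' @param dialect Must be `"csv"`.
#' @return `destination`, invisibly.
#' @export
write_template <- function(experiment, destination, dialect = "csv") {
  if (!identical(dialect, "csv"))
    fm_stop("io_failure",
            sprintf("dialect '%s' is not writable; templates are written as sectioned CSV", dialect))
  problems <- experiment_problems(unclass_experiment(experiment))
  if (length(problems))
    fm_stop("validation_error",
            paste0("experiment fails validation; nothing written:\n  ",
                   paste(vapply(problems, `[[`, "", "message"), collapse = "\n  ")))
  x <- experiment
  q <- csv_quote
  lines <- c(
    "#METADATA",
    if (length(x$metadata)) paste0(q(names(x$metadata)), ",", q(unname(x$metadata))),
    "#CONDITIONS", q(x$conditions),
    "#TIMEPOINTS", q(x$timepoints),
    "#WEIGHTS",
    if (length(x$weights)) paste0(q(names(x$weights)), ",", fm_num(unname(x$weights))),
    "#REACTIONS",
    vapply(x$reactions, function(r) paste0(q(r$name), ",", q(deparse_reaction_equation(r))), character(1)),
    "#FLUXES",
    if (nrow(x$measurements))
      paste0(q(x$measurements$reaction), ",", q(x$measurements$condition), ",",
             q(x$measurements$timepoint), ",", fm_num(x$measurements$value), ",",
             ifelse(is.na(x$measurements$quality), "", fm_num(x$measurements$quality)))
  )
  ok <- tryCatch({ writeLines(lines, destination, useBytes = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    fm_stop("io_failure", sprintf("cannot write '%s': %s", destination,
                                  conditionMessage(ok)))
  invisible(destination)
}

unclass_experiment <- function(x) {
  y <- unclass(x)
  class(y) <- "flux_experiment"
  y
}

csv_quote <- function(s) {
  needs <- grepl('[",\n]', s)
  s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
  s
}
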