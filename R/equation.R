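#' Parse a reaction equation
#'
#' Parses the arrow-separated reaction mini-language used in flux templates:
#' two non-empty lists of `+`-separated terms, each term an optional
#' stoichiometric factor followed by whitespace and a metabolite label, e.g.
#' `"0.5 Glc + ATP_c -> G6P + ADP_c"`. Accepted arrow tokens are `->`, `-->`,
#' `=>` and the Unicode arrow `→`. An omitted stoichiometry defaults
#' to 1, and factors may be non-integer.
#'
#' The factor must be separated from the label by whitespace: `"2Suc"` is a
#' *label* with stoichiometry 1, not twice `Suc`. This deliberate strictness
#' is what lets downstream balance validation catch the classic glued-number
#' template typo (`"2Suc"` instead of `"2 Suc"`).
#'
#' @param text Equation string containing exactly one arrow token.
#' @param name Reaction identifier attached to the result.
#' @return A `reaction_equation`: list with `name`, `reactants`, `products`;
#'   the sides are data frames with columns `label` and `stoichiometry`.
#' @examples
#' eq <- parse_reaction_equation("Suc -> Fru + Glc", "inv")
#' eq$products$label
#' parse_reaction_equation("2Suc -> Fru", "typo")$reactants  # label "2Suc"!
#' @export
parse_reaction_equation <- function(text, name) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    fm_stop("malformed_equation", "reaction name must be a non-empty string")
  name <- trimws(name)

  # normalize arrow variants to a single sentinel; longest token first
  sep <- "\x01"
  norm <- text
  for (arrow in c("-->", "->", "=>", "\u2192"))
    norm <- gsub(arrow, sep, norm, fixed = TRUE)
  n_arrows <- sum(strsplit(norm, "", fixed = TRUE)[[1]] == sep)
  if (n_arrows != 1L)
    fm_stop("malformed_equation",
            sprintf("equation '%s' (%s): expected exactly one arrow, found %d",
                    text, name, n_arrows))
  sides <- strsplit(norm, sep, fixed = TRUE)[[1]]
  if (length(sides) < 2L) sides <- c(sides, "")

  eq <- structure(
    list(name = name,
         reactants = parse_equation_side(sides[[1]], "reactant", text, name),
         products  = parse_equation_side(sides[[2]], "product", text, name)),
    class = "reaction_equation")
  eq
}

parse_equation_side <- function(side, role, text, name) {
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L)
    fm_stop("malformed_equation",
            sprintf("equation '%s' (%s): empty %s side", text, name, role))
  labels <- character(length(terms))
  stoich <- numeric(length(terms))
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$"
  for (i in seq_along(terms)) {
    toks <- strsplit(terms[[i]], "[[:space:]]+")[[1]]
    first <- toks[[1]]
    if (length(toks) >= 2L && grepl(num_re, first)) {
      s <- as.numeric(first)
      if (!is.finite(s) || s <= 0)
        fm_stop("malformed_equation",
                sprintf("equation '%s' (%s): stoichiometry '%s' must be > 0",
                        text, name, first))
      labels[i] <- paste(toks[-1], collapse = " ")
      stoich[i] <- s
    } else {
      if (length(toks) >= 2L && grepl(",", first, fixed = TRUE) &&
          grepl("^[+-]?[0-9][0-9,]*\\.?[0-9]*$", first))
        fm_stop("malformed_equation",
                sprintf(paste0("equation '%s' (%s): '%s' looks like a number ",
                               "with a thousands separator; use '.' decimals ",
                               "and no grouping"), text, name, first))
      labels[i] <- paste(toks, collapse = " ")
      stoich[i] <- 1
    }
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    fm_stop("duplicate_reactant",
            sprintf("equation '%s' (%s): label(s) %s repeated on the %s side",
                    text, name, paste(sQuote(dup), collapse = ", "), role),
            labels = dup)
  data.frame(label = labels, stoichiometry = stoich, stringsAsFactors = FALSE)
}

#' Deparse a reaction equation back to template text
#'
#' Inverse of [parse_reaction_equation()]: stoichiometries of 1 are omitted,
#' others printed with full double precision so write/parse round trips are
#' exact.
#'
#' @param eq A `reaction_equation`.
#' @return A single string such as `"2 Suc -> Fru + Glc"`.
#' @export
deparse_reaction_equation <- function(eq) {
  stopifnot(inherits(eq, "reaction_equation"))
  side <- function(df) {
    paste(ifelse(df$stoichiometry == 1, df$label,
                 paste(fm_num(df$stoichiometry), df$label)),
          collapse = " + ")
  }
  paste(side(eq$reactants), "->", side(eq$products))
}

# shortest plain-decimal (never exponent) representation that round-trips a double
fm_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in 1:17) {
      s <- sub("\\.$", "", formatC(v, digits = d, format = "fg", flag = "#"))
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 22, format = "fg")
  }, character(1))
}

#' @export
print.reaction_equation <- function(x, ...) {
  cat(sprintf("<reaction_equation> %s: %s\n", x$name,
              deparse_reaction_equation(x)))
  invisible(x)
}

#' @export
format.reaction_equation <- function(x, ...) deparse_reaction_equation(x)

# all metabolite labels appearing in an equation (both sides, deduplicated)
equation_labels <- function(eq) unique(c(eq$reactants$label, eq$products$label))
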