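# Atom selection grammar.
#
#   expr    := term { "or" term }
#   term    := factor { "and" factor }
#   factor  := "not" factor | "(" expr ")" | primary
#   primary := "name" value+ | "resname" value+ | "element" value+
#            | "chain" value+ | "resid" ranges
#            | "protein" | "water" | "ion" | "hydrogen" | "backbone" | "all"
#   ranges  := (number | number "to" number)+
#
# Matching on name/resname/element/chain is case-insensitive.

#' Select atoms by expression
#'
#' Evaluates a small selection grammar against a topology and returns the
#' matching atom indices (1-based, strictly increasing). Keywords: `name`,
#' `resname`, `element`, `chain`, `resid` (with `a to b` ranges), and the
#' bare classes `protein`, `water`, `ion`, `hydrogen`, `backbone`, `all`,
#' combined with `and`, `or`, `not` and parentheses.
#'
#' @param top A [topology()].
#' @param expr Selection string, e.g. `"protein and not hydrogen"`,
#'   `"resid 35 to 145"`, `"water and name OH2"`.
#' @param label Optional label stored on the selection.
#' @return An integer vector of class `"selection"`; empty selections are
#'   returned, not errors.
#' @export
#' @examples
#' top <- topology(data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
#'                            resname = "GLY", resid = 1))
#' select_atoms(top, "backbone and not name CA")
select_atoms <- function(top, expr, label = expr) {
  toks <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, top)
  if (st$pos <= nrow(st$toks)) {
    sel_syntax_error(st, "unexpected trailing input")
  }
  new_selection(which(mask), label)
}

new_selection <- function(idx, label = "") {
  structure(as.integer(idx), label = label, class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("# selection \"%s\": %d atoms\n", attr(x, "label"), length(x)))
  if (length(x)) print(as.integer(x))
  invisible(x)
}

#' @export
`[.selection` <- function(x, i) new_selection(as.integer(unclass(x))[i], attr(x, "label"))

tokenize_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr))) {
    abort("selection expression must be a non-empty string")
  }
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1L]]
  if (m[1L] == -1L) abort("selection expression must be a non-empty string")
  tibble(
    text = regmatches(expr, gregexpr(pat, expr, perl = TRUE))[[1L]],
    at = as.integer(m)
  )
}

peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks$text[st$pos - 1L] }

sel_syntax_error <- function(st, msg) {
  at <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else NA_integer_
  tok <- peek(st)
  abort(sprintf(
    "selection syntax error at position %s (near \"%s\"): %s",
    ifelse(is.na(at), "end", at), ifelse(is.na(tok), "<end>", tok), msg
  ))
}

parse_or <- function(st, top) {
  m <- parse_and(st, top)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    m <- m | parse_and(st, top)
  }
  m
}

parse_and <- function(st, top) {
  m <- parse_factor(st, top)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    m <- m & parse_factor(st, top)
  }
  m
}

parse_factor <- function(st, top) {
  tok <- peek(st)
  if (is.na(tok)) sel_syntax_error(st, "expected a selection term")
  if (tolower(tok) == "not") {
    advance(st)
    return(!parse_factor(st, top))
  }
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, top)
    if (is.na(peek(st)) || peek(st) != ")") sel_syntax_error(st, "expected \")\"")
    advance(st)
    return(m)
  }
  parse_primary(st, top)
}

stop_words <- c("and", "or", "not", ")", "(")

collect_values <- function(st) {
  vals <- character()
  while (!is.na(peek(st)) && !(tolower(peek(st)) %in% stop_words)) {
    vals <- c(vals, advance(st))
  }
  if (length(vals) == 0L) sel_syntax_error(st, "keyword needs at least one value")
  vals
}

parse_primary <- function(st, top) {
  key <- tolower(advance(st))
  switch(
    key,
    all = rep(TRUE, nrow(top)),
    protein = toupper(top$resname) %in% protein_resnames(),
    water = top$is_water,
    ion = top$is_ion,
    hydrogen = top$is_hydrogen,
    backbone = toupper(top$resname) %in% protein_resnames() &
      toupper(top$name) %in% backbone_names(),
    name = toupper(top$name) %in% toupper(collect_values(st)),
    resname = toupper(top$resname) %in% toupper(collect_values(st)),
    element = toupper(top$element) %in% toupper(collect_values(st)),
    chain = toupper(top$chain) %in% toupper(collect_values(st)),
    resid = top$resid %in% parse_resid_values(st),
    { st$pos <- st$pos - 1L; sel_syntax_error(st, "unknown keyword") }
  )
}

parse_resid_values <- function(st) {
  vals <- collect_values(st)
  out <- integer()
  i <- 1L
  while (i <= length(vals)) {
    a <- suppressWarnings(as.integer(vals[i]))
    if (is.na(a)) {
      st$pos <- st$pos - (length(vals) - i + 1L)
      sel_syntax_error(st, "resid expects integers or \"a to b\" ranges")
    }
    if (i + 2L <= length(vals) && tolower(vals[i + 1L]) == "to") {
      b <- suppressWarnings(as.integer(vals[i + 2L]))
      if (is.na(b)) {
        st$pos <- st$pos - (length(vals) - i - 1L)
        sel_syntax_error(st, "resid range needs an integer after \"to\"")
      }
      out <- c(out, a:b)
      i <- i + 3L
    } else {
      out <- c(out, a)
      i <- i + 1L
    }
  }
  out
}
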