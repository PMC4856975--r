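#' Selection query language
#'
#' Boolean combinations of regular expressions over sequence labels and
#' the aligned sequence strings, plus exact residue-at-position tests.
#' Grammar (keywords case-insensitive; AND binds tighter than OR):
#'
#' ```
#' expr   := term ('OR' term)*
#' term   := factor ('AND' factor)*
#' factor := 'NOT' factor | '(' expr ')' | atom
#' atom   := 'label' '~' /regex/
#'         | 'seq'   '~' [degap:]/regex/
#'         | 'site' '(' int ')' '=' symbol
#' ```
#'
#' Regexes are unanchored searches (write `^...$` to anchor). `seq`
#' matches the full aligned row including gap characters; the `degap:`
#' flag matches against the row with gaps removed. `site(i) = X` tests
#' exact symbol equality at 1-based column i.
#'
#' @param text Query string.
#' @return A `query_ast` (nested list of nodes).
#' @examples
#' ast <- parse_query("label ~ /Ciona/ AND site(241) = M")
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    bk_stop("syntax_error", "empty query")
  toks <- tokenize_query(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- parse_expr(st)
  if (st$pos <= length(st$toks))
    qerr(st, "unexpected input after end of query")
  ast
}

qnode <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "query_ast")
}

# --- tokenizer ------------------------------------------------------------

tokenize_query <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, at) toks[[length(toks) + 1L]] <<-
    list(type = type, value = value, at = at)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == "~") { push("TILDE", "~", i); i <- i + 1L; next }
    if (ch == "=") { push("EQ", "=", i); i <- i + 1L; next }
    if (ch == "/") {                      # /regex/ with \/ escape
      j <- i + 1L
      buf <- character()
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\" && j < n && substr(text, j + 1L, j + 1L) == "/") {
          buf <- c(buf, "/"); j <- j + 2L
        } else if (cj == "/") { closed <- TRUE; break
        } else { buf <- c(buf, cj); j <- j + 1L }
      }
      if (!closed)
        bk_stop("syntax_error", "unterminated /regex/ starting at position %d", i)
      push("REGEX", paste(buf, collapse = ""), i)
      i <- j + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n),
                            perl = TRUE))
    if (length(m) && nzchar(m)) {
      word <- m
      up <- toupper(word)
      type <- switch(up, AND = "AND", OR = "OR", NOT = "NOT",
                     LABEL = "LABEL", SEQ = "SEQ", SITE = "SITE", "WORD")
      push(type, word, i)
      i <- i + nchar(word)
      next
    }
    bk_stop("syntax_error", "unexpected character '%s' at position %d", ch, i)
  }
  toks
}

# --- recursive-descent parser ---------------------------------------------

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }
qerr <- function(st, msg) {
  t <- peek(st)
  at <- if (is.null(t)) "end of query" else sprintf("position %d", t$at)
  bk_stop("syntax_error", "%s at %s", msg, at)
}
expect <- function(st, type, what) {
  t <- peek(st)
  if (is.null(t) || t$type != type) qerr(st, sprintf("expected %s", what))
  advance(st)
}

parse_expr <- function(st) {
  terms <- list(parse_term(st))
  while (!is.null(t <- peek(st)) && t$type == "OR") {
    advance(st)
    terms[[length(terms) + 1L]] <- parse_term(st)
  }
  if (length(terms) == 1L) terms[[1]] else qnode("OR", children = terms)
}

parse_term <- function(st) {
  factors <- list(parse_factor(st))
  while (!is.null(t <- peek(st)) && t$type == "AND") {
    advance(st)
    factors[[length(factors) + 1L]] <- parse_factor(st)
  }
  if (length(factors) == 1L) factors[[1]] else qnode("AND", children = factors)
}

parse_factor <- function(st) {
  t <- peek(st)
  if (is.null(t)) qerr(st, "expected expression")
  if (t$type == "NOT") {
    advance(st)
    return(qnode("NOT", children = list(parse_factor(st))))
  }
  if (t$type == "LPAREN") {
    advance(st)
    e <- parse_expr(st)
    expect(st, "RPAREN", "')'")
    return(e)
  }
  parse_atom(st)
}

parse_atom <- function(st) {
  t <- peek(st)
  if (is.null(t)) qerr(st, "expected atom")
  if (t$type %in% c("LABEL", "SEQ")) {
    advance(st)
    expect(st, "TILDE", "'~' after label/seq")
    degap <- FALSE
    rt <- peek(st)
    if (!is.null(rt) && rt$type == "WORD" &&
        tolower(rt$value) %in% c("degap:", "degap")) {
      if (t$type != "SEQ") qerr(st, "degap: applies only to seq")
      degap <- TRUE
      advance(st)
    }
    r <- expect(st, "REGEX", "/regex/")
    check_regex(r$value, r$at)
    return(qnode(if (t$type == "LABEL") "LABEL_MATCH" else "SEQ_MATCH",
                 pattern = r$value, degap = degap))
  }
  if (t$type == "SITE") {
    advance(st)
    expect(st, "LPAREN", "'(' after site")
    it <- expect(st, "WORD", "column index")
    if (!grepl("^[0-9]+$", it$value))
      bk_stop("syntax_error", "site index must be an integer at position %d",
              it$at)
    expect(st, "RPAREN", "')'")
    expect(st, "EQ", "'='")
    sy <- expect(st, "WORD", "symbol")
    if (nchar(sy$value) != 1L)
      bk_stop("syntax_error", "site symbol must be one character at position %d",
              sy$at)
    return(qnode("SITE_EQ", col = as.integer(it$value),
                 symbol = toupper(sy$value)))
  }
  qerr(st, sprintf("unexpected token '%s'", t$value))
}

check_regex <- function(pattern, at) {
  ok <- tryCatch({ grepl(pattern, "x", perl = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    bk_stop("syntax_error", "invalid regular expression /%s/ at position %d",
            pattern, at)
  invisible(TRUE)
}

#' Evaluate a query against an MSA
#'
#' Returns the set of sequences satisfying the boolean expression. Label
#' matching is case-sensitive; sequence matching operates on the stored
#' (upper-cased) rows, gaps included unless the atom carries `degap:`.
#' Queries select sequences only; site selection is a direct API
#' ([selection()]).
#'
#' @param ast A `query_ast` from [parse_query()] (a plain query string is
#'   also accepted and parsed first).
#' @param x An `msa`.
#' @return A `bk_selection` with `seq_indices` set, `site_indices` empty.
#' @export
evaluate_query <- function(ast, x) {
  if (is.character(ast)) ast <- parse_query(ast)
  mask <- eval_node(ast, x)
  selection(which(mask), integer(), msa = x)
}

eval_node <- function(node, x) {
  switch(node$kind,
    AND = Reduce(`&`, lapply(node$children, eval_node, x = x)),
    OR  = Reduce(`|`, lapply(node$children, eval_node, x = x)),
    NOT = !eval_node(node$children[[1]], x),
    LABEL_MATCH = grepl(node$pattern, x$labels, perl = TRUE),
    SEQ_MATCH = {
      subj <- if (isTRUE(node$degap))
        gsub(x$alphabet$gap_symbol, "", x$rows, fixed = TRUE) else x$rows
      grepl(node$pattern, subj, perl = TRUE)
    },
    SITE_EQ = {
      col <- check_col(x, node$col)
      substr(x$rows, col, col) == node$symbol
    },
    bk_stop("syntax_error", "unknown query node kind '%s'", node$kind))
}
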