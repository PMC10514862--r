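# Safe infix equation language for pixelwise signal models.
#
# Grammar (whitespace insignificant):
#   expr    := term (('+'|'-') term)*
#   term    := unary (('*'|'/') unary)*
#   unary   := '-' unary | primary
#   primary := number | symbol | fn '(' expr ')' | '(' expr ')'
#   fn      := 'exp' | 'abs'
#
# Only the whitelisted functions are callable: an identifier followed by '('
# that is not on the whitelist is rejected, so configuration files can never
# invoke arbitrary R functions.

EQ_FUNCTIONS <- c("exp", "abs")

ast_const <- function(value) structure(list(kind = "const", value = as.numeric(value)), class = "eq_ast")
ast_sym   <- function(name)  structure(list(kind = "sym", name = name), class = "eq_ast")
ast_call  <- function(fn, arg) structure(list(kind = "call", fn = fn, arg = arg), class = "eq_ast")
ast_neg   <- function(arg)   structure(list(kind = "neg", arg = arg), class = "eq_ast")
ast_bin   <- function(op, lhs, rhs) structure(list(kind = "bin", op = op, lhs = lhs, rhs = rhs), class = "eq_ast")

eq_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^[ \t\r\n]$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("+", "-", "*", "/", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = "op", value = ch, pos = i)
      i <- i + 1L
    } else if (grepl("^[0-9.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9.]$", chars[[j]])) j <- j + 1L
      num <- paste(chars[i:(j - 1L)], collapse = "")
      if (!grepl("^([0-9]+\\.?[0-9]*|\\.[0-9]+)$", num)) {
        stop(eq_syntax_error(sprintf("malformed number '%s'", num), i, text))
      }
      tokens[[length(tokens) + 1L]] <- list(type = "num", value = as.numeric(num), pos = i)
      i <- j
    } else if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", chars[[j]])) j <- j + 1L
      tokens[[length(tokens) + 1L]] <-
        list(type = "ident", value = paste(chars[i:(j - 1L)], collapse = ""), pos = i)
      i <- j
    } else if (ch %in% c("'", "\"")) {
      # tokenize string literals so the parser can reject them (or the
      # enclosing non-whitelisted call) with a precise message
      j <- i + 1L
      while (j <= n && chars[[j]] != ch) j <- j + 1L
      if (j > n) stop(eq_syntax_error("unterminated string literal", i, text))
      tokens[[length(tokens) + 1L]] <-
        list(type = "str", value = paste(chars[i:j], collapse = ""), pos = i)
      i <- j + 1L
    } else {
      stop(eq_syntax_error(sprintf("unexpected character '%s'", ch), i, text))
    }
  }
  tokens
}

eq_syntax_error <- function(msg, pos, text) {
  structure(
    class = c("mrisynth_syntax_error", "error", "condition"),
    list(message = sprintf("equation syntax error at position %d: %s (in \"%s\")", pos, msg, text),
         call = NULL, position = pos)
  )
}

#' Parse a signal-model equation
#'
#' Parses an infix equation string (for example
#' `"PD*(1-exp(-TR/T1))"`) into an abstract syntax tree. The language is
#' deliberately minimal and safe: decimal constants, identifiers, binary
#' `+ - * /`, unary minus, parentheses, and the whitelisted functions `exp`
#' and `abs` only. Any other function name is rejected, so equations coming
#' from configuration files cannot call arbitrary code.
#'
#' @param text Equation as a single character string.
#' @return An object of class `eq_ast`.
#' @seealso [free_symbols()], [deparse_equation()], [evaluate_model()]
#' @examples
#' ast <- parse_equation("PD*(1-exp(-TR/T1))")
#' free_symbols(ast)
#' @export
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(trimws(text))) stop(eq_syntax_error("empty equation", 1L, text))
  tokens <- eq_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L
  state$text <- text

  peek <- function() if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
  advance <- function() { tok <- peek(); state$i <- state$i + 1L; tok }
  expect_op <- function(op) {
    tok <- peek()
    if (is.null(tok) || tok$type != "op" || tok$value != op) {
      pos <- if (is.null(tok)) nchar(state$text) + 1L else tok$pos
      stop(eq_syntax_error(sprintf("expected '%s'", op), pos, state$text))
    }
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    repeat {
      tok <- peek()
      if (!is.null(tok) && tok$type == "op" && tok$value %in% c("+", "-")) {
        advance()
        node <- ast_bin(tok$value, node, parse_term())
      } else break
    }
    node
  }
  parse_term <- function() {
    node <- parse_unary()
    repeat {
      tok <- peek()
      if (!is.null(tok) && tok$type == "op" && tok$value %in% c("*", "/")) {
        advance()
        node <- ast_bin(tok$value, node, parse_unary())
      } else break
    }
    node
  }
  parse_unary <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "op" && tok$value == "-") {
      advance()
      return(ast_neg(parse_unary()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) {
      stop(eq_syntax_error("unexpected end of input", nchar(state$text) + 1L, state$text))
    }
    if (tok$type == "num") { advance(); return(ast_const(tok$value)) }
    if (tok$type == "ident") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "op" && nxt$value == "(") {
        if (!tok$value %in% EQ_FUNCTIONS) {
          stop(eq_syntax_error(
            sprintf("unknown function '%s' (allowed: %s)", tok$value,
                    paste(EQ_FUNCTIONS, collapse = ", ")),
            tok$pos, state$text))
        }
        advance()
        arg <- parse_expr()
        expect_op(")")
        return(ast_call(tok$value, arg))
      }
      return(ast_sym(tok$value))
    }
    if (tok$type == "op" && tok$value == "(") {
      advance()
      node <- parse_expr()
      expect_op(")")
      return(node)
    }
    if (tok$type == "str") {
      stop(eq_syntax_error("string literals are not supported", tok$pos, state$text))
    }
    stop(eq_syntax_error(sprintf("unexpected '%s'", tok$value), tok$pos, state$text))
  }

  node <- parse_expr()
  tok <- peek()
  if (!is.null(tok)) {
    stop(eq_syntax_error(sprintf("unexpected trailing '%s'", tok$value), tok$pos, state$text))
  }
  node
}

#' Free symbols of an equation
#'
#' Returns the sorted set of identifiers appearing in a parsed equation —
#' the union of map symbols and scanner-parameter symbols it references.
#'
#' @param ast An `eq_ast` from [parse_equation()].
#' @return Character vector of unique symbol names (sorted, C locale).
#' @export
free_symbols <- function(ast) {
  stopifnot(inherits(ast, "eq_ast"))
  walk <- function(node) {
    switch(node$kind,
      const = character(),
      sym   = node$name,
      call  = walk(node$arg),
      neg   = walk(node$arg),
      bin   = c(walk(node$lhs), walk(node$rhs)))
  }
  sort(unique(walk(ast)), method = "radix")
}

eq_precedence <- function(node) {
  switch(node$kind, bin = if (node$op %in% c("+", "-")) 1L else 2L, neg = 3L, 4L)
}

#' Serialize an equation AST back to infix text
#'
#' The output reparses to a structurally identical tree
#' (`parse_equation(deparse_equation(ast))` is the identity on ASTs).
#'
#' @param ast An `eq_ast`.
#' @return A single equation string.
#' @export
deparse_equation <- function(ast) {
  stopifnot(inherits(ast, "eq_ast"))
  fmt_num <- function(x) {
    if (is.finite(x) && x == round(x) && abs(x) < 1e15) {
      format(x, scientific = FALSE, trim = TRUE)
    } else {
      format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }
  }
  walk <- function(node) {
    switch(node$kind,
      const = fmt_num(node$value),
      sym   = node$name,
      call  = paste0(node$fn, "(", walk(node$arg), ")"),
      neg   = {
        inner <- walk(node$arg)
        if (node$arg$kind == "bin") paste0("-(", inner, ")") else paste0("-", inner)
      },
      bin   = {
        p <- eq_precedence(node)
        lhs <- walk(node$lhs)
        rhs <- walk(node$rhs)
        if (eq_precedence(node$lhs) < p) lhs <- paste0("(", lhs, ")")
        # right child needs parens at equal precedence too: '-' and '/' are
        # left-associative, and a bare unary minus on the right is ambiguous
        if (eq_precedence(node$rhs) <= p) rhs <- paste0("(", rhs, ")")
        paste0(lhs, node$op, rhs)
      })
  }
  walk(ast)
}

# Evaluate an AST over a named environment of numeric arrays/scalars.
# Arithmetic is R-vectorized, so passing full 3D arrays evaluates the whole
# volume in one pass.
eval_ast <- function(ast, env) {
  walk <- function(node) {
    switch(node$kind,
      const = node$value,
      sym   = {
        v <- env[[node$name]]
        if (is.null(v)) stop(sprintf("equation references unknown symbol '%s'", node$name), call. = FALSE)
        v
      },
      call  = switch(node$fn, exp = exp(walk(node$arg)), abs = abs(walk(node$arg))),
      neg   = -walk(node$arg),
      bin   = switch(node$op,
        "+" = walk(node$lhs) + walk(node$rhs),
        "-" = walk(node$lhs) - walk(node$rhs),
        "*" = walk(node$lhs) * walk(node$rhs),
        "/" = walk(node$lhs) / walk(node$rhs)))
  }
  walk(ast)
}

#' @export
print.eq_ast <- function(x, ...) {
  cat("<equation> ", deparse_equation(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.eq_ast <- function(x, ...) deparse_equation(x)
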