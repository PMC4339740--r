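#' Finite fields GF(q) for small orders
#'
#' Constructs the arithmetic tables of the Galois field GF(q) for the orders
#' used by the outer barcode codes, `q` in \{2, 3, 4, 5, 7, 8, 9\}. Prime
#' fields use modular arithmetic; the extension fields GF(4), GF(8) and GF(9)
#' are built from fixed irreducible polynomials (x^2+x+1, x^3+x+1 and x^2+1
#' respectively) so that tables are identical across calls and platforms.
#'
#' Field elements are represented as integers `0 .. q-1`. For extension
#' fields of characteristic p the integer packs the polynomial coefficients
#' in base p, the constant term being the least significant digit.
#'
#' @param q field order; one of 2, 3, 4, 5, 7, 8, 9.
#' @return an object of class `galois_field`: a list with elements `q`,
#'   `p` (characteristic), `m` (extension degree), `poly` (irreducible
#'   polynomial coefficients, constant first; `NULL` for prime fields),
#'   `add` and `mul` (q x q tables over elements 0..q-1), `neg` and `inv`
#'   (length-q lookup vectors; `inv[1]`, the inverse of 0, is `NA`).
#' @examples
#' F8 <- galois_field(8)
#' F8$mul[2 + 1, 3 + 1]   # product of elements 2 and 3 in GF(8)
#' @export
galois_field <- function(q) {
  if (length(q) != 1L || !is.numeric(q) || q != as.integer(q)) {
    stop("field order must be a single integer")
  }
  q <- as.integer(q)
  fs <- .gf_specs[[as.character(q)]]
  if (is.null(fs)) {
    stop("unsupported field order ", q,
         "; supported orders are 2, 3, 4, 5, 7, 8, 9")
  }
  p <- fs$p
  m <- fs$m
  if (m == 1L) {
    el <- 0:(q - 1L)
    add <- outer(el, el, function(a, b) (a + b) %% q)
    mul <- outer(el, el, function(a, b) (a * b) %% q)
  } else {
    coeffs <- .gf_int_to_poly(0:(q - 1L), p, m)        # q x m matrix
    add <- matrix(0L, q, q)
    mul <- matrix(0L, q, q)
    for (a in 0:(q - 1L)) {
      for (b in 0:(q - 1L)) {
        add[a + 1L, b + 1L] <- .gf_poly_to_int((coeffs[a + 1L, ] + coeffs[b + 1L, ]) %% p, p)
        pr <- .gf_poly_mul(coeffs[a + 1L, ], coeffs[b + 1L, ], p, fs$poly)
        mul[a + 1L, b + 1L] <- .gf_poly_to_int(pr, p)
      }
    }
  }
  storage.mode(add) <- "integer"
  storage.mode(mul) <- "integer"
  neg <- vapply(0:(q - 1L), function(a) which(add[a + 1L, ] == 0L) - 1L, integer(1))
  inv <- c(NA_integer_,
           vapply(1:(q - 1L), function(a) which(mul[a + 1L, ] == 1L) - 1L, integer(1)))
  structure(list(q = q, p = p, m = m, poly = fs$poly,
                 add = add, mul = mul, neg = neg, inv = inv),
            class = "galois_field")
}

# canonical irreducible polynomials, coefficients constant-term first
.gf_specs <- list(
  "2" = list(p = 2L, m = 1L, poly = NULL),
  "3" = list(p = 3L, m = 1L, poly = NULL),
  "4" = list(p = 2L, m = 2L, poly = c(1L, 1L, 1L)),   # x^2 + x + 1
  "5" = list(p = 5L, m = 1L, poly = NULL),
  "7" = list(p = 7L, m = 1L, poly = NULL),
  "8" = list(p = 2L, m = 3L, poly = c(1L, 1L, 0L, 1L)), # x^3 + x + 1
  "9" = list(p = 3L, m = 2L, poly = c(1L, 0L, 1L))      # x^2 + 1
)

.gf_int_to_poly <- function(x, p, m) {
  out <- matrix(0L, length(x), m)
  for (i in seq_len(m)) {
    out[, i] <- x %% p
    x <- x %/% p
  }
  out
}

.gf_poly_to_int <- function(coef, p) {
  as.integer(sum(coef * p^(seq_along(coef) - 1L)))
}

# multiply two polynomials over GF(p), reduce modulo the irreducible `mod`
.gf_poly_mul <- function(a, b, p, mod) {
  m <- length(a)
  prod <- rep(0L, 2L * m - 1L)
  for (i in seq_len(m)) {
    if (a[i] != 0L) {
      idx <- i:(i + m - 1L)
      prod[idx] <- (prod[idx] + a[i] * b) %% p
    }
  }
  # reduction: mod has degree m with leading coefficient 1
  for (d in (2L * m - 1L):(m + 1L)) {
    lead <- prod[d]
    if (lead != 0L) {
      idx <- (d - m):(d)
      prod[idx] <- (prod[idx] - lead * mod) %% p
      prod[d] <- 0L
    }
  }
  prod[seq_len(m)]
}

#' Elementwise finite-field operations
#'
#' Table-lookup arithmetic in a field built by [galois_field()]. `add` and
#' `mul` take two element vectors (recycled); `neg` and `inv` take one.
#'
#' @param field a `galois_field` object.
#' @param op one of `"add"`, `"mul"`, `"neg"`, `"inv"`.
#' @param a,b element vectors with values in `0 .. q-1` (`b` ignored for
#'   unary operations). `inv` requires all `a != 0`.
#' @return integer vector of results.
#' @export
ff_op <- function(field, op = c("add", "mul", "neg", "inv"), a, b = NULL) {
  stopifnot(inherits(field, "galois_field"))
  op <- match.arg(op)
  q <- field$q
  .chk <- function(x, nm) {
    if (any(x != as.integer(x)) || any(x < 0L) || any(x >= q)) {
      stop(nm, " contains elements outside 0..", q - 1L)
    }
    as.integer(x)
  }
  a <- .chk(a, "a")
  if (op %in% c("add", "mul")) {
    if (is.null(b)) stop("binary operation '", op, "' needs b")
    b <- .chk(b, "b")
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    tab <- if (op == "add") field$add else field$mul
    return(tab[cbind(a + 1L, b + 1L)])
  }
  if (op == "neg") return(field$neg[a + 1L])
  if (any(a == 0L)) stop("inv(0) is undefined")
  field$inv[a + 1L]
}

#' @export
print.galois_field <- function(x, ...) {
  cat("GF(", x$q, ")", sep = "")
  if (x$m > 1L) {
    cat(" = GF(", x$p, "^", x$m, "), irreducible polynomial coefficients (",
        paste(x$poly, collapse = ", "), ") [constant first]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# a . G over the field: message matrix (rows = messages, k columns) times
# generator matrix G (k x n); returns (nrow(msg) x n) codeword matrix
.ff_matmul <- function(field, msg, G) {
  k <- ncol(msg)
  n <- ncol(G)
  out <- matrix(0L, nrow(msg), n)
  for (i in seq_len(k)) {
    gi <- G[i, ]
    term <- field$mul[cbind(rep(msg[, i], times = n) + 1L,
                            rep(gi, each = nrow(msg)) + 1L)]
    out <- matrix(field$add[cbind(as.vector(out) + 1L, term + 1L)],
                  nrow(msg), n)
  }
  out
}
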