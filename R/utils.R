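# Internal helpers: validation, seeded RNG scopes, stable string hashing.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  `seed = NULL` leaves the global stream
# untouched (results then depend on the ambient RNG state).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over a string, reduced to a valid set.seed() value.
# Used to derive independent, order-invariant RNG streams per subnetwork id.
hash32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # (h * p) mod 2^32 via 16-bit split; doubles stay below 2^53 throughout
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Seed for a named substream of `seed`; always < 2^31.
derive_seed <- function(seed, id) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + as.double(hash32(id))) %% 2147483647)
}

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite values", name),
         call. = FALSE)
  }
  invisible(x)
}

check_square_symmetric <- function(x, name = deparse(substitute(x)),
                                   tol = 1e-10) {
  stopifnot_matrix(x, name)
  if (nrow(x) != ncol(x)) {
    stop(sprintf("'%s' must be square", name), call. = FALSE)
  }
  if (max(abs(x - t(x))) > tol) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
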