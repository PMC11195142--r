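# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream (the caller's .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

check_rate <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("maturation efficiency `r` must be a single finite number",
         call. = FALSE)
  if (r <= 0)
    stop("maturation efficiency `r` must be > 0 (got ", format(r), ")",
         call. = FALSE)
  if (r > 1)
    stop("maturation efficiency `r` must be <= 1 (got ", format(r), ")",
         call. = FALSE)
  invisible(r)
}

# Validate a point on the 2-simplex; returns it renormalized exactly.
check_simplex <- function(q, tol = 1e-6) {
  if (!is.numeric(q) || length(q) != 3L || anyNA(q))
    stop("`q` must be a numeric vector of three probabilities", call. = FALSE)
  if (any(q < 0) || any(q > 1))
    stop("`q` entries must lie in [0, 1]", call. = FALSE)
  if (abs(sum(q) - 1) > tol)
    stop("`q` must sum to 1 (got ", format(sum(q)), ")", call. = FALSE)
  q <- q / sum(q)
  names(q) <- c("monomer", "dimer", "oligomer")
  q
}

check_count_vector <- function(n) {
  if (!is.numeric(n) || length(n) != 3L || anyNA(n))
    stop("step counts must be three numbers (n1, n2, n3)", call. = FALSE)
  if (any(n < 0))
    stop("step counts must be non-negative", call. = FALSE)
  if (any(n != round(n)))
    stop("step counts must be whole numbers", call. = FALSE)
  as.integer(round(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
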