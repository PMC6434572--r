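# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Harmonic number
#'
#' Sum of 1/i for i = 1..k, the normalising constant of the
#' Benjamini-Yekutieli threshold.
#'
#' @param k positive integer.
#' @return numeric scalar.
#' @keywords internal
harmonic_number <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  sum(1 / seq_len(k))
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a master seed and a stage label,
# kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

# Dirichlet draws, one row per sample.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  rs <- rowSums(x)
  # Guard against all-zero rows when alpha is tiny: fall back to a point
  # mass on the component with the largest gamma draw.
  zero <- rs == 0
  if (any(zero)) {
    for (i in which(zero)) {
      x[i, ] <- 0
      x[i, which.max(alpha)] <- 1
    }
    rs[zero] <- 1
  }
  x / rs
}

# Probability that an allele with n_a copies out of t is absent from a
# hypergeometric subsample of m copies.
hyper_absent_prob <- function(n_a, t, m) {
  exp(lchoose(t - n_a, m) - lchoose(t, m))
}

check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix", call. = FALSE)
  bad <- which(abs(m - t(m)) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    lab <- if (!is.null(rownames(m))) paste(rownames(m)[i], rownames(m)[j])
           else paste(i, j)
    stop(name, " is not symmetric (first offending pair: ", lab, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Permutation p-value convention used throughout: (b + 1) / (B + 1),
# never exactly zero.
perm_pvalue <- function(b, n_perm) (b + 1) / (n_perm + 1)
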