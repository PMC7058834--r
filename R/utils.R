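# Internal numerical helpers.

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(sum_i s_i * exp(l_i)) for signs s_i in {-1, +1}.  The quantities combined
# here are sums over variant assignments, which are non-negative by
# construction; a total driven below zero by floating-point cancellation is
# clamped to zero mass (-Inf).
signed_logsumexp <- function(l, s) {
  keep <- is.finite(l)
  if (!any(keep)) return(-Inf)
  l <- l[keep]
  s <- s[keep]
  m <- max(l)
  tot <- sum(s * exp(l - m))
  if (tot <= 0) return(-Inf)
  m + log(tot)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
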