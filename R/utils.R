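# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive `n` reproducible child seeds (< 2^31) from one parent seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal draws by rejection; bounds may be infinite.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Bivariate normal draws with given marginals and correlation (Cholesky).
rbvnorm <- function(n, mean = c(0, 0), sd = c(1, 1), rho = 0) {
  stopifnot(abs(rho) < 1, all(sd >= 0))
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(mean[1] + sd[1] * z1, mean[2] + sd[2] * z2)
}

stop_if_not_df <- function(data, cols, what = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(data)
}

cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)
  stats::sd(x) / abs(m)
}
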