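# Internal helpers: seeding substreams and count distributions.

#' @keywords internal
#' @noRd
.stable_hash <- function(x) {
  # deterministic 31-bit hash of a character scalar (platform independent)
  bytes <- as.integer(charToRaw(as.character(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

#' @keywords internal
#' @noRd
.substream_seed <- function(master_seed, key) {
  # per-unit substream so subsetting a design never reshuffles other units
  as.integer((as.numeric(master_seed) * 48271 + .stable_hash(key)) %% 2147483647)
}

#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Zero-truncated negative binomial, parameterised by its *conditional* mean
# so that multiplicative effects on the conditional mean are exact.

#' @keywords internal
#' @noRd
.ztnb_mu_for_mean <- function(target_mean, size) {
  stopifnot(target_mean > 1)
  f <- function(mu) mu / (1 - dnbinom(0, size = size, mu = mu)) - target_mean
  uniroot(f, lower = 1e-8, upper = target_mean * 2, tol = 1e-12)$root
}

#' @keywords internal
#' @noRd
.rztnb_mean <- function(n, target_mean, size) {
  if (n == 0L) return(integer(0))
  mu <- vapply(unique(target_mean), .ztnb_mu_for_mean, numeric(1), size = size)
  names(mu) <- as.character(unique(target_mean))
  mu_vec <- mu[as.character(target_mean)]
  p0 <- dnbinom(0, size = size, mu = mu_vec)
  u <- runif(n, min = p0, max = 1)
  qnbinom(u, size = size, mu = mu_vec)
}

#' @keywords internal
#' @noRd
.assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
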