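# internal helpers

# evaluate expr with a temporary RNG state seeded from `seed`; restores the
# caller's RNG afterwards so library code never disturbs user randomness
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds below 2^31, derived from a master seed
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(index)) %% 2147483647)
}

# draw from a multivariate Gaussian via Cholesky (jittered if near-singular)
rmvn <- function(k, mean, sigma) {
  p <- length(mean)
  if (p == 0) return(matrix(0, k, 0))
  R <- tryCatch(chol(sigma),
                error = function(e) chol(sigma + diag(1e-10, p)))
  z <- matrix(stats::rnorm(k * p), k, p)
  sweep(z %*% R, 2, mean, "+")
}

logDet <- function(M) {
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0) stop("matrix must have positive determinant")
  as.numeric(d$modulus)
}

# md5 of the canonical JSON serialization, for provenance blocks
configHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

provenance <- function(seed = NULL, config = NULL) {
  list(package = "tdcsdcm",
       version = as.character(utils::packageVersion("tdcsdcm")),
       seed = seed,
       configHash = if (!is.null(config)) configHash(config) else NULL,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
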