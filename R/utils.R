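# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# run expr with a local RNG state so fixture generation never disturbs the
# caller's random stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

pairwise_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

# are all points collinear (within tol)?
points_collinear <- function(xyz, tol = 1e-8) {
  if (nrow(xyz) <= 2L) return(TRUE)
  x0 <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(x0, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}
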