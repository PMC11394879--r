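#' @keywords internal
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coords_matrix <- function(x) {
  m <- as.matrix(x[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mcdpa <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mcdpa_error")))
}
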