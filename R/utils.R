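#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package functions do not perturb the
#' user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Add a length-k vector to every row of an n x k matrix.
add_row <- function(M, v) M + matrix(v, nrow = nrow(M), ncol = length(v), byrow = TRUE)

#' Energy distance between two point clouds
#'
#' Two-sample energy distance
#' \eqn{2 E\|A-B\| - E\|A-A'\| - E\|B-B'\|} computed from pairwise
#' Euclidean distances. Nonnegative, symmetric, and zero when the two
#' clouds coincide; used to quantify agreement between generated and
#' observed records in the low-dimensional QC embedding.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @return a nonnegative scalar.
#' @export
energy_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must have the same number of columns")
  n <- nrow(A); m <- nrow(B)
  if (n < 1 || m < 1) stop("both clouds must be nonempty")
  D <- as.matrix(stats::dist(rbind(A, B)))
  dab <- mean(D[seq_len(n), n + seq_len(m), drop = FALSE])
  daa <- mean(D[seq_len(n), seq_len(n), drop = FALSE])
  dbb <- mean(D[n + seq_len(m), n + seq_len(m), drop = FALSE])
  max(2 * dab - daa - dbb, 0)
}
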