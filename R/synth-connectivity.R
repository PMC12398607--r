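#' Generate a stack of per-iteration streamline-count matrices
#'
#' Emulates the iteration-to-iteration fluctuation of probabilistic
#' tractography counts: each iteration is an independent symmetric
#' negative-binomial draw around `mean_matrix` (variance
#' `mu + dispersion * mu^2`), so the stack average converges to
#' `mean_matrix` as iterations grow. `dispersion = 0` is the degenerate
#' noise-free limit: every iteration equals `mean_matrix` exactly.
#'
#' @param n_iterations Number of iterations (default 50).
#' @param mean_matrix Labelled square symmetric non-negative matrix with a
#'   zero diagonal.
#' @param dispersion Non-negative overdispersion parameter.
#' @param seed Integer seed.
#' @return List of `n_iterations` labelled matrices.
#' @export
generate_connectivity_stack <- function(n_iterations = 50L, mean_matrix,
                                        dispersion = 0.02, seed = 1L) {
  stopifnot(n_iterations >= 1L, dispersion >= 0)
  check_conn_matrix(mean_matrix, label = "mean_matrix")
  if (dispersion == 0) {
    return(replicate(n_iterations, mean_matrix, simplify = FALSE))
  }
  ut <- upper.tri(mean_matrix)
  mu <- mean_matrix[ut]
  withr::with_seed(seed, {
    lapply(seq_len(n_iterations), function(k) {
      m <- mean_matrix
      draws <- ifelse(mu > 0,
                      rnbinom(length(mu), size = 1 / dispersion, mu = mu), 0)
      m[ut] <- draws
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
  })
}
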