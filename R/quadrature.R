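#' Gauss-Hermite quadrature for a standard-normal latent variable
#'
#' Returns nodes and weights such that \eqn{\sum_k w_k f(x_k) \approx
#' E[f(Z)]} for \eqn{Z \sim N(0,1)}. Physicists' Gauss-Hermite nodes are
#' rescaled by \eqn{\sqrt 2} and the weights normalized to sum to one, so
#' the rule is exact for polynomial moments up to degree \code{2 * order - 1}.
#'
#' @param order number of quadrature nodes (positive integer).
#' @return list with components \code{nodes} and \code{weights}, each of
#'   length \code{order}; weights sum to 1.
#' @examples
#' q <- gh_quadrature(15)
#' sum(q$weights)                  # 1
#' sum(q$weights * q$nodes^2)      # Var(Z) = 1
#' @export
gh_quadrature <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("'order' must be a positive integer")
  }
  if (order == 1) return(list(nodes = 0, weights = 1))
  gh <- pracma::gaussHermite(as.integer(order))
  nodes <- gh$x * sqrt(2)
  weights <- gh$w / sqrt(pi)
  ## guard against accumulated floating error in the tails
  weights <- weights / sum(weights)
  list(nodes = nodes, weights = weights)
}
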