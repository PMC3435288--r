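## Exact first-passage (visit) probabilities for the absorbing chain: the
## ground truth against which the Monte-Carlo estimates are validated.

#' Exact probability of ever visiting a destination before absorption
#'
#' Solves the standard first-passage system for a substochastic chain: with
#' destination d, \eqn{h_i = p_{id} + \sum_{k \ne d} p_{ik} h_k}. Because
#' every row sum of a valid transmission matrix is strictly below 1 the
#' spectral radius of the substochastic block is below 1 and the system is
#' non-singular. The destination's own entry is returned as 1 (a walk
#' starting there trivially is there); Monte-Carlo arrival rates exclude
#' the origin by convention, so comparisons apply to i != d.
#'
#' @param P a [TransmissionMatrix-class].
#' @param destination destination port id.
#' @return named numeric vector of visit probabilities over all ports.
#' @examples
#' ka <- knownAnswerCase("chain3")
#' visitProbability(ka$P, "Z")  # h(X -> Z) = 0.25, h(Y -> Z) = 0.5
#' @export
visitProbability <- function(P, destination) {
  stopifnot(is(P, "TransmissionMatrix"))
  d <- match(destination, P@ports)
  if (is.na(d)) stop("destination '", destination, "' is not a network node",
                     call. = FALSE)
  n <- length(P@ports)
  if (n == 1) return(setNames(1, P@ports))
  Q <- P@rates[-d, -d, drop = FALSE]
  b <- P@rates[-d, d]
  h <- solve(diag(nrow(Q)) - Q, b)
  out <- numeric(n)
  out[-d] <- h
  out[d] <- 1
  setNames(out, P@ports)
}

#' All-pairs visit probabilities via the fundamental matrix
#'
#' Computes \eqn{N = (I - P)^{-1}} (expected visit counts of the absorbing
#' chain) and applies the renewal identity \eqn{h_{ij} = N_{ij} / N_{jj}}
#' for i != j: a single dense solve instead of one linear system per
#' destination. Agrees with [visitProbability()] column by column.
#'
#' @param P a [TransmissionMatrix-class].
#' @return numeric matrix of visit probabilities, diagonal 1.
#' @export
visitProbabilityMatrix <- function(P) {
  stopifnot(is(P, "TransmissionMatrix"))
  n <- length(P@ports)
  N <- solve(diag(n) - P@rates)
  h <- sweep(N, 2, diag(N), "/")
  diag(h) <- 1
  dimnames(h) <- list(P@ports, P@ports)
  h
}

#' Visit probability by truncated path enumeration
#'
#' Independent cross-check of the linear-algebra oracle: accumulates the
#' probability mass of all pathways of at most `maxLen` steps that first
#' reach the destination, by depth iteration over the path tree
#' (\eqn{h^{(L)}_i = p_{id} + \sum_{k \ne d} p_{ik} h^{(L-1)}_k}). The
#' truncation error is geometrically bounded: the mass of walks still alive
#' after L steps is at most \eqn{s^L} with s the largest row sum, returned
#' as `tailBound`. On acyclic networks the enumeration is exact once
#' `maxLen` exceeds the longest path.
#'
#' @param P a [TransmissionMatrix-class].
#' @param destination destination port id.
#' @param maxLen maximum pathway length enumerated.
#' @return list with `h` (named lower-bound probabilities, destination entry
#'   1) and `tailBound` (upper bound on the un-enumerated mass).
#' @export
visitProbabilityByEnumeration <- function(P, destination, maxLen = 20L) {
  stopifnot(is(P, "TransmissionMatrix"))
  d <- match(destination, P@ports)
  if (is.na(d)) stop("destination '", destination, "' is not a network node",
                     call. = FALSE)
  n <- length(P@ports)
  b <- P@rates[, d]
  Q <- P@rates
  Q[, d] <- 0  # pathways stop on first arrival at the destination
  h <- numeric(n)
  for (l in seq_len(maxLen)) h <- b + as.vector(Q %*% h)
  h[d] <- 1
  s <- max(rowSums(P@rates))
  list(h = setNames(h, P@ports), tailBound = s^maxLen)
}
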