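## Route decomposition, segment counting, transmission-matrix assembly and
## degree centrality: the network half of the pathway model.

#' Decompose a voyage into ordered origin-destination segments
#'
#' A container loaded at any call of a voyage may stay aboard and alight at
#' any later call, so a route A-B-C-D carries transmission potential over
#' AB, AC, AD, BC, BD and CD: every ordered pair (i, j) with i called
#' strictly before j. Each unique pair is reported once per voyage,
#' however many call-position pairs realize it, and self-pairs (a revisited
#' port) are excluded.
#'
#' @param calls character vector of port ids, earliest call first.
#' @return data.frame with columns `from`, `to`; zero rows (with a warning)
#'   for routes shorter than two calls.
#' @examples
#' decomposeRoute(c("A", "B", "C", "D"))
#' @export
decomposeRoute <- function(calls) {
  if (length(calls) < 2) {
    warning("route with fewer than 2 calls decomposes to no segments")
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  L <- length(calls)
  a <- rep(seq_len(L - 1), times = (L - 1):1)
  b <- unlist(lapply(seq_len(L - 1), function(i) (i + 1):L))
  from <- calls[a]; to <- calls[b]
  keep <- from != to
  pairs <- unique(data.frame(from = from[keep], to = to[keep],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

#' Count vessels per ordered segment across all voyages
#'
#' Builds the segment-count matrix \eqn{m_{ij}}: the number of voyages whose
#' decomposition contains the ordered pair (i, j). The node set is exactly
#' the set of ports observed on the routes; registry-only ports carry no
#' traffic and are excluded. With `mode = "unique"` (default) a voyage
#' contributes at most 1 to any \eqn{m_{ij}} -- segment counts are numbers
#' of vessels, not call-position pairs; `mode = "positional"` counts every
#' qualifying position pair, for comparison.
#'
#' @param routes voyage collection from [readRoutes()] (or any data.frame
#'   with a `calls` list-column).
#' @param mode `"unique"` or `"positional"`.
#' @param period optional label of the pooled survey period.
#' @return a [SegmentCounts-class].
#' @export
countSegments <- function(routes, mode = c("unique", "positional"), period = NULL) {
  mode <- match.arg(mode)
  if (nrow(routes) == 0) stop("no routes to count", call. = FALSE)
  allPorts <- sort(unique(unlist(routes$calls)))
  n <- length(allPorts)
  m <- matrix(0L, n, n, dimnames = list(allPorts, allPorts))
  pairCache <- list()
  for (calls in routes$calls) {
    L <- length(calls)
    if (L < 2) next
    ck <- as.character(L)
    if (is.null(pairCache[[ck]])) {
      a <- rep(seq_len(L - 1), times = (L - 1):1)
      b <- unlist(lapply(seq_len(L - 1), function(i) (i + 1):L))
      pairCache[[ck]] <- cbind(a, b)
    }
    pr <- pairCache[[ck]]
    idx <- match(calls, allPorts)
    from <- idx[pr[, 1]]; to <- idx[pr[, 2]]
    keep <- from != to
    lin <- (to[keep] - 1L) * n + from[keep]  # column-major linear index
    if (mode == "unique") lin <- unique(lin)
    tab <- tabulate(match(lin, unique(lin)))
    ulin <- unique(lin)
    m[ulin] <- m[ulin] + tab
  }
  new("SegmentCounts", ports = allPorts, counts = m,
      period = if (is.null(period)) NA_character_ else period)
}

#' Rescale segment counts into a transmission matrix with absorption
#'
#' The per-segment transmission rate is \eqn{p_{ij} = \lambda_t m_{ij}},
#' with the scaling coefficient chosen as \eqn{\lambda_t = c / \max_i
#' \sum_j m_{ij}} so that the largest row sum equals `cap` and every row
#' satisfies \eqn{\sum_j p_{ij} < 1}. The terminal column is
#' \eqn{p_{i,Y+1} = 1 - \sum_j p_{ij}} (probability the organism does not
#' survive transit onward from i); rows with no outgoing traffic absorb
#' with probability 1. Because lambda multiplies every element linearly,
#' its exact value does not affect the partial order of arrival rates --
#' only row-sum admissibility matters -- so `cap` is a reproducibility
#' device, not a biological parameter.
#'
#' @param counts a [SegmentCounts-class].
#' @param cap target maximum row sum, in (0, 1). Default 0.9 keeps
#'   absorption strictly positive everywhere.
#' @return a [TransmissionMatrix-class].
#' @export
buildTransmission <- function(counts, cap = 0.9) {
  stopifnot(is(counts, "SegmentCounts"))
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0 || cap >= 1)
    stop("cap must be a single number in (0, 1)", call. = FALSE)
  rs <- rowSums(counts@counts)
  if (max(rs) == 0) stop("all-zero count matrix: no network", call. = FALSE)
  lam <- cap / max(rs)
  rates <- counts@counts * lam
  new("TransmissionMatrix", ports = counts@ports, rates = rates,
      absorption = 1 - rowSums(rates), lam = lam, cap = cap)
}

#' Degree centrality: total ship arrivals plus departures per port
#'
#' Each interior call of a voyage is one arrival plus one departure; the
#' first call of a voyage is a departure only and the last an arrival only,
#' so every leg contributes exactly one arrival and one departure and the
#' centralities sum to `2 * (total legs)`.
#'
#' @param routes voyage collection.
#' @return named integer vector (all observed ports, decreasing order).
#' @export
degreeCentrality <- function(routes) {
  allPorts <- sort(unique(unlist(routes$calls)))
  deg <- setNames(integer(length(allPorts)), allPorts)
  for (calls in routes$calls) {
    idx <- match(calls, allPorts)
    add <- rep(2L, length(idx))
    add[1] <- add[1] - 1L
    add[length(idx)] <- add[length(idx)] - 1L
    agg <- rowsum(add, idx)
    deg[as.integer(rownames(agg))] <- deg[as.integer(rownames(agg))] + agg[, 1]
  }
  sort(deg, decreasing = TRUE)
}
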