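## Monte-Carlo pathway simulation: repeated stochastic walks from each
## origin port until absorption, tallied into arrival-rate estimates.

## Compressed sparse-row view of the rate matrix for the compiled walker.
.rowStructure <- function(rates) {
  n <- nrow(rates)
  idxs <- vector("list", n)
  cums <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rates[i, ]
    nz <- which(r > 0)
    idxs[[i]] <- nz - 1L
    cums[[i]] <- cumsum(r[nz])
  }
  list(ptr = c(0L, cumsum(lengths(idxs))),
       idx = as.integer(unlist(idxs, use.names = FALSE)),
       cum = as.numeric(unlist(cums, use.names = FALSE)))
}

## Deterministic per-(seed, origin) substream seed: a Lehmer step on the base
## seed mixed with a polynomial hash of the port id, reduced mod 2^31 - 2.
## Results are therefore reproducible and independent of origin order.
.substreamSeed <- function(seed, originId) {
  M <- 2147483647
  s <- (as.numeric(seed) %% M) * 48271 %% M
  h <- 0
  for (ch in utf8ToInt(originId)) h <- (h * 31 + ch) %% M
  as.integer((s + h) %% (M - 1) + 1)
}

#' Simulate a single pathway walk
#'
#' Starts at `origin` and repeatedly draws the next state from the current
#' row's categorical distribution over destinations plus the terminal
#' state. The walk ends on a terminal draw, on reaching a port with no
#' outgoing rates, or after `maxSteps` transitions. Intended for
#' inspection and small-scale checks; [estimateArrivalRates()] runs the
#' compiled bulk equivalent.
#'
#' @param P a [TransmissionMatrix-class].
#' @param origin origin port id (must be a network node).
#' @param maxSteps hard cap on walk length.
#' @return character vector of visited port ids, in order, excluding the
#'   origin's initial position (revisits included).
#' @export
simulateWalk <- function(P, origin, maxSteps = 10000L) {
  stopifnot(is(P, "TransmissionMatrix"))
  cur <- match(origin, P@ports)
  if (is.na(cur)) stop("origin '", origin, "' is not a network node", call. = FALSE)
  visited <- character()
  for (step in seq_len(maxSteps)) {
    r <- P@rates[cur, ]
    nz <- which(r > 0)
    if (length(nz) == 0) break
    cum <- cumsum(r[nz])
    u <- runif(1)
    if (u >= cum[length(cum)]) break
    cur <- nz[which(u < cum)[1]]
    visited <- c(visited, P@ports[cur])
  }
  visited
}

#' Estimate arrival rates by Monte-Carlo pathway simulation
#'
#' For each origin port, `K` independent walks are simulated through the
#' transmission matrix and the fraction reaching each destination port
#' estimates the arrival rate \eqn{\hat\varphi_{ij} = J_{ij}/K}. Under the
#' default first-visit counting a realization contributes at most once per
#' destination. Each origin draws from its own RNG substream derived
#' deterministically from `(seed, origin)`, so estimates are bit-reproducible
#' and independent of the order (or subsetting) of origins.
#'
#' The default `K` is the study-scale 2e6 realizations per origin; scale it
#' down for exploratory runs.
#'
#' @param P a [TransmissionMatrix-class].
#' @param origins character vector of origin port ids (non-empty subset of
#'   the network nodes).
#' @param K walks per origin.
#' @param seed base seed for the per-origin substreams.
#' @param maxSteps hard cap on walk length. With row sums capped at 0.9 the
#'   probability of a walk exceeding the default 10000 steps is below
#'   0.9^10000; a truncated walk keeps the visits it made.
#' @param countMode `"firstVisit"` (default) or `"visits"`.
#' @return an [ArrivalRates-class].
#' @export
estimateArrivalRates <- function(P, origins, K = 2e6, seed = 1L,
                                 maxSteps = 10000L,
                                 countMode = c("firstVisit", "visits")) {
  stopifnot(is(P, "TransmissionMatrix"))
  countMode <- match.arg(countMode)
  if (length(origins) == 0) stop("origins must be non-empty", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K < 1)
    stop("K must be a positive integer", call. = FALSE)
  K <- as.integer(K)
  bad <- setdiff(origins, P@ports)
  if (length(bad))
    stop("origin(s) not in the network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rs <- .rowStructure(P@rates)
  n <- length(P@ports)
  J <- matrix(0L, length(origins), n, dimnames = list(origins, P@ports))
  for (i in seq_along(origins)) {
    o0 <- match(origins[i], P@ports) - 1L
    set.seed(.substreamSeed(seed, origins[i]))
    J[i, ] <- .walk_origin_counts(rs$ptr, rs$idx, rs$cum, o0, K,
                                  as.integer(maxSteps), n,
                                  countMode == "firstVisit")
  }
  new("ArrivalRates", origins = as.character(origins),
      destinations = P@ports, J = J, K = K, countMode = countMode,
      seed = as.integer(seed))
}
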