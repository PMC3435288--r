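## Aggregation of per-pair arrival rates into per-port and per-country
## overall rates, relative rates and rankings.

#' Combine per-source arrival rates into an overall rate
#'
#' Aggregates a set of independent per-pathway arrival rates as the
#' probability that at least one source delivers:
#' \deqn{\Phi = 1 - \prod (1 - \varphi).}
#' The complementary product is bounded by `max(phi) <= Phi <= min(1,
#' sum(phi))`, reduces to the sum in the small-rate limit, is
#' permutation-invariant and monotone in every argument, and keeps the
#' result in \[0, 1\] -- properties a raw product or raw sum of rates both
#' lack. Computed via `log1p` for accuracy with many small rates.
#'
#' @param phi numeric vector of arrival rates, each in \[0, 1\]; an empty
#'   vector combines to 0.
#' @return single combined rate in \[0, 1\].
#' @examples
#' combineRates(c(0.245, 0.227))  # 1 - 0.755 * 0.773 = 0.41645
#' @export
combineRates <- function(phi) {
  if (length(phi) == 0) return(0)
  if (anyNA(phi) || any(phi < 0) || any(phi > 1))
    stop("arrival rates must lie in [0, 1]", call. = FALSE)
  -expm1(sum(log1p(-phi)))
}

## Shared ranking assembly: descending phi, lexicographic entity-id
## tie-break, mean over the full entity set.
.makeRanking <- function(ids, phi, kind) {
  mp <- mean(phi)
  ord <- order(-phi, ids, method = "radix")
  tb <- data.frame(entity_id = ids[ord], phi = phi[ord],
                   relative_phi = phi[ord] / mp,
                   rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("RankingTable", entityKind = kind, table = tb, meanPhi = mp)
}

#' Rank domestic ports by overall arrival rate
#'
#' For each domestic (destination-country) port j, the overall rate is the
#' complementary product of the arrival rates from every origin:
#' `combineRates(phi[, j])`. Relative rates divide by the mean over the
#' full domestic-port set, so they average to 1.
#'
#' @param ar an [ArrivalRates-class].
#' @param registry port registry from [readPorts()].
#' @return a [RankingTable-class] with `entityKind = "domestic_port"`.
#' @export
rankDomesticPorts <- function(ar, registry) {
  stopifnot(is(ar, "ArrivalRates"))
  dom <- intersect(ar@destinations,
                   registry$port_id[registry$is_domestic])
  if (length(dom) == 0)
    stop("no domestic ports on the network", call. = FALSE)
  phi <- arrivalPhi(ar)
  overall <- vapply(dom, function(j) combineRates(phi[, j]), numeric(1))
  .makeRanking(dom, unname(overall), "domestic_port")
}

#' Rank foreign origin ports by overall arrival rate to all domestic ports
#'
#' Mirror of [rankDomesticPorts()]: for each origin i, the overall rate
#' combines i's arrival rates across every domestic destination.
#'
#' @inheritParams rankDomesticPorts
#' @return a [RankingTable-class] with `entityKind = "foreign_port"`.
#' @export
rankForeignPorts <- function(ar, registry) {
  stopifnot(is(ar, "ArrivalRates"))
  dom <- intersect(ar@destinations,
                   registry$port_id[registry$is_domestic])
  if (length(dom) == 0)
    stop("no domestic ports on the network", call. = FALSE)
  phi <- arrivalPhi(ar)[, dom, drop = FALSE]
  overall <- vapply(seq_along(ar@origins),
                    function(i) combineRates(phi[i, ]), numeric(1))
  .makeRanking(ar@origins, overall, "foreign_port")
}

#' Rank source countries
#'
#' A country's rate combines the per-port overall rates of its origin
#' ports with the same complementary product used within ports, then
#' countries are ranked and normalized like ports.
#'
#' @inheritParams rankDomesticPorts
#' @return a [RankingTable-class] with `entityKind = "foreign_country"`.
#' @export
rankCountries <- function(ar, registry) {
  fp <- rankForeignPorts(ar, registry)
  tb <- rankingData(fp)
  country <- registry$country[match(tb$entity_id, registry$port_id)]
  rates <- split(tb$phi, country)
  overall <- vapply(rates, combineRates, numeric(1))
  .makeRanking(names(overall), unname(overall), "foreign_country")
}

#' Per-destination breakdown of origins (port-by-port tables)
#'
#' For each domestic port, lists every origin's arrival rate in rank
#' order. Following the convention of the published port-by-port tables,
#' all panels share a single relative-rate denominator: the mean of
#' \eqn{\varphi_{ij}} over all origin x domestic-destination pairs.
#'
#' @inheritParams rankDomesticPorts
#' @return named list (one data.frame per domestic port) with columns
#'   `origin`, `phi`, `relative_phi`, `rank`; the shared mean is attached
#'   as attribute `meanPhi`.
#' @export
portByPortBreakdown <- function(ar, registry) {
  stopifnot(is(ar, "ArrivalRates"))
  dom <- intersect(ar@destinations,
                   registry$port_id[registry$is_domestic])
  if (length(dom) == 0)
    stop("no domestic ports on the network", call. = FALSE)
  phi <- arrivalPhi(ar)[, dom, drop = FALSE]
  mp <- mean(phi)
  out <- lapply(dom, function(j) {
    v <- phi[, j]
    ord <- order(-v, ar@origins, method = "radix")
    df <- data.frame(origin = ar@origins[ord], phi = unname(v[ord]),
                     relative_phi = unname(v[ord]) / mp,
                     rank = seq_along(ord), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
  names(out) <- dom
  attr(out, "meanPhi") <- mp
  out
}
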