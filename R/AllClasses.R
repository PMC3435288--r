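## Central S4 containers: segment counts, transmission matrix, arrival rates,
## ranking tables. Everything downstream consumes these.

#' SegmentCounts: vessel counts per ordered port pair
#'
#' A directed, integer-valued matrix whose entry \eqn{m_{ij}} is the number
#' of voyages whose route called at port i strictly before port j. The node
#' set is the set of ports observed on at least one route (registry-only
#' ports are excluded). The diagonal is structurally zero: the data carry no
#' information on within-port container movement.
#'
#' @slot ports character vector of port identifiers (row/column order).
#' @slot counts integer matrix of segment counts, `dimnames` equal to `ports`.
#' @slot period label of the pooled survey period the counts refer to.
#'
#' @seealso [countSegments()], [buildTransmission()]
#' @export
setClass("SegmentCounts",
  representation(ports = "character", counts = "matrix", period = "character"),
  prototype(period = NA_character_)
)

setValidity("SegmentCounts", function(object) {
  msg <- character()
  m <- object@counts
  if (!is.numeric(m)) msg <- c(msg, "counts must be a numeric/integer matrix")
  if (nrow(m) != length(object@ports) || ncol(m) != length(object@ports))
    msg <- c(msg, "counts dimensions must match length(ports)")
  if (anyDuplicated(object@ports)) msg <- c(msg, "duplicated port ids")
  if (length(msg) == 0) {
    if (any(m < 0)) msg <- c(msg, "negative segment counts")
    if (any(m != round(m))) msg <- c(msg, "non-integer segment counts")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal of counts must be zero")
    if (!identical(rownames(m), object@ports) ||
        !identical(colnames(m), object@ports))
      msg <- c(msg, "dimnames of counts must equal ports")
  }
  if (length(msg)) msg else TRUE
})

#' TransmissionMatrix: scaled per-segment transmission rates with absorption
#'
#' Substochastic one-step matrix of an absorbing Markov chain over ports.
#' Rates are \eqn{p_{ij} = \lambda_t m_{ij}}, with \eqn{\lambda_t} chosen so
#' the largest row sum equals `cap` (< 1); the implicit terminal column
#' \eqn{p_{i,Y+1} = 1 - \sum_j p_{ij}} is stored in `absorption` and models
#' the organism not surviving transit beyond port i. Row sums of `rates`
#' plus `absorption` equal 1 to within 1e-12.
#'
#' @slot ports character vector of port identifiers.
#' @slot rates numeric matrix of transmission rates \eqn{p_{ij}}.
#' @slot absorption numeric vector, terminal-state rate per origin row.
#' @slot lam the scaling coefficient \eqn{\lambda_t} applied to the counts
#'   (NA when the matrix was built directly from rates).
#' @slot cap the row-sum cap used to select \eqn{\lambda_t}.
#'
#' @seealso [buildTransmission()], [estimateArrivalRates()], [visitProbability()]
#' @export
setClass("TransmissionMatrix",
  representation(ports = "character", rates = "matrix",
                 absorption = "numeric", lam = "numeric", cap = "numeric"),
  prototype(lam = NA_real_, cap = NA_real_)
)

.closure_tol <- 1e-12

setValidity("TransmissionMatrix", function(object) {
  msg <- character()
  p <- object@rates
  n <- length(object@ports)
  if (nrow(p) != n || ncol(p) != n) msg <- c(msg, "rates dimensions must match ports")
  if (length(object@absorption) != n) msg <- c(msg, "absorption length must match ports")
  if (length(msg) == 0) {
    if (any(p < 0) || any(p > 1)) msg <- c(msg, "rates must lie in [0, 1]")
    if (any(diag(p) != 0)) msg <- c(msg, "diagonal of rates must be zero")
    rs <- rowSums(p)
    if (any(rs >= 1)) msg <- c(msg, "every row sum of rates must be < 1")
    if (any(abs(rs + object@absorption - 1) > .closure_tol))
      msg <- c(msg, "rates row sum + absorption must equal 1 (tol 1e-12)")
    if (!identical(rownames(p), object@ports) || !identical(colnames(p), object@ports))
      msg <- c(msg, "dimnames of rates must equal ports")
  }
  if (length(msg)) msg else TRUE
})

#' ArrivalRates: Monte-Carlo arrival-rate estimates
#'
#' For each origin port i (a port inside the organism's known range) and
#' every network port j, `J[i, j]` counts the realizations (out of `K`
#' walks started at i) that reached j, and \eqn{\hat\varphi_{ij} = J_{ij}/K}
#' estimates the arrival rate. With `countMode = "firstVisit"` (the default)
#' a realization contributes at most once per destination, so
#' \eqn{\varphi_{ij} \le 1} is a per-pathway arrival probability;
#' `"visits"` counts every arrival event.
#'
#' @slot origins character, origin port ids (rows of `J`).
#' @slot destinations character, all network port ids (columns of `J`).
#' @slot J integer matrix of arrival counts.
#' @slot K integer, walks per origin.
#' @slot countMode `"firstVisit"` or `"visits"`.
#' @slot seed base seed the per-origin substreams were derived from.
#'
#' @seealso [estimateArrivalRates()], [arrivalPhi()]
#' @export
setClass("ArrivalRates",
  representation(origins = "character", destinations = "character",
                 J = "matrix", K = "integer", countMode = "character",
                 seed = "integer"),
  prototype(countMode = "firstVisit", seed = NA_integer_)
)

setValidity("ArrivalRates", function(object) {
  msg <- character()
  J <- object@J
  if (nrow(J) != length(object@origins) || ncol(J) != length(object@destinations))
    msg <- c(msg, "J dimensions must match origins x destinations")
  if (length(object@K) != 1 || is.na(object@K) || object@K < 1)
    msg <- c(msg, "K must be a single positive integer")
  if (!object@countMode %in% c("firstVisit", "visits"))
    msg <- c(msg, "countMode must be 'firstVisit' or 'visits'")
  if (length(msg) == 0) {
    if (any(J < 0) || any(J != round(J))) msg <- c(msg, "J must be non-negative integers")
    if (object@countMode == "firstVisit" && any(J > object@K))
      msg <- c(msg, "first-visit counts cannot exceed K")
  }
  if (length(msg)) msg else TRUE
})

#' RankingTable: aggregated arrival rates, relative rates and ranks
#'
#' One row per entity (domestic port, foreign port, or foreign country)
#' with the combined arrival rate `phi`, the relative rate
#' `phi / meanPhi`, and an integer rank (1 = highest rate; ties broken
#' lexicographically by entity id). `meanPhi` is the mean of `phi` over the
#' full entity set of the ranking, so relative rates average to 1.
#'
#' @slot entityKind `"domestic_port"`, `"foreign_port"` or `"foreign_country"`.
#' @slot table data.frame with columns `entity_id`, `phi`, `relative_phi`, `rank`.
#' @slot meanPhi the denominator used for relative rates.
#'
#' @seealso [rankDomesticPorts()], [rankForeignPorts()], [rankCountries()]
#' @export
setClass("RankingTable",
  representation(entityKind = "character", table = "data.frame",
                 meanPhi = "numeric")
)

setValidity("RankingTable", function(object) {
  msg <- character()
  if (!object@entityKind %in% c("domestic_port", "foreign_port", "foreign_country"))
    msg <- c(msg, "unknown entityKind")
  tb <- object@table
  need <- c("entity_id", "phi", "relative_phi", "rank")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  if (length(msg) == 0 && nrow(tb) > 0) {
    if (!identical(sort(tb$rank), as.numeric(seq_len(nrow(tb)))) &&
        !identical(sort(tb$rank), seq_len(nrow(tb))))
      msg <- c(msg, "ranks must be 1..n without gaps")
    if (is.unsorted(tb$rank)) msg <- c(msg, "rows must be sorted by rank")
    if (any(diff(tb$phi) > 1e-15)) msg <- c(msg, "rows must be sorted by descending phi")
    if (any(abs(tb$relative_phi - tb$phi / object@meanPhi) > 1e-9))
      msg <- c(msg, "relative_phi must equal phi / meanPhi")
  }
  if (length(msg)) msg else TRUE
})
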