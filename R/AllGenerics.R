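#' Accessors for the pathway-model containers
#'
#' @param x a SegmentCounts, TransmissionMatrix, ArrivalRates or RankingTable.
#' @return `ports()` the node set; `segmentCounts()` the integer count matrix;
#'   `transmissionRates()` the rate matrix; `absorptionRates()` the terminal
#'   column; `scalingCoefficient()` the lambda used to rescale counts;
#'   `arrivalJ()` / `arrivalK()` the raw Monte-Carlo counts and walks per
#'   origin; `arrivalPhi()` the estimated rates J/K; `rankingData()` the
#'   ranking as a data.frame; `meanPhi()` the relative-rate denominator;
#'   `entityKind()` which entities the ranking covers.
#'
#' @name accessors
#' @aliases ports segmentCounts transmissionRates absorptionRates
#'   scalingCoefficient arrivalJ arrivalK arrivalPhi rankingData meanPhi
#'   entityKind
NULL

#' @rdname accessors
#' @export
setGeneric("ports", function(x) standardGeneric("ports"))
#' @rdname accessors
#' @export
setGeneric("segmentCounts", function(x) standardGeneric("segmentCounts"))
#' @rdname accessors
#' @export
setGeneric("transmissionRates", function(x) standardGeneric("transmissionRates"))
#' @rdname accessors
#' @export
setGeneric("absorptionRates", function(x) standardGeneric("absorptionRates"))
#' @rdname accessors
#' @export
setGeneric("scalingCoefficient", function(x) standardGeneric("scalingCoefficient"))
#' @rdname accessors
#' @export
setGeneric("arrivalJ", function(x) standardGeneric("arrivalJ"))
#' @rdname accessors
#' @export
setGeneric("arrivalK", function(x) standardGeneric("arrivalK"))
#' @rdname accessors
#' @export
setGeneric("arrivalPhi", function(x) standardGeneric("arrivalPhi"))
#' @rdname accessors
#' @export
setGeneric("rankingData", function(x) standardGeneric("rankingData"))
#' @rdname accessors
#' @export
setGeneric("meanPhi", function(x) standardGeneric("meanPhi"))
#' @rdname accessors
#' @export
setGeneric("entityKind", function(x) standardGeneric("entityKind"))

#' @rdname accessors
setMethod("ports", "SegmentCounts", function(x) x@ports)
#' @rdname accessors
setMethod("ports", "TransmissionMatrix", function(x) x@ports)
#' @rdname accessors
setMethod("segmentCounts", "SegmentCounts", function(x) x@counts)
#' @rdname accessors
setMethod("transmissionRates", "TransmissionMatrix", function(x) x@rates)
#' @rdname accessors
setMethod("absorptionRates", "TransmissionMatrix", function(x) x@absorption)
#' @rdname accessors
setMethod("scalingCoefficient", "TransmissionMatrix", function(x) x@lam)
#' @rdname accessors
setMethod("arrivalJ", "ArrivalRates", function(x) x@J)
#' @rdname accessors
setMethod("arrivalK", "ArrivalRates", function(x) x@K)
#' @rdname accessors
setMethod("arrivalPhi", "ArrivalRates", function(x) x@J / x@K)
#' @rdname accessors
setMethod("rankingData", "RankingTable", function(x) x@table)
#' @rdname accessors
setMethod("meanPhi", "RankingTable", function(x) x@meanPhi)
#' @rdname accessors
setMethod("entityKind", "RankingTable", function(x) x@entityKind)

setMethod("show", "SegmentCounts", function(object) {
  cat("SegmentCounts:", length(object@ports), "ports,",
      sum(object@counts > 0), "directed segments,",
      sum(object@counts), "segment traversals",
      if (!is.na(object@period)) paste0("(period ", object@period, ")"), "\n")
})

setMethod("show", "TransmissionMatrix", function(object) {
  rs <- rowSums(object@rates)
  cat("TransmissionMatrix:", length(object@ports), "ports,",
      sum(object@rates > 0), "positive rates\n")
  cat(sprintf("  lambda = %s, max row sum = %.6g, min absorption = %.6g\n",
              format(object@lam), max(rs), min(object@absorption)))
})

setMethod("show", "ArrivalRates", function(object) {
  cat("ArrivalRates:", length(object@origins), "origins x",
      length(object@destinations), "destinations, K =", object@K,
      paste0("(", object@countMode, " counting)"), "\n")
})

setMethod("show", "RankingTable", function(object) {
  cat("RankingTable (", object@entityKind, "): ", nrow(object@table),
      " entities, mean phi = ", format(object@meanPhi, digits = 4), "\n", sep = "")
  print(head(object@table, 5), row.names = FALSE)
  if (nrow(object@table) > 5) cat("  ...", nrow(object@table) - 5, "more rows\n")
})
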