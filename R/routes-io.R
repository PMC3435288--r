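## Fixed CSV dialect for route histories, port registries, pest ranges and
## ranking outputs. All readers validate into the domain representations the
## rest of the pipeline consumes.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a port registry
#'
#' Expects a CSV with header `port_id,name,country,is_domestic`
#' (`is_domestic` coded 0/1; domestic ports are the destination-country
#' ports of entry). Port ids must be unique and countries non-empty.
#'
#' @param path path to `ports.csv`.
#' @return data.frame with columns `port_id`, `name`, `country`,
#'   `is_domestic` (logical).
#' @export
readPorts <- function(path) {
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  .require_columns(df, c("port_id", "name", "country", "is_domestic"), path)
  if (anyDuplicated(df$port_id))
    stop("validation error: duplicated port_id in registry: ",
         paste(unique(df$port_id[duplicated(df$port_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$country)))
    stop("validation error: empty country code for port(s) ",
         paste(df$port_id[!nzchar(df$country)], collapse = ", "), call. = FALSE)
  if (!all(df$is_domestic %in% c("0", "1")))
    stop("format error: is_domestic must be 0 or 1", call. = FALSE)
  df$is_domestic <- df$is_domestic == "1"
  df
}

#' Read vessel route histories
#'
#' One CSV row per port call, header
#' `ship_id,voyage_id,seq,port_id,arrival_date`. Rows are grouped into
#' voyages by `(ship_id, voyage_id)` and ordered by the `seq` call number
#' (file order is irrelevant). The final call of each voyage is its
#' destination. Consecutive duplicate calls within a voyage are collapsed
#' with a warning (a ship cannot make a zero-length leg), and voyages with
#' fewer than two distinct consecutive calls are dropped with a warning.
#'
#' @param path path to `routes.csv`.
#' @param registry port registry from [readPorts()]; every `port_id` in the
#'   file must resolve in it.
#' @param requireDomesticDestination if TRUE, error unless every voyage ends
#'   at a registry port flagged domestic (the convention of
#'   arrival-conditioned vessel-movement extracts).
#' @param maxCalls truncation limit on calls per voyage (destination plus
#'   prior ports of call); NULL disables the check. Default 11 = ten prior
#'   calls plus the destination.
#' @param dateWindow optional length-2 Date (or coercible) vector; voyages
#'   whose arrival date falls outside `[dateWindow[1], dateWindow[2]]` are
#'   dropped.
#' @return data.frame with one row per voyage: `ship_id`, `voyage_id`,
#'   `arrival_date`, and a list-column `calls` of ordered port-id vectors.
#' @export
readRoutes <- function(path, registry, requireDomesticDestination = FALSE,
                       maxCalls = 11L, dateWindow = NULL) {
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  .require_columns(df, c("ship_id", "voyage_id", "seq", "port_id", "arrival_date"), path)
  if (nrow(df) == 0) {
    warning("empty route file: ", path)
    return(data.frame(ship_id = character(), voyage_id = character(),
                      arrival_date = as.Date(character()),
                      calls = I(list()), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(df$port_id), registry$port_id)
  if (length(unknown))
    stop("validation error: unknown port_id(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  df$seq <- as.integer(df$seq)
  if (anyNA(df$seq)) stop("format error: non-integer seq values", call. = FALSE)

  key <- paste(df$ship_id, df$voyage_id, sep = "\r")
  ord <- order(key, df$seq)
  df <- df[ord, ]
  key <- key[ord]
  grp <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))

  collapsed <- FALSE
  short <- character()
  out <- lapply(grp, function(ix) {
    calls <- df$port_id[ix]
    dup <- c(FALSE, calls[-1] == calls[-length(calls)])
    if (any(dup)) { collapsed <<- TRUE; calls <- calls[!dup] }
    list(ship_id = df$ship_id[ix[1]], voyage_id = df$voyage_id[ix[1]],
         arrival_date = df$arrival_date[ix[length(ix)]], calls = calls)
  })
  if (collapsed)
    warning("collapsed consecutive duplicate port calls within voyage(s)")
  keep <- vapply(out, function(v) length(v$calls) >= 2, logical(1))
  if (any(!keep)) {
    short <- vapply(out[!keep], function(v) v$voyage_id, character(1))
    warning("dropped voyage(s) with fewer than 2 calls: ",
            paste(short, collapse = ", "))
    out <- out[keep]
  }
  routes <- data.frame(
    ship_id = vapply(out, `[[`, character(1), "ship_id"),
    voyage_id = vapply(out, `[[`, character(1), "voyage_id"),
    arrival_date = as.Date(vapply(out, `[[`, character(1), "arrival_date")),
    stringsAsFactors = FALSE
  )
  routes$calls <- I(unname(lapply(out, `[[`, "calls")))
  rownames(routes) <- NULL

  if (!is.null(dateWindow)) {
    dw <- as.Date(dateWindow)
    routes <- routes[routes$arrival_date >= dw[1] & routes$arrival_date <= dw[2], ]
    rownames(routes) <- NULL
  }
  if (!is.null(maxCalls)) {
    long <- lengths(routes$calls) > maxCalls
    if (any(long))
      stop("validation error: voyage(s) exceed the ", maxCalls,
           "-call truncation limit: ",
           paste(routes$voyage_id[long], collapse = ", "), call. = FALSE)
  }
  if (requireDomesticDestination) {
    dest <- vapply(routes$calls, function(x) x[length(x)], character(1))
    dom <- registry$is_domestic[match(dest, registry$port_id)]
    if (any(!dom))
      stop("validation error: voyage(s) not ending at a domestic port: ",
           paste(routes$voyage_id[!dom], collapse = ", "), call. = FALSE)
  }
  routes
}

#' Read the organism's established range and derive origin ports
#'
#' The range file lists one country code per line (`#` comments and blank
#' lines allowed). Origin ports are the registry ports whose country is in
#' the range *and* which appear on at least one route: ports of range
#' countries that never trade on the network cannot seed a pathway. Range
#' countries with no matching on-network port are reported with a warning,
#' not an error (a recorded range routinely extends beyond the network).
#'
#' @param path path to `pest_range.txt`.
#' @param registry port registry from [readPorts()].
#' @param routes route collection from [readRoutes()].
#' @return list with `countries` (the range, as given), `matchedCountries`
#'   (range countries with at least one on-network port) and `originPorts`
#'   (character vector of origin port ids).
#' @export
readPestRange <- function(path, registry, routes) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  countries <- unique(trimws(lines[nzchar(trimws(lines))]))
  if (length(countries) == 0)
    stop("validation error: empty pest range", call. = FALSE)
  onRoute <- unique(unlist(routes$calls))
  candidate <- registry[registry$country %in% countries &
                          registry$port_id %in% onRoute, , drop = FALSE]
  matched <- sort(unique(candidate$country))
  unmatched <- setdiff(countries, matched)
  if (length(unmatched))
    warning("range country(ies) with no port on the network: ",
            paste(unmatched, collapse = ", "))
  if (nrow(candidate) == 0)
    warning("pest range is disjoint from the shipping network: empty origin set")
  list(countries = countries, matchedCountries = matched,
       originPorts = sort(candidate$port_id))
}

#' Write / read a ranking table as CSV
#'
#' Columns `rank,entity_id,entity_kind,phi,relative_phi`, floats at six
#' decimals, rows in rank order. `readRanking()` restores the numeric
#' columns; a write/read round trip is the identity at that precision.
#'
#' @param ranking a [RankingTable-class].
#' @param path output path.
#' @return `writeRanking()` returns `path` invisibly; `readRanking()` a
#'   data.frame.
#' @export
writeRanking <- function(ranking, path) {
  stopifnot(is(ranking, "RankingTable"))
  tb <- ranking@table
  out <- data.frame(
    rank = tb$rank,
    entity_id = tb$entity_id,
    entity_kind = rep(ranking@entityKind, nrow(tb)),
    phi = sprintf("%.6f", tb$phi),
    relative_phi = sprintf("%.6f", tb$relative_phi),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRanking
#' @export
readRanking <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(rank = "integer", entity_id = "character",
                                entity_kind = "character", phi = "numeric",
                                relative_phi = "numeric"))
  .require_columns(df, c("rank", "entity_id", "entity_kind", "phi", "relative_phi"), path)
  df
}

#' Export network matrices as edge lists
#'
#' `writeSegmentCounts()` writes `from,to,count` for every positive segment;
#' `writeTransmission()` writes `from,to,rate` plus a `port,absorption`
#' sidecar; `writeArrivalRates()` writes `origin,destination,J,K,phi` for
#' every positive estimate.
#'
#' @param x the object to export.
#' @param path output CSV path.
#' @param absorptionPath sidecar path for the absorption column.
#' @return the main output path, invisibly.
#' @export
writeSegmentCounts <- function(x, path) {
  stopifnot(is(x, "SegmentCounts"))
  ij <- which(x@counts > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(from = x@ports[ij[, 1]], to = x@ports[ij[, 2]],
                   count = x@counts[ij])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSegmentCounts
#' @export
writeTransmission <- function(x, path, absorptionPath) {
  stopifnot(is(x, "TransmissionMatrix"))
  ij <- which(x@rates > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(from = x@ports[ij[, 1]], to = x@ports[ij[, 2]],
                   rate = sprintf("%.12g", x@rates[ij]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- data.frame(port = x@ports, absorption = sprintf("%.12g", x@absorption))
  write.csv(side, absorptionPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSegmentCounts
#' @export
writeArrivalRates <- function(x, path) {
  stopifnot(is(x, "ArrivalRates"))
  ij <- which(x@J > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(origin = x@origins[ij[, 1]], destination = x@destinations[ij[, 2]],
                   J = x@J[ij], K = x@K, phi = sprintf("%.8g", x@J[ij] / x@K))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
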