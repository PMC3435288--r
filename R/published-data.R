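## Headline estimates reported by the khapra beetle container-pathway risk
## assessment for Australia, shipped as plain-text reference data. The
## underlying vessel-movement records are proprietary, so these published
## aggregates are the only quantitative anchor available for internal
## consistency checks (relative-rate arithmetic, complement-product lower
## bounds, journey-duration arithmetic).

#' Published reference tables of the khapra beetle pathway assessment
#'
#' Loads the reported top-ten rankings: source countries, domestic
#' (Australian) destination ports, and the port-by-port breakdown of the
#' ten most threatened destination ports. Rates are stored exactly as
#' printed (3-5 decimals depending on panel); `phi_decimals` and
#' `relative_decimals` give the printed precision of each value so checks
#' can propagate rounding honestly.
#'
#' @param which `"countries"`, `"domestic_ports"` or `"port_by_port"`.
#' @return data.frame of the requested table with numeric `phi`,
#'   `relative_phi` and the printed-precision columns.
#' @seealso [publishedConstants()], [runChecks()]
#' @export
publishedTable <- function(which = c("countries", "domestic_ports", "port_by_port")) {
  which <- match.arg(which)
  fname <- switch(which,
    countries = "country_rankings.csv",
    domestic_ports = "domestic_port_rankings.csv",
    port_by_port = "port_by_port_rankings.csv")
  path <- system.file("extdata", "published", fname, package = "pestPathways",
                      mustWork = TRUE)
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  decimals <- function(s) {
    d <- rep(0L, length(s))
    hasDot <- grepl(".", s, fixed = TRUE)
    d[hasDot] <- nchar(sub("^[^.]*\\.", "", s[hasDot]))
    d
  }
  df$phi_decimals <- decimals(df$phi)
  df$relative_decimals <- decimals(df$relative_phi)
  df$phi <- as.numeric(df$phi)
  df$relative_phi <- as.numeric(df$relative_phi)
  df
}

#' Published scalar constants of the pathway assessment
#'
#' The per-table relative-rate denominators, the reported degree
#' centralities, the 7.9-day mean leg duration, the ten-prior-port window
#' and its ~71-day coverage, the simulations-per-origin count, and the
#' network scale (ports, countries, ships, call events, organism range).
#'
#' @return nested list, see `inst/extdata/published/constants.json`.
#' @export
publishedConstants <- function() {
  path <- system.file("extdata", "published", "constants.json",
                      package = "pestPathways", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
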