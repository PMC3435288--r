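## Uncertainty scenarios for the transmission matrix -- multiplicative
## errors, additive errors, random removal of network paths -- and the
## rank-stability statistics that summarize their downstream effect.

## Re-close perturbed rows so they remain valid probability rows.
## "rescale": any row whose rate sum exceeds `cap` is scaled down to `cap`
##   (within-row relative structure, which the rankings consume, is kept).
## "clip": rows are left untouched unless their sum reaches 1, in which
##   case they are scaled to `cap`.
## Absorption is recomputed as the complement in either case.
.recloseRows <- function(rates, method = c("rescale", "clip"), cap = 0.99) {
  method <- match.arg(method)
  rs <- rowSums(rates)
  over <- if (method == "rescale") rs > cap else rs >= 1
  if (any(over)) {
    scale <- ifelse(over, cap / rs, 1)
    rates <- rates * scale
  }
  rates
}

.finishPerturbed <- function(P, rates, rowClosure, closureCap) {
  diag(rates) <- 0
  rates <- .recloseRows(rates, rowClosure, closureCap)
  new("TransmissionMatrix", ports = P@ports, rates = rates,
      absorption = 1 - rowSums(rates), lam = NA_real_, cap = P@cap)
}

#' Perturb transmission rates: the three uncertainty scenarios
#'
#' `perturbMultiplicative()` replaces every positive rate p by a draw from
#' Uniform\[p(1-bound), p(1+bound)\] clipped to \[0, 1\]: mean-preserving
#' measurement error proportional to the rate, leaving zero entries (and
#' hence the network's support) unchanged.
#'
#' `perturbAdditive()` adds an independent Uniform\[bounds\] variate to
#' every off-diagonal entry including zeros, so the support becomes (almost
#' surely) complete -- an increasing loss of knowledge about where ships
#' travel that shifts the network toward uniform connectivity.
#'
#' `perturbRemove()` draws a removal fraction f ~ Uniform\[0, removalMax\]
#' and zeroes floor(f * E) of the E positive entries chosen uniformly
#' without replacement: uncertainty about the presence of individual
#' network paths.
#'
#' All three recompute the absorption column after re-closing rows via the
#' `rowClosure` policy (see Details). Randomness comes from the current R
#' RNG stream; seed the caller for reproducibility.
#'
#' @details Literal additive noise across several hundred columns can push
#' a row's rate sum far above 1, which a probability row cannot carry. Rows
#' whose sum exceeds `closureCap` are therefore rescaled to it (default
#' policy), preserving within-row relative structure; `"clip"` instead
#' touches only rows whose sum reaches 1.
#'
#' @param P a [TransmissionMatrix-class].
#' @param bound multiplicative half-width as a fraction of each rate
#'   (study value 0.3), in (0, 1); 0 is accepted and returns the matrix
#'   unchanged (degenerate limit).
#' @param bounds length-2 interval within \[0, 1\] for the additive variate
#'   (study value c(0, 0.05)).
#' @param removalMax upper bound of the removal fraction (study value 0.3),
#'   in \[0, 1).
#' @param rowClosure `"rescale"` or `"clip"`.
#' @param closureCap row-sum cap applied on re-closing.
#' @return a perturbed [TransmissionMatrix-class].
#' @export
perturbMultiplicative <- function(P, bound = 0.3, rowClosure = c("rescale", "clip"),
                                  closureCap = 0.99) {
  stopifnot(is(P, "TransmissionMatrix"))
  if (!is.numeric(bound) || length(bound) != 1 || bound < 0 || bound >= 1)
    stop("bound must be a single fraction in [0, 1)", call. = FALSE)
  rates <- P@rates
  nz <- which(rates > 0)
  if (bound > 0 && length(nz)) {
    p <- rates[nz]
    draw <- runif(length(nz), p * (1 - bound), p * (1 + bound))
    rates[nz] <- pmin(pmax(draw, 0), 1)
  }
  .finishPerturbed(P, rates, match.arg(rowClosure), closureCap)
}

#' @rdname perturbMultiplicative
#' @export
perturbAdditive <- function(P, bounds = c(0, 0.05), rowClosure = c("rescale", "clip"),
                            closureCap = 0.99) {
  stopifnot(is(P, "TransmissionMatrix"))
  if (!is.numeric(bounds) || length(bounds) != 2 || bounds[1] > bounds[2] ||
      bounds[1] < 0 || bounds[2] > 1)
    stop("bounds must be an ordered interval within [0, 1]", call. = FALSE)
  rates <- P@rates
  n <- nrow(rates)
  add <- matrix(runif(n * n, bounds[1], bounds[2]), n, n)
  diag(add) <- 0
  rates <- pmin(pmax(rates + add, 0), 1)
  .finishPerturbed(P, rates, match.arg(rowClosure), closureCap)
}

#' @rdname perturbMultiplicative
#' @export
perturbRemove <- function(P, removalMax = 0.3, rowClosure = c("rescale", "clip"),
                          closureCap = 0.99) {
  stopifnot(is(P, "TransmissionMatrix"))
  if (!is.numeric(removalMax) || length(removalMax) != 1 ||
      removalMax < 0 || removalMax >= 1)
    stop("removalMax must be a single fraction in [0, 1)", call. = FALSE)
  rates <- P@rates
  nz <- which(rates > 0)
  f <- runif(1, 0, removalMax)
  nRemove <- floor(f * length(nz))
  if (nRemove > 0) rates[sample(nz, nRemove)] <- 0
  .finishPerturbed(P, rates, match.arg(rowClosure), closureCap)
}

#' Least-squares regression of perturbed ranks on baseline ranks
#'
#' Ordinary least squares of y (perturbed rank) on x (baseline rank),
#' computed in closed form so the degenerate identical-ranking case yields
#' slope = 1 and R-squared = 1 *exactly* (zero residuals, not numerically
#' tiny ones). Ties should be encoded as average ranks by the caller.
#' The t statistic is slope / SE(slope) with n - 2 degrees of freedom
#' (infinite when the fit is exact).
#'
#' @param baseline numeric vector of baseline ranks.
#' @param perturbed numeric vector of perturbed ranks, same length >= 3.
#' @return list with `slope`, `intercept`, `r_squared`, `t_statistic`,
#'   `dof`, `n`.
#' @export
rankRegression <- function(baseline, perturbed) {
  n <- length(baseline)
  if (length(perturbed) != n) stop("rank vectors differ in length", call. = FALSE)
  if (n < 3) stop("rank regression needs at least 3 entities", call. = FALSE)
  x <- as.numeric(baseline); y <- as.numeric(perturbed)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("baseline ranks are constant", call. = FALSE)
  slope <- sum(xc * yc) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum(yc^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- if (se == 0) Inf else slope / se
  list(slope = slope, intercept = intercept, r_squared = r2,
       t_statistic = tstat, dof = n - 2L, n = n)
}

## Average ranks of entities by decreasing phi (ties averaged), for the
## rank-on-rank regressions.
.avgRanks <- function(phi) rank(-phi, ties.method = "average")

## phi summaries reused by runSensitivity: combined rate per foreign origin
## and per domestic port.
.entityPhis <- function(ar, registry) {
  dom <- intersect(ar@destinations, registry$port_id[registry$is_domestic])
  phi <- arrivalPhi(ar)[, dom, drop = FALSE]
  list(
    foreign_port = setNames(vapply(seq_along(ar@origins),
                                   function(i) combineRates(phi[i, ]), numeric(1)),
                            ar@origins),
    domestic_port = setNames(vapply(seq_along(dom),
                                    function(j) combineRates(phi[, j]), numeric(1)),
                             dom)
  )
}

.perturbOnce <- function(P, scenario, multBound, addBounds, removalMax,
                         rowClosure, closureCap) {
  switch(scenario,
    multiplicative = perturbMultiplicative(P, multBound, rowClosure, closureCap),
    additive = perturbAdditive(P, addBounds, rowClosure, closureCap),
    removal = perturbRemove(P, removalMax, rowClosure, closureCap),
    stop("unknown scenario: ", scenario, call. = FALSE))
}

## Per-realization variant: a fresh perturbed matrix for every single walk.
## Pure R; intended for small networks.
.estimatePerRealization <- function(P, origins, K, seed, maxSteps, scenario,
                                    multBound, addBounds, removalMax,
                                    rowClosure, closureCap) {
  n <- length(P@ports)
  J <- matrix(0L, length(origins), n, dimnames = list(origins, P@ports))
  for (i in seq_along(origins)) {
    ## same substream as the compiled baseline walker; perturbation draws
    ## interleave into it, so a zero-magnitude multiplicative perturbation
    ## (which consumes no RNG) reproduces the baseline bit for bit
    set.seed(.substreamSeed(seed, origins[i]))
    o <- match(origins[i], P@ports)
    for (k in seq_len(K)) {
      Pk <- .perturbOnce(P, scenario, multBound, addBounds, removalMax,
                         rowClosure, closureCap)
      cur <- o
      seen <- logical(n)
      for (step in seq_len(maxSteps)) {
        r <- Pk@rates[cur, ]
        nz <- which(r > 0)
        if (length(nz) == 0) break
        cum <- cumsum(r[nz])
        u <- runif(1)
        if (u >= cum[length(cum)]) break
        cur <- nz[which(u < cum)[1]]
        if (cur != o && !seen[cur]) { seen[cur] <- TRUE; J[i, cur] <- J[i, cur] + 1L }
      }
    }
  }
  new("ArrivalRates", origins = as.character(origins), destinations = P@ports,
      J = J, K = as.integer(K), countMode = "firstVisit",
      seed = as.integer(seed))
}

#' Rank-stability analysis under network uncertainty
#'
#' Runs the three perturbation scenarios against a baseline ranking and
#' reports, per scenario, replicate and entity kind (foreign origin ports
#' and domestic destination ports), the least-squares regression of
#' perturbed rank on baseline rank -- slope, R-squared, t statistic and
#' degrees of freedom -- plus the same regression restricted to the
#' top-`topFraction` of the baseline ranking (the high-risk entities an
#' inspection programme would act on).
#'
#' The baseline and every perturbed run use the identical Monte-Carlo
#' seed policy (`seed`, per-origin substreams), so a zero-magnitude
#' perturbation reproduces the baseline counts bit for bit and the
#' regression returns slope 1 and R-squared 1 exactly; perturbation draws
#' come from an independent stream varied across replicates.
#'
#' With `redraw = "perReplicate"` (default) one perturbed matrix is drawn
#' per replicate and walked K times; `"perRealization"` draws a fresh
#' matrix for every walk (pure R -- use on small networks only).
#'
#' @param P baseline [TransmissionMatrix-class].
#' @param origins origin ports within the organism's range.
#' @param registry port registry.
#' @param scenarios subset of `c("multiplicative", "additive", "removal")`.
#' @param multBound,addBounds,removalMax scenario magnitudes (study values
#'   0.3, c(0, 0.05), 0.3).
#' @param nReplicates perturbation replicates per scenario.
#' @param K walks per origin per run.
#' @param seed base Monte-Carlo seed (also seeds the perturbation streams).
#' @param maxSteps walk-length cap.
#' @param rowClosure,closureCap row re-closing policy, see
#'   [perturbMultiplicative()].
#' @param redraw `"perReplicate"` or `"perRealization"`.
#' @param topFraction fraction of top-ranked entities for the restricted
#'   regression.
#' @return data.frame with one row per (scenario, replicate, entity kind):
#'   `entity_kind`, `scenario`, `replicate`, `n`, `slope`, `r_squared`,
#'   `t_statistic`, `dof`, `top_n`, `top_r_squared`, `seed`.
#' @export
runSensitivity <- function(P, origins, registry,
                           scenarios = c("multiplicative", "additive", "removal"),
                           multBound = 0.3, addBounds = c(0, 0.05),
                           removalMax = 0.3, nReplicates = 10, K = 1e4,
                           seed = 1L, maxSteps = 10000L,
                           rowClosure = c("rescale", "clip"), closureCap = 0.99,
                           redraw = c("perReplicate", "perRealization"),
                           topFraction = 0.5) {
  rowClosure <- match.arg(rowClosure)
  redraw <- match.arg(redraw)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  ar0 <- estimateArrivalRates(P, origins, K = K, seed = seed, maxSteps = maxSteps)
  base <- .entityPhis(ar0, registry)
  for (kind in names(base)) if (length(base[[kind]]) < 3)
    stop("fewer than 3 entities of kind ", kind, ": regression undefined",
         call. = FALSE)
  baseRanks <- lapply(base, .avgRanks)

  rows <- list()
  for (s in seq_along(scenarios)) {
    scen <- scenarios[s]
    for (r in seq_len(nReplicates)) {
      perturbSeed <- (as.integer(seed) + 104729L * s + 7919L * r) %% 2147483647L
      if (redraw == "perReplicate") {
        set.seed(perturbSeed)
        Pp <- .perturbOnce(P, scen, multBound, addBounds, removalMax,
                           rowClosure, closureCap)
        ar <- estimateArrivalRates(Pp, origins, K = K, seed = seed,
                                   maxSteps = maxSteps)
      } else {
        ar <- .estimatePerRealization(P, origins, K, seed, maxSteps, scen,
                                      multBound, addBounds, removalMax,
                                      rowClosure, closureCap)
      }
      pert <- .entityPhis(ar, registry)
      for (kind in names(base)) {
        x <- baseRanks[[kind]]
        y <- .avgRanks(pert[[kind]])
        reg <- rankRegression(x, y)
        topN <- max(3L, floor(length(x) * topFraction))
        topIx <- order(x)[seq_len(topN)]
        topReg <- rankRegression(x[topIx], y[topIx])
        rows[[length(rows) + 1L]] <- data.frame(
          entity_kind = kind, scenario = scen, replicate = r,
          n = reg$n, slope = reg$slope, r_squared = reg$r_squared,
          t_statistic = reg$t_statistic, dof = reg$dof,
          top_n = topReg$n, top_r_squared = topReg$r_squared,
          seed = as.integer(seed), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
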