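# Perturbation scenarios, row re-closing, rank regression, and the
# degenerate identities.

test_that("multiplicative perturbation is mean-preserving and support-preserving", {
  P <- mkTM(rateMatrix(c("A", "B", "C"), list("A", "B", 0.5), list("B", "C", 0.2)))
  set.seed(4)
  draws <- replicate(1e4, transmissionRates(perturbMultiplicative(P, 0.3))["A", "B"])
  expect_true(all(draws >= 0.35 - 1e-12 & draws <= 0.65 + 1e-12))
  # uniform on [0.35, 0.65]: mean 0.5, sd 0.3/sqrt(12)
  expect_lt(abs(mean(draws) - 0.5), 4 * (0.3 / sqrt(12)) / sqrt(1e4))

  # zero entries never become positive
  set.seed(8)
  for (i in 1:20) {
    Pp <- perturbMultiplicative(P, 0.3)
    expect_identical(transmissionRates(Pp) > 0, transmissionRates(P) > 0)
    expect_true(validObject(Pp))
  }
  # degenerate bound: matrix unchanged
  expect_equal(transmissionRates(perturbMultiplicative(P, 0)),
               transmissionRates(P))
  expect_error(perturbMultiplicative(P, 1.2), "fraction")
})

test_that("additive perturbation completes the support within its bounds", {
  P <- mkTM(rateMatrix(c("A", "B", "C"), list("A", "B", 0.5)))
  set.seed(12)
  Pp <- perturbAdditive(P, c(0, 0.05))
  r <- transmissionRates(Pp)
  off <- r[row(r) != col(r)]
  expect_true(all(off > 0))          # almost surely complete support
  expect_true(all(diag(r) == 0))
  # previously-zero entries lie in (0, 0.05]
  zeroBefore <- transmissionRates(P) == 0 & row(r) != col(r)
  expect_true(all(r[zeroBefore] <= 0.05 + 1e-12))
  expect_true(validObject(Pp))
  expect_error(perturbAdditive(P, c(0.1, 0.05)), "interval")
})

test_that("row re-closing keeps heavily perturbed rows valid probability rows", {
  # wide additive bounds force raw row sums far above 1
  set.seed(3)
  ports <- paste0("P", 1:12)
  m <- rateMatrix(ports, list("P1", "P2", 0.8))
  P <- mkTM(m)
  Pp <- perturbAdditive(P, c(0.2, 0.4))
  rs <- rowSums(transmissionRates(Pp))
  expect_true(all(rs <= 0.99 + 1e-12))
  expect_true(validObject(Pp))
  # deterministic additive bounds: entries clip at 1, then the row rescales
  # to the cap keeping relative structure
  set.seed(3)
  Pd <- perturbAdditive(P, c(0.3, 0.3))
  r1 <- transmissionRates(Pd)["P1", ]
  raw <- pmin(transmissionRates(P)["P1", ] + 0.3, 1); raw["P1"] <- 0
  expect_equal(sum(r1), 0.99)
  expect_equal(r1, raw * (0.99 / sum(raw)), tolerance = 1e-12)
})

test_that("removal zeroes floor(f * E) entries with f uniform on [0, max]", {
  set.seed(9)
  ports <- paste0("P", 1:8)
  args <- lapply(1:20, function(i)
    list(ports[(i - 1) %% 8 + 1], ports[i %% 8 + 1], 0.04))
  m <- do.call(rateMatrix, c(list(ports), args))
  P <- mkTM(m)
  E <- sum(transmissionRates(P) > 0)
  removed <- replicate(2000, E - sum(transmissionRates(perturbRemove(P, 0.3)) > 0))
  expect_true(all(removed >= 0 & removed <= floor(0.3 * E)))
  # counts distribute as floor(U[0, 0.3] * E): mean ~ E*0.3/2 (floor bias < 0.5)
  expect_lt(abs(mean(removed) - 0.3 * E / 2), 0.5 + 4 * (0.3 * E / sqrt(12)) / sqrt(2000))
  # near-zero magnitude: nothing removed
  expect_equal(transmissionRates(perturbRemove(P, 1e-9)), transmissionRates(P))
})

test_that("removing all outgoing paths of an origin zeroes its arrival row", {
  P <- mkTM(rateMatrix(c("A", "B"), list("A", "B", 0.5)))
  rates <- transmissionRates(P); rates["A", "B"] <- 0
  Pdead <- mkTM(rates)
  phi <- arrivalPhi(estimateArrivalRates(Pdead, "A", K = 500, seed = 1))
  expect_true(all(phi == 0))
})

test_that("rank regression matches hand-computed Pearson values", {
  r <- rankRegression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$slope, 0.5)
  expect_equal(r$r_squared, 0.25)
  expect_equal(r$dof, 1L)
  expect_error(rankRegression(c(1, 2), c(2, 1)), "at least 3")
  expect_error(rankRegression(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("zero-magnitude perturbations return slope 1 and R-squared 1 exactly", {
  fx <- mkSensFixture()
  rpt <- runSensitivity(fx$P, fx$origins, fx$registry,
                        multBound = 0, addBounds = c(0, 0), removalMax = 1e-12,
                        nReplicates = 2, K = 2000, seed = 5)
  expect_identical(rpt$r_squared, rep(1, nrow(rpt)))
  expect_identical(rpt$slope, rep(1, nrow(rpt)))
  expect_identical(rpt$t_statistic, rep(Inf, nrow(rpt)))
  expect_equal(rpt$dof, rpt$n - 2L)

  # regression is contractually undefined below 3 entities
  co <- knownAnswerCase("corridor6")  # a single domestic port
  expect_error(runSensitivity(co$P, co$origins, co$ports, nReplicates = 1,
                              K = 100, seed = 1), "fewer than 3")
})

test_that("per-realization redraw reproduces the degenerate identity too", {
  fx <- mkSensFixture()
  rpt <- runSensitivity(fx$P, fx$origins, fx$registry,
                        scenarios = "multiplicative",
                        multBound = 0, nReplicates = 1, K = 300, seed = 5,
                        redraw = "perRealization")
  expect_equal(rpt$r_squared, rep(1, 2))
  expect_equal(rpt$slope, rep(1, 2))
})

test_that("perturbed matrices always satisfy the transmission invariants", {
  net <- generateNetwork(smallConfig())
  P <- buildTransmission(countSegments(net$routes))
  set.seed(14)
  for (f in list(function() perturbMultiplicative(P, 0.3),
                 function() perturbAdditive(P, c(0, 0.05)),
                 function() perturbRemove(P, 0.3))) {
    for (i in 1:5) {
      Pp <- f()
      expect_true(validObject(Pp))
      expect_lt(max(abs(rowSums(transmissionRates(Pp)) + absorptionRates(Pp) - 1)),
                1e-12)
    }
  }
})
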