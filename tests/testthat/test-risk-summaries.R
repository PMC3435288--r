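# Complement-product aggregation and the three ranking tables.

test_that("combineRates matches hand arithmetic and handles edge cases", {
  expect_equal(combineRates(c(0.245, 0.227)), 1 - 0.755 * 0.773)
  expect_equal(combineRates(0.3), 0.3)
  expect_equal(combineRates(numeric(0)), 0)
  expect_equal(combineRates(c(0.5, 1)), 1)
  expect_error(combineRates(c(0.2, 1.1)), "\\[0, 1\\]")
  expect_error(combineRates(c(-0.1)), "\\[0, 1\\]")
})

test_that("combineRates is bounded, permutation-invariant, monotone, ~additive for small rates", {
  set.seed(11)
  for (i in 1:25) {
    x <- runif(sample(1:8, 1))
    cb <- combineRates(x)
    expect_gte(cb, max(x))
    expect_lte(cb, min(1, sum(x)))
    expect_equal(cb, combineRates(sample(x)))
    bumped <- x; j <- sample(length(x), 1)
    bumped[j] <- min(1, bumped[j] + 0.1)
    expect_gte(combineRates(bumped), cb)
  }
  small <- c(2e-6, 5e-7, 1e-6)
  expect_equal(combineRates(small), sum(small), tolerance = 1e-5)
})

mkAR <- function(origins, destinations, phi, K = 1000L) {
  new("ArrivalRates", origins = origins, destinations = destinations,
      J = matrix(as.integer(round(phi * K)), nrow = length(origins),
                 dimnames = list(origins, destinations)),
      K = K, countMode = "firstVisit", seed = 1L)
}

test_that("domestic-port ranking combines origins and orders by overall rate", {
  reg <- mkRegistry("F1", c("D1", "D2"))
  # D1 gets a single 0.5 source; D2 gets 0.4 and 0.2 from two origins
  reg2 <- mkRegistry(c("F1", "F2"), c("D1", "D2"))
  ar <- mkAR(c("F1", "F2"), c("F1", "F2", "D1", "D2"),
             rbind(c(0, 0, 0.5, 0.4), c(0, 0, 0, 0.2)))
  rk <- rankDomesticPorts(ar, reg2)
  tb <- rankingData(rk)
  expect_equal(tb$entity_id, c("D2", "D1"))      # 1 - 0.6*0.8 = 0.52 > 0.5
  expect_equal(tb$phi, c(0.52, 0.5))
  expect_equal(tb$rank, 1:2)
  expect_equal(mean(tb$relative_phi), 1, tolerance = 1e-9)

  # single origin, single domestic port
  ar1 <- mkAR("F1", c("F1", "D1"), rbind(c(0, 0.3)))
  rk1 <- rankDomesticPorts(ar1, reg)
  expect_equal(rankingData(rk1)$phi, 0.3)
  expect_equal(rankingData(rk1)$relative_phi, 1)

  # permuting origins leaves the table unchanged
  arP <- mkAR(c("F2", "F1"), c("F1", "F2", "D1", "D2"),
              rbind(c(0, 0, 0, 0.2), c(0, 0, 0.5, 0.4)))
  expect_equal(rankingData(rankDomesticPorts(arP, reg2)), tb)
})

test_that("foreign-port and country rankings mirror the domestic combine", {
  reg <- mkRegistry(c("F1", "F2", "F3"), c("D1", "D2"),
                    foreignCountry = c("TW", "TW", "KR"))
  # F1 -> {0.3, 0.2}, F2 -> {0.1, 0.1}, F3 reaches nothing
  phi <- rbind(c(0, 0, 0, 0.3, 0.2), c(0, 0, 0, 0.1, 0.1), c(0, 0, 0, 0, 0))
  ar <- mkAR(c("F1", "F2", "F3"), c("F1", "F2", "F3", "D1", "D2"), phi)
  fp <- rankingData(rankForeignPorts(ar, reg))
  expect_equal(fp$phi[fp$entity_id == "F1"], 1 - 0.7 * 0.8)
  expect_equal(fp$phi[fp$entity_id == "F2"], 1 - 0.9 * 0.9)
  expect_equal(fp$phi[fp$entity_id == "F3"], 0)
  expect_equal(fp$rank[fp$entity_id == "F3"], 3)  # unreachable origin ranks last
  expect_equal(mean(fp$relative_phi), 1, tolerance = 1e-9)

  cn <- rankingData(rankCountries(ar, reg))
  expect_equal(cn$phi[cn$entity_id == "TW"],
               1 - (1 - (1 - 0.7 * 0.8)) * (1 - (1 - 0.9 * 0.9)))
  expect_equal(cn$phi[cn$entity_id == "KR"], 0)  # single all-zero port
})

test_that("country reconstruction reproduces the two-port hand example", {
  # two ports with combined rates 0.537 and 0.211 -> 1 - 0.463*0.789
  expect_equal(combineRates(c(0.537, 0.211)), 1 - 0.463 * 0.789)
  expect_equal(round(combineRates(c(0.537, 0.211)), 3), 0.635)
})

test_that("ranks are invariant under common positive rescaling of phi", {
  set.seed(21)
  reg <- mkRegistry(paste0("F", 1:6), c("D1", "D2", "D3"))
  phi <- matrix(runif(18, 0, 0.4), 6, 3)
  dest <- c(paste0("F", 1:6), "D1", "D2", "D3")
  full <- cbind(matrix(0, 6, 6), phi)
  ar <- mkAR(paste0("F", 1:6), dest, full, K = 100000L)
  r1 <- rankingData(rankForeignPorts(ar, reg))
  ar2 <- mkAR(paste0("F", 1:6), dest, full * 0.5, K = 100000L)
  r2 <- rankingData(rankForeignPorts(ar2, reg))
  expect_equal(r1$entity_id, r2$entity_id)
  expect_equal(r1$rank, r2$rank)
})

test_that("pathway rank and degree rank can invert on a corridor network", {
  co <- knownAnswerCase("corridor6")
  est <- estimateArrivalRates(co$P, co$origins, K = 2e4, seed = 13)
  fp <- rankingData(rankForeignPorts(est, co$ports))
  deg <- degreeCentrality(co$routes)
  rankOf <- function(p) fp$rank[fp$entity_id == p]
  expect_equal(deg[[co$answers$inversion[["lowDegreeCorridor"]]]], 20)
  expect_equal(deg[[co$answers$inversion[["highDegreePeripheral"]]]], 60)
  # ...yet the corridor port outranks the peripheral port by arrival rate
  expect_lt(rankOf("C"), rankOf("E"))
})

test_that("per-destination breakdowns share a single mean denominator", {
  reg <- mkRegistry(c("F1", "F2"), c("D1", "D2"))
  phi <- rbind(c(0, 0, 0.4, 0.2), c(0, 0, 0.1, 0.3))
  ar <- mkAR(c("F1", "F2"), c("F1", "F2", "D1", "D2"), phi)
  bd <- portByPortBreakdown(ar, reg)
  expect_named(bd, c("D1", "D2"))
  expect_equal(attr(bd, "meanPhi"), mean(c(0.4, 0.2, 0.1, 0.3)))
  expect_equal(bd$D1$origin, c("F1", "F2"))
  expect_equal(bd$D1$relative_phi, c(0.4, 0.1) / 0.25)
  expect_equal(bd$D2$relative_phi, c(0.3, 0.2) / 0.25)
})
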