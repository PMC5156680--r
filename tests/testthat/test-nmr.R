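shiftTruth <- function(n = 8) {
  data.frame(chain = "A", resnum = seq_len(n),
             atom = rep(c("CA", "N"), length.out = n),
             shift = rep(c(55, 120), length.out = n) + seq_len(n) / 10)
}

test_that("chi-square is zero on exact agreement and matches hand arithmetic", {
  d <- makeShiftData(shiftTruth(), nFrames = 5, noiseSd = 0, seed = 1)
  out <- chi2Shifts(d$predicted, d$experimental)
  expect_equal(out$chi2, rep(0, nrow(out)))
  expect_setequal(out$group, c("CA", "N", "all"))
  expect_equal(out$s[out$group == "all"], 8L)

  ## s = 2, experimental {4, 4}, frame means {5, 3} -> chi2 = 0.5
  exp2 <- data.frame(chain = "A", resnum = 1:2, atom = "HA", shift = 4)
  pred2 <- data.frame(frame = rep(1:2, 2L), chain = "A",
                      resnum = rep(1:2, each = 2L), atom = "HA",
                      shift = c(6, 4, 2, 4))        # means 5 and 3
  out2 <- chi2Shifts(pred2, exp2)
  expect_equal(out2$chi2[out2$group == "all"], 0.5)
})

test_that("chi-square validates its inputs", {
  d <- makeShiftData(shiftTruth(), 3, 0, seed = 1)
  stray <- rbind(d$predicted,
                 data.frame(chain = "B", resnum = 99L, atom = "CA",
                            shift = 50, frame = 1L))
  expect_error(chi2Shifts(stray, d$experimental), "B 99 CA")
  zero <- d$experimental
  zero$shift[1L] <- 0
  expect_error(chi2Shifts(d$predicted, zero), "denominator")
  one <- d$experimental[1L, ]
  onep <- d$predicted[d$predicted$resnum == 1L, ]
  expect_error(chi2Shifts(onep, one), "fewer than 2")
})

test_that("chi-square is invariant to frame and record order", {
  d <- makeShiftData(shiftTruth(), 10, noiseSd = 0.4, seed = 3)
  base <- chi2Shifts(d$predicted, d$experimental)
  perm <- withr::with_seed(5, d$predicted[sample.int(nrow(d$predicted)), ])
  eperm <- withr::with_seed(6,
    d$experimental[sample.int(nrow(d$experimental)), ])
  expect_equal(chi2Shifts(perm, eperm), base)
})

test_that("constant-offset predictions satisfy the closed-form chi-square", {
  truth <- shiftTruth(6)
  d <- makeShiftData(truth, 4, 0, seed = 1)
  for (c0 in c(0.5, -1.2, 2)) {
    pred <- d$predicted
    pred$shift <- pred$shift + c0
    got <- chi2Shifts(pred, d$experimental)
    s <- nrow(truth)
    want <- (s / (s - 1)) * mean(c0^2 / truth$shift)
    expect_equal(got$chi2[got$group == "all"], want, tolerance = 1e-12)
  }
})

test_that("expected chi-square grows with prediction noise", {
  truth <- shiftTruth(6)
  meanChi2 <- function(sigma)
    mean(vapply(1:60, function(r) {
      d <- makeShiftData(truth, 5, noiseSd = sigma, seed = 1000 + r)
      out <- chi2Shifts(d$predicted, d$experimental)
      out$chi2[out$group == "all"]
    }, numeric(1)))
  expect_lt(meanChi2(0.2), meanChi2(0.8))
  expect_lt(meanChi2(0.8), meanChi2(2.0))
})

test_that("running chi-square is cumulative and consistent with the full statistic", {
  d <- makeShiftData(shiftTruth(), 20, noiseSd = 0.5, seed = 9)
  run <- runningChi2(d$predicted, d$experimental, c(1, 10, 20))
  full <- chi2Shifts(d$predicted, d$experimental)
  expect_equal(run[run$windowEnd == 20, c("group", "chi2", "s")], full,
               ignore_attr = TRUE)
  ## a 1-frame window means the "ensemble mean" is that frame's value
  f1 <- d$predicted[d$predicted$frame == 1L, ]
  expect_equal(run$chi2[run$windowEnd == 1 & run$group == "all"],
               chi2Shifts(f1, d$experimental)$chi2[3L])
  expect_error(runningChi2(d$predicted, d$experimental, 25),
               "beyond last frame")
})

test_that("stationary predictions give a flattening chi-square curve", {
  d <- makeShiftData(shiftTruth(10), 400, noiseSd = 0.5, seed = 11)
  ## stationary bias + frame noise: the curve levels off at the bias term
  d$predicted$shift <- d$predicted$shift + 0.5
  run <- runningChi2(d$predicted, d$experimental, c(200, 400),
                     groupByAtomType = FALSE)
  last <- run$chi2[run$windowEnd == 400]
  half <- run$chi2[run$windowEnd == 200]
  expect_lt(abs(last - half), 0.1 * last)
})

test_that("NOE distance averaging: linear mean, r6 lower bound, exact zero", {
  ens <- pairDistanceEnsemble(c(0.3, 0.5))
  noe <- data.frame(chain_a = "A", res_a = 1L, atom_a = "CB",
                    chain_b = "A", res_b = 10L, atom_b = "CB",
                    distance_nm = 0.4)
  lin <- noeDifferences(ens, noe)
  expect_equal(lin$d_avg, 0.4)
  expect_equal(lin$diff, 0)
  r6 <- noeDifferences(ens, noe, averaging = "r6")
  expect_equal(r6$d_avg, mean(c(0.3, 0.5)^-6)^(-1 / 6))
  expect_lt(r6$d_avg, lin$d_avg)

  same <- pairDistanceEnsemble(rep(0.37, 4L))
  noe$distance_nm <- 0.37
  expect_equal(noeDifferences(same, noe)$diff, 0)
})

test_that("r6 averages never exceed linear averages", {
  for (s in 1:50) {
    d <- withr::with_seed(s, runif(20, 0.2, 1.0))
    ens <- pairDistanceEnsemble(d)
    noe <- data.frame(chain_a = "A", res_a = 1L, atom_a = "CB",
                      chain_b = "A", res_b = 10L, atom_b = "CB",
                      distance_nm = 0.5)
    expect_lte(noeDifferences(ens, noe, "r6")$d_avg,
               noeDifferences(ens, noe, "linear")$d_avg + 1e-12)
  }
})

test_that("restraints with missing atoms or bad geometry are rejected", {
  ens <- pairDistanceEnsemble(0.4)
  noe <- data.frame(chain_a = "A", res_a = 1L, atom_a = "CG",
                    chain_b = "A", res_b = 10L, atom_b = "CB",
                    distance_nm = 0.4)
  expect_error(noeDifferences(ens, noe), "A:1:CG")
  bad <- transform(noe, atom_a = "CB", res_a = 10L)
  expect_error(noeDifferences(ens, bad), "identical partner")
})

test_that("restraint categories partition by chain and sequence separation", {
  expect_equal(categorizeRestraint("A", 10L, "A", 15L), "long")
  expect_equal(categorizeRestraint("A", 10L, "A", 12L), "short")
  expect_equal(categorizeRestraint("A", 10L, "A", 14L), "short")  # delta 4
  expect_equal(categorizeRestraint("A", 10L, "B", 10L), "intermolecular")
  ## vectorised partition: counts sum to the total
  cats <- categorizeRestraint(rep("A", 6L), c(1, 1, 1, 5, 9, 2),
                              c("A", "A", "B", "A", "A", "B"),
                              c(2, 9, 1, 6, 1, 9))
  expect_equal(sum(table(cats)), 6L)
})

test_that("RMSIP is 1 on self, symmetric, and 0 for orthogonal modes", {
  ens <- makeDimerEnsemble(30, 4, noiseSd = 0.03, seed = 19)
  expect_equal(rmsip(ens, ens, nModes = 5), 1, tolerance = 1e-8)
  other <- makeDimerEnsemble(30, 4, noiseSd = 0.03, seed = 23)
  expect_equal(rmsip(ens, other, 5), rmsip(other, ens, 5),
               tolerance = 1e-10)
  expect_error(rmsip(ens, makeDimerEnsemble(30, 5, seed = 1), 5),
               "mismatched")
  expect_error(rmsip(ens, other, nModes = 50), "at least 50 frames")

  ## two x-displacement modes of a zig-zag chain, orthogonal as
  ## 3N-vectors, with zero net translation and zero net torque so the
  ## superposition fit leaves them untouched
  zigzagEns <- function(pattern, seed) {
    atoms <- data.frame(chain = "A", resnum = 1:4, resname = "ALA",
                        atom = "CA")
    amp <- withr::with_seed(seed, rnorm(8, sd = 0.05))
    tinyEnsemble(lapply(amp, function(a)
      cbind(c(0, 1, 2, 3) + a * pattern, c(0, 1, 0, 1), 0)), atoms)
  }
  a <- zigzagEns(c(1, -1, -1, 1) / 2, 1)
  b <- zigzagEns(c(1, 1, -1, -1) / 2, 2)
  expect_equal(rmsip(a, a, 1), 1, tolerance = 1e-8)
  expect_lt(rmsip(a, b, 1), 0.05)
})

test_that("RMSIP matches an independent SVD-based oracle", {
  for (s in 1:5) {
    a <- makeDimerEnsemble(25, 3, noiseSd = 0.05, seed = s)
    b <- makeDimerEnsemble(25, 3, noiseSd = 0.05, seed = s + 100)
    expect_equal(rmsip(a, b, nModes = 4), oracleRmsip(a, b, 4),
                 tolerance = 1e-8)
  }
})

test_that("histidine tautomer follows the strict 122 ppm rule", {
  expect_equal(hisTautomer(120), "Ne2-H")
  expect_equal(hisTautomer(125), "Nd1-H")
  expect_equal(hisTautomer(122), "Nd1-H")
  expect_equal(hisTautomer(c(121.9, 122.1)), c("Ne2-H", "Nd1-H"))
})
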