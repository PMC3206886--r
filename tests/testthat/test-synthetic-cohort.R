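test_that("default cohort reproduces the 2x2 study layout", {
  coh <- generateCohort(cohortConfig(seed = 42))
  sub <- subjectTable(coh)
  expect_equal(nrow(sub), 76)
  tab <- table(sub$group, sub$sex)
  expect_equal(unname(tab["patient", "female"]), 20)
  expect_equal(unname(tab["patient", "male"]), 18)
  expect_equal(unname(tab["control", "female"]), 20)
  expect_equal(unname(tab["control", "male"]), 18)
  expect_equal(sum(sub$group == "patient"), 38)
  expect_equal(sum(sub$group == "control"), 38)
  ts <- coh@series[[1]]
  expect_equal(dim(seriesMatrix(ts)), c(90, 205))
  expect_equal(repetitionTime(ts), 2)
  expect_identical(regionLabels(ts), aalRegionLabels())
})

test_that("clinical covariates exist for patients only and respect ranges", {
  coh <- generateCohort(smallCohortConfig(seed = 7))
  sub <- subjectTable(coh)
  pat <- sub[sub$group == "patient", ]
  ctl <- sub[sub$group == "control", ]
  expect_true(all(is.na(ctl$disease_duration)))
  expect_true(all(is.na(ctl$pain_intensity)))
  expect_true(all(pat$disease_duration > 0))
  expect_true(all(pat$pain_intensity >= 0 & pat$pain_intensity <= 10))
  expect_true(all(sub$age > 0))
  expect_false(anyDuplicated(sub$subject_id) > 0)
})

test_that("identical seed and config give a bit-identical cohort", {
  cfg <- smallCohortConfig(seed = 11)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(subjectTable(c1), subjectTable(c2))
  expect_identical(seriesMatrix(c1@series[[3]]), seriesMatrix(c2@series[[3]]))
  expect_identical(c1@nuisance[[5]]@motion, c2@nuisance[[5]]@motion)
  expect_identical(c1@mixing, c2@mixing)
  c3 <- generateCohort(smallCohortConfig(seed = 12))
  expect_false(identical(seriesMatrix(c1@series[[1]]),
                         seriesMatrix(c3@series[[1]])))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(withinModuleR = 0.1, betweenModuleR = 0.3),
               "exceed")
  expect_error(cohortConfig(withinModuleR = 1.2), "\\(-1, 1\\)")
  expect_error(cohortConfig(nTimepoints = 20), "at least 30")
  expect_error(cohortConfig(noiseAr1 = 1.5), "noiseAr1")
})

test_that("zero effects make patient and control covariance identical", {
  cfg <- cohortConfig(diseaseEffect = 0, sexDiseaseInteraction = 0,
                      durationSlope = 0)
  rPatient <- restnet:::.subjectCorrelation(cfg, seq_len(90), 0)
  rControl <- restnet:::.subjectCorrelation(cfg, seq_len(90), 0)
  expect_identical(rPatient, rControl)
  # and a nonzero delta changes the within-module entries only
  rDelta <- restnet:::.subjectCorrelation(cfg, seq_len(90), -0.1)
  mod <- restnet:::.moduleAssignment(90, cfg@nModules)
  same <- outer(mod, mod, "==") & upper.tri(rDelta)
  expect_true(all((rDelta - rPatient)[same] < 0))
  expect_true(all((rDelta - rPatient)[!same & upper.tri(rDelta)] == 0))
})

test_that("generator hits its own within-module correlation target", {
  # long series, no nuisance, no effects: empirical within-module mean
  # correlation must land within +/-0.05 of the configured target
  cfg <- cohortConfig(nFemalePerGroup = 1, nMalePerGroup = 1, nRegions = 20,
                      nModules = 4, nTimepoints = 2000, withinModuleR = 0.6,
                      betweenModuleR = 0.1, diseaseEffect = 0,
                      sexDiseaseInteraction = 0, durationSlope = 0,
                      nuisanceWeight = 0, seed = 21)
  coh <- generateCohort(cfg)
  mod <- restnet:::.moduleAssignment(20, 4)
  same <- outer(mod, mod, "==")
  rWithin <- vapply(coh@series, function(ts) {
    r <- corValues(correlationMatrix(ts))
    mean(r[same & upper.tri(r)])
  }, numeric(1))
  expect_true(all(abs(rWithin - 0.6) < 0.05))
  rBetween <- vapply(coh@series, function(ts) {
    r <- corValues(correlationMatrix(ts))
    mean(r[!same & upper.tri(r)])
  }, numeric(1))
  expect_true(all(abs(rBetween - 0.1) < 0.05))
})

test_that("nuisance mixing weights are recorded and actually mixed in", {
  cfg <- smallCohortConfig(seed = 31, nuisanceWeight = 0.5)
  coh <- generateCohort(cfg)
  w <- coh@mixing[[1]]
  expect_equal(dim(w), c(40, 8))
  # regressing the true nuisance out removes the injected contamination
  resid <- regressNuisance(coh@series[[1]], coh@nuisance[[1]])
  nu <- coh@nuisance[[1]]
  nmat <- rbind(nu@motion, nu@wmSignal, nu@csfSignal)
  cross <- seriesMatrix(resid) %*% scale(t(nmat), scale = FALSE)
  expect_lt(max(abs(cross)), 1e-6)
})

test_that("fixture graphs have their canonical shapes", {
  expect_equal(edgeCount(generateFixtureGraph("complete", 5)), 10)
  degStar <- sort(unname(degrees(generateFixtureGraph("star", 5))))
  expect_equal(degStar, c(1, 1, 1, 1, 4))
  expect_equal(edgeCount(generateFixtureGraph("ring_lattice", 90, k = 12)),
               540)
  ws <- generateFixtureGraph("watts_strogatz", 90, k = 12, p = 0.1, seed = 1)
  expect_equal(edgeCount(ws), 540)
  expect_true(restnet:::.isConnected(adjacency(ws)))
  ws2 <- generateFixtureGraph("watts_strogatz", 90, k = 12, p = 0.1, seed = 1)
  expect_identical(adjacency(ws), adjacency(ws2))
  er <- generateFixtureGraph("erdos_renyi", 30, nEdges = 60, seed = 2)
  expect_equal(edgeCount(er), 60)
  expect_error(generateFixtureGraph("mystery", 10), "arg")
  expect_error(generateFixtureGraph("ring_lattice", 10, k = 3), "even k")
})
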