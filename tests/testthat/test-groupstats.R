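test_that("two-way ANOVA matches the balanced closed form", {
  set.seed(41)
  n <- 5
  cellMeans <- c(fc = 0, mc = 0, fp = 0, mp = 1)
  sex <- rep(rep(c("female", "male"), each = n), 2)
  disease <- rep(c("control", "patient"), each = 2 * n)
  y <- rep(cellMeans, each = n) + rnorm(4 * n, 0, 0.1)
  res <- twoWayAnova(y, sex, disease)

  # balanced 2x2 closed form
  ybar <- mean(y)
  cm <- tapply(y, list(sex, disease), mean)
  sexM <- rowMeans(cm); disM <- colMeans(cm)
  ssInt <- n * sum((sweep(sweep(cm, 1, sexM), 2, disM) + ybar)^2)
  ssSex <- 2 * n * sum((sexM - ybar)^2)
  ssDis <- 2 * n * sum((disM - ybar)^2)
  sse <- sum((y - rep(as.vector(cm[cbind(sex, disease)]), 1))^2)
  mse <- sse / (4 * n - 4)
  tab <- res$table
  expect_equal(tab$F[tab$term == "sex:disease"], ssInt / mse,
               tolerance = 1e-10)
  expect_equal(tab$F[tab$term == "sex"], ssSex / mse, tolerance = 1e-10)
  expect_equal(tab$F[tab$term == "disease"], ssDis / mse, tolerance = 1e-10)
  expect_equal(nrow(res$cells), 4)
})

test_that("ANOVA handles degenerate and unbalanced inputs", {
  sex <- rep(c("female", "male"), each = 6)
  disease <- rep(c("control", "patient"), 6)
  flat <- twoWayAnova(rep(2.5, 12), sex, disease)
  expect_true(all(flat$table$F == 0))
  expect_true(all(flat$table$p == 1))

  expect_error(twoWayAnova(rnorm(6), rep("female", 6),
                           rep(c("control", "patient"), 3)), "two levels")
  expect_error(twoWayAnova(rnorm(5), c("f", "f", "f", "m", "m"),
                           c("c", "p", "c", "c", "c")), "at least 2")

  # unbalanced cells: Type II F invariant to factor order
  set.seed(42)
  sex2 <- c(rep("female", 20), rep("male", 18), rep("female", 20),
            rep("male", 18))
  dis2 <- rep(c("control", "patient"), c(38, 38))
  y2 <- rnorm(76) + 0.8 * (dis2 == "patient")
  a12 <- twoWayAnova(y2, sex2, dis2)
  a21 <- twoWayAnova(y2, dis2, sex2)   # swapped roles
  expect_equal(a12$table$F[a12$table$term == "sex:disease"],
               a21$table$F[a21$table$term == "sex:disease"],
               tolerance = 1e-10)
  expect_equal(sort(a12$table$F[1:2]), sort(a21$table$F[1:2]),
               tolerance = 1e-10)
  # Type III also runs on unbalanced data
  a3 <- twoWayAnova(y2, sex2, dis2, ssType = "III")
  expect_true(all(a3$table$F >= 0))
})

test_that("ANOVA is invariant to consistent factor label swaps", {
  set.seed(43)
  sex <- rep(rep(c("female", "male"), each = 4), 2)
  disease <- rep(c("control", "patient"), each = 8)
  y <- rnorm(16) + (sex == "female") * (disease == "patient")
  a <- twoWayAnova(y, sex, disease)
  swapped <- twoWayAnova(y, ifelse(sex == "female", "male", "female"),
                         ifelse(disease == "control", "patient", "control"))
  expect_equal(a$table$F, swapped$table$F, tolerance = 1e-10)
})

test_that("BH adjustment reproduces hand-stepped decisions", {
  res <- fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(res$reject))     # p_(i) <= i * 0.05 / 4 for all i
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.04))

  expect_true(fdrAdjust(0.04)$reject)          # m = 1 reduces to raw
  expect_false(any(fdrAdjust(rep(1, 6))$reject))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # adjusted values are monotone in raw-p rank order
  set.seed(44)
  p <- runif(50)
  adj <- fdrAdjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))

  # BY is more conservative
  expect_true(all(fdrAdjust(p, method = "BY")$adjusted >= adj - 1e-12))
})

test_that("BH controls the FDR in a null/alternative mixture simulation", {
  set.seed(45)
  m <- 200; m0 <- 150
  fdp <- replicate(200, {
    p <- c(runif(m0), rbeta(m - m0, 0.05, 1))
    rej <- fdrAdjust(p, q = 0.05)$reject
    if (!any(rej)) 0 else sum(rej[seq_len(m0)]) / sum(rej)
  })
  expect_lt(mean(fdp), 0.05 + 2 * stats::sd(fdp) / sqrt(length(fdp)))
})

test_that("Tukey post-hoc flags only the shifted cell's contrasts", {
  set.seed(46)
  n <- 18
  sex <- rep(rep(c("female", "male"), each = n), 2)
  disease <- rep(c("control", "patient"), each = 2 * n)
  y0 <- rnorm(4 * n, 0, 1)
  none <- posthocPairwise(y0 * 0 + rnorm(4 * n, 0, 1e-6), sex, disease)
  expect_equal(nrow(none), 6)

  y <- y0 + 5 * (sex == "female" & disease == "patient")
  res <- posthocPairwise(y, sex, disease)
  hit <- grepl("female:patient", res$contrast)
  expect_equal(sum(hit), 3)
  expect_true(all(res$significant[hit]))
  expect_false(any(res$significant[!hit]))
  expect_equal(sum(res$within_sex_disease), 2)   # HC-vs-PM within each sex

  expect_error(posthocPairwise(rnorm(10), rep("f", 10),
                               rep(c("c", "p"), 5)), "two levels")
})

test_that("partial correlation removes shared covariates", {
  set.seed(47)
  n <- 500
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  plain <- partialCorrelation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)  # no covariates
  expect_equal(plain$df, n - 2)
  ctrl <- partialCorrelation(x, y, z)
  expect_gt(plain$r, 0.4)
  expect_lt(abs(ctrl$r), 0.12)       # confound removed
  expect_equal(ctrl$df, n - 3)

  expect_equal(partialCorrelation(x, x, z)$r, 1, tolerance = 1e-12)

  # covariate orthogonal to both leaves the plain correlation intact
  w <- qr.resid(qr(cbind(1, x, y)), rnorm(n))
  expect_equal(partialCorrelation(x, y, w)$r, cor(x, y), tolerance = 1e-10)

  expect_error(partialCorrelation(x, y, cbind(z, z)), "collinear")
  expect_error(partialCorrelation(1:3, 1:3, cbind(rnorm(3), rnorm(3))),
               "n >")
})

test_that("partial correlation p-value matches the t reference", {
  set.seed(48)
  n <- 40
  z <- rnorm(n); x <- 0.4 * z + rnorm(n); y <- 0.4 * z + rnorm(n)
  res <- partialCorrelation(x, y, z)
  tstat <- res$r * sqrt(res$df / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), res$df), tolerance = 1e-12)
})

test_that("vectorized edge ANOVA agrees with the per-metric ANOVA", {
  set.seed(49)
  sex <- c(rep("female", 20), rep("male", 18), rep("female", 20),
           rep("male", 18))
  disease <- rep(c("control", "patient"), c(38, 38))
  z <- matrix(rnorm(76 * 12), 76, 12)
  z[, 3] <- z[, 3] + 0.9 * (disease == "patient")
  colnames(z) <- sprintf("e%02d", 1:12)
  res <- edgeStats(z, sex, disease)
  expect_equal(nrow(res), 12)
  for (j in c(1, 3, 7)) {
    ref <- twoWayAnova(z[, j], sex, disease)$table
    expect_equal(res$F_sex[j], ref$F[ref$term == "sex"], tolerance = 1e-8)
    expect_equal(res$F_disease[j], ref$F[ref$term == "disease"],
                 tolerance = 1e-8)
    expect_equal(res$F_interaction[j], ref$F[ref$term == "sex:disease"],
                 tolerance = 1e-8)
    expect_equal(res$p_interaction[j],
                 ref$p[ref$term == "sex:disease"], tolerance = 1e-8)
  }
  expect_true(res$increased[3])
  expect_gt(res$diff_patient_minus_control[3], 0)
})
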