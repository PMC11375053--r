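makeTlsSignatures <- function(nGenes = 300, perSig = 12, seed = 61) {
  withr::local_seed(seed)
  genes <- sprintf("g%04d", seq_len(nGenes))
  sigs <- setNames(lapply(seq_along(tlsSignatureNames()), function(i)
    genes[((i - 1) * perSig + 1):(i * perSig)]), tlsSignatureNames())
  list(genes = genes, sigs = sigs)
}

test_that("TLS score matrix is z-standardised and validates its inputs", {
  fx <- makeTlsSignatures()
  withr::local_seed(62)
  m <- matrix(rnorm(300 * 12, 5), nrow = 300,
              dimnames = list(fx$genes, sprintf("s%02d", 1:12)))
  z <- tlsCsMatrix(m, fx$sigs)
  expect_equal(dim(z), c(7L, 12L))
  expect_equal(rownames(z), tlsSignatureNames())
  expect_equal(unname(rowMeans(z)), rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 7), tolerance = 1e-12)
  # duplicated sample columns give identical z columns
  m2 <- cbind(m, dup = m[, 1])
  z2 <- tlsCsMatrix(m2, fx$sigs)
  expect_equal(z2[, "dup"], z2[, 1], ignore_attr = TRUE)
  expect_error(tlsCsMatrix(m, fx$sigs[1:5]), "missing TLS signature")
  expect_error(tlsCsMatrix(m, fx$sigs[-3]), tlsSignatureNames()[3])
})

test_that("two-module clustering separates planted blobs and orients by mean", {
  withr::local_seed(63)
  scores <- cbind(matrix(rnorm(7 * 10, 1.5, 0.3), 7),
                  matrix(rnorm(7 * 10, -1.5, 0.3), 7))
  colnames(scores) <- sprintf("s%02d", 1:20)
  rownames(scores) <- tlsSignatureNames()
  mod <- clusterTwoModules(scores)
  expect_equal(as.character(mod[1:10]), rep("high", 10))
  expect_equal(as.character(mod[11:20]), rep("low", 10))
  expect_equal(levels(mod), c("low", "high"))
  # swapping the blobs swaps the labels (orientation by mean total score)
  modSw <- clusterTwoModules(scores[, c(11:20, 1:10)])
  expect_equal(as.character(modSw[1:10]), rep("low", 10))
  expect_error(clusterTwoModules(scores[, 1:3]), "at least 4")
  expect_error(clusterTwoModules(matrix(1, 7, 6)), "identical")
})

test_that("ROC cutoff maximises Youden's J against a brute-force scan", {
  # perfectly separable scores: J = 1 at the separating midpoint
  sc <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  res <- rocOptimalCutoff(sc, y)
  expect_equal(res$J, 1)
  expect_equal(res$threshold, 6.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  # random instances: J equals the max over all midpoints
  withr::local_seed(64)
  for (i in 1:20) {
    s <- rnorm(40)
    o <- rbinom(40, 1, plogis(s))
    if (length(unique(o)) < 2) next
    r <- rocOptimalCutoff(s, o)
    u <- sort(unique(s))
    thr <- (head(u, -1) + u[-1]) / 2
    Jall <- vapply(thr, function(t)
      mean(s[o == 1] > t) + mean(s[o == 0] <= t) - 1, numeric(1))
    expect_equal(r$J, max(Jall))
    expect_equal(r$threshold, thr[which(Jall == max(Jall))[1]])
  }
  # exchangeable scores: J stays near 0
  expect_lt(rocOptimalCutoff(rnorm(400), rbinom(400, 1, 0.5))$J, 0.25)
  expect_error(rocOptimalCutoff(1:4, c(1, 1, 1, 1)), "both outcome")
  expect_error(rocOptimalCutoff(rep(1, 4), c(0, 1, 0, 1)), "constant")
  # closest-to-corner criterion agrees on the separable fixture
  expect_equal(rocOptimalCutoff(sc, y, criterion = "closest")$threshold, 6.5)
})

test_that("Kaplan-Meier estimates match hand fixtures and the oracle", {
  # events at 1, 2, 3 with no censoring: S = 2/3, 1/3, 0
  surv <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- kmEstimate(surv)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$nRisk, c(3, 2, 1))
  # censoring between events: classic product-limit fixture
  s2 <- data.frame(time = c(1, 2, 2, 3, 4), event = c(1, 0, 1, 1, 0))
  km2 <- kmEstimate(s2)
  ev <- km2[km2$nEvent > 0, ]
  orc <- oracleKM(s2$time, s2$event)
  expect_equal(ev$survival, orc$survival)
  expect_equal(ev$time, orc$time)
  # no events: survival identically 1
  s3 <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_true(all(kmEstimate(s3)$survival == 1))
  # two groups are estimated independently
  s4 <- rbind(data.frame(time = c(1, 2, 3), event = 1),
              data.frame(time = c(5, 6, 7), event = 1))
  g <- rep(c("a", "b"), each = 3)
  km4 <- kmEstimate(s4, g)
  expect_equal(km4$survival[km4$group == "a"],
               kmEstimate(s4[1:3, ])$survival)
  # random data vs the hand oracle
  withr::local_seed(65)
  s5 <- data.frame(time = rexp(60, 0.1), event = rbinom(60, 1, 0.7))
  ev5 <- kmEstimate(s5); ev5 <- ev5[ev5$nEvent > 0, ]
  orc5 <- oracleKM(s5$time, s5$event)
  expect_equal(ev5$survival, orc5$survival, tolerance = 1e-12)
})

test_that("Cox hazard ratio matches the Efron oracle and flags separation", {
  # small grid with ties, checked against the hand-coded Efron likelihood
  surv <- data.frame(time = c(2, 2, 3, 4, 5, 5, 7, 9),
                     event = c(1, 1, 0, 1, 1, 1, 0, 1))
  x <- c(0, 1, 0, 1, 0, 1, 0, 1)
  fit <- coxHr(surv, factor(ifelse(x == 1, "B", "A")))
  betaOracle <- oracleCoxBetaHat(surv$time, surv$event, x)
  expect_equal(fit$beta, betaOracle, tolerance = 1e-3)
  expect_equal(fit$HR, exp(betaOracle), tolerance = 1e-3)
  expect_false(fit$flagged)
  expect_true(fit$ci[1] < fit$HR && fit$HR < fit$ci[2])
  # identical survival in both groups: HR near 1
  withr::local_seed(66)
  t2 <- rexp(200, 0.1)
  s2 <- data.frame(time = t2, event = 1)
  f2 <- coxHr(s2, rep(c("a", "b"), 100))
  expect_lt(abs(f2$beta), 0.3)
  expect_gt(f2$p, 0.01)
  # complete separation is flagged and capped
  s3 <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                   event = c(1, 1, 1, 1, 1, 1, 1, 1))
  expect_warning(f3 <- coxHr(s3, rep(c("early", "late"), each = 4)),
                 "monotone")
  expect_true(f3$flagged)
  expect_lte(abs(f3$beta), 20)
  expect_error(coxHr(surv, rep("a", 8)), "two levels")
  expect_error(coxHr(data.frame(time = 1:4, event = c(1, 1, 0, 0)),
                     c("a", "a", "b", "b")), "at least one event")
})

test_that("Cox adjusts for covariates and recovers a planted hazard ratio", {
  cohort <- generateSurvivalCohort(200, beta = log(0.3), seed = 67)
  grp <- factor(cohort$scores$group, levels = c("low", "high"))
  fit <- coxHr(cohort$surv, grp)
  expect_lt(abs(fit$beta - log(0.3)), 0.5)
  expect_lt(fit$p, 0.01)
  # adding an independent covariate leaves the estimate close
  withr::local_seed(68)
  cov <- data.frame(age = rnorm(200, 60, 8))
  fitAdj <- coxHr(cohort$surv, grp, covariates = cov)
  expect_lt(abs(fitAdj$beta - fit$beta), 0.2)
})

test_that("log-rank test matches the O-E oracle and detects group differences", {
  withr::local_seed(69)
  surv <- data.frame(time = rexp(80, rate = rep(c(0.05, 0.2), each = 40)),
                     event = rbinom(80, 1, 0.8))
  g <- rep(c("low", "high"), each = 40)
  lr <- logrankTest(surv, g)
  expect_equal(lr$chisq, oracleLogrank(surv$time, surv$event, g),
               tolerance = 1e-6)
  expect_equal(lr$df, 1L)
  expect_lt(lr$p, 0.01)
  # identical groups: chi-square small
  s2 <- data.frame(time = rexp(100, 0.1), event = 1)
  expect_gt(logrankTest(s2, rep(c("a", "b"), 50))$p, 0.01)
  expect_error(logrankTest(s2, rep("a", 100)), "at least 2")
  expect_error(logrankTest(data.frame(time = 1:4, event = 0),
                           c("a", "a", "b", "b")), "no events")
})

test_that("the survival pipeline stratifies a simulated cohort end to end", {
  fx <- makeTlsSignatures()
  withr::local_seed(70)
  n <- 40
  highSamp <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(rnorm(300 * n, 3, 0.5), nrow = 300,
              dimnames = list(fx$genes, sprintf("s%02d", 1:n)))
  sigGenes <- unlist(fx$sigs)
  m[sigGenes, highSamp] <- m[sigGenes, highSamp] + 1.5
  z <- tlsCsMatrix(m, fx$sigs)
  mod <- clusterTwoModules(z)
  expect_gte(mean((mod == "high") == highSamp), 0.95)
  # high-TLS samples get the protective hazard
  beta <- log(0.3)
  cohort <- generateSurvivalCohort(n, beta = beta, seed = 71)
  # reuse simulated times but assign groups from the called modules
  surv <- cohort$surv
  h <- 0.05 * exp(beta * (mod == "high"))
  withr::local_seed(72)
  surv$time <- rexp(n, h)
  surv$event <- 1
  fit <- coxHr(surv, factor(as.character(mod), levels = c("low", "high")))
  expect_lt(fit$HR, 1)
  expect_lt(logrankTest(surv, as.character(mod))$p, 0.05)
})
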