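# Balanced helper: phenotype-like frame with a known generative model.
sim_pois_records <- function(n, b0 = log(20), b_pe = 0, pe = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pe)) pe <- runif(n, 0, 20)
  mu <- exp(b0 + b_pe * pe)
  data.frame(mean_ovarioles = rpois(n, mu), father_pe_cn = pe,
             mother_genotype = sample(c("M", "P"), n, TRUE),
             temperature = sample(c(23, 29), n, TRUE))
}

test_that("multinomial fits recover symmetric and degenerate category probabilities", {
  rec30 <- data.frame(ovary_count = rep(c(0, 1, 2), each = 10))
  fit <- fit_multinomial(rec30, ovary_count ~ 1)
  p <- predict(fit$fit, newdata = rec30[1, , drop = FALSE], type = "probs")
  expect_true(all(abs(p - 1 / 3) < 1e-4))
  expect_false(fit$separation)
  # all females healthy: separation detected and flagged, P(2) -> 1
  rec2 <- data.frame(ovary_count = rep(2, 30))
  rec2$ovary_count <- factor(rec2$ovary_count, levels = c("2", "0", "1"))
  fit2 <- fit_multinomial(rec2, ovary_count ~ 1)
  expect_true(fit2$separation)
  p2 <- predict(fit2$fit, newdata = rec2[1, , drop = FALSE], type = "probs")
  expect_gt(p2["2"], 0.99)
})

test_that("poisson fit matches closed-form intercept and rejects empty data", {
  rec <- data.frame(mean_ovarioles = rep(20, 50))
  fit <- fit_poisson(rec, mean_ovarioles ~ 1)
  expect_equal(unname(coef(fit$fit)), log(20), tolerance = 1e-6)
  expect_error(fit_poisson(data.frame(mean_ovarioles = rep(NA_real_, 5)),
                           mean_ovarioles ~ 1), "no usable")
  # atrophied females (missing response) are dropped
  rec$mean_ovarioles[1:10] <- NA
  expect_equal(fit_poisson(rec, mean_ovarioles ~ 1)$n, 40)
})

test_that("rounding modes differ as documented", {
  expect_equal(round_ovarioles(c(18.5, 18.4)), c(19L, 18L))
  expect_equal(round_ovarioles(c(18.5, 18.4), "up"), c(19L, 19L))
})

test_that("likelihood-ratio test matches per-record log-likelihood arithmetic", {
  rec <- sim_pois_records(20, b_pe = -0.03, seed = 70)
  full <- fit_poisson(rec, mean_ovarioles ~ father_pe_cn)
  red <- fit_poisson(rec, mean_ovarioles ~ 1)
  lr <- lrt(full, red)
  # oracle: chi2 from per-record Poisson log-probabilities
  y <- round(rec$mean_ovarioles)
  ll <- function(mu) sum(dpois(y, mu, log = TRUE))
  chi2_oracle <- 2 * (ll(fitted(full$fit)) - ll(fitted(red$fit)))
  expect_equal(lr$chi2, chi2_oracle, tolerance = 1e-8)
  expect_equal(lr$df, 1)
  # independent implementation agreement
  lo <- lmtest::lrtest(full$fit, red$fit)
  expect_equal(lr$chi2, lo$Chisq[2], tolerance = 1e-8)
  expect_equal(lr$p, lo$`Pr(>Chisq)`[2], tolerance = 1e-8)
  # identical models and the chi-square tail sanity point
  same <- lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 0.001)
  expect_error(lrt(red, full), "nested")
})

test_that("type-III term table respects marginality", {
  rec <- sim_pois_records(300, b_pe = -0.02, seed = 71)
  f <- mean_ovarioles ~ mother_genotype * father_pe_cn
  tab <- type3_terms(rec, f, family = "poisson")
  expect_equal(tab$term, c("mother_genotype", "father_pe_cn",
                           "mother_genotype:father_pe_cn"))
  expect_false(any(tab$deletable[1:2]))
  expect_true(tab$deletable[3])
  expect_true(all(is.na(tab$p[1:2])))
  # single-term model: the one row equals lrt against intercept-only
  t1 <- type3_terms(rec, mean_ovarioles ~ father_pe_cn, family = "poisson")
  lr <- lrt(fit_poisson(rec, mean_ovarioles ~ father_pe_cn),
            fit_poisson(rec, mean_ovarioles ~ 1))
  expect_equal(t1$chi2, lr$chi2, tolerance = 1e-8)
  expect_equal(nrow(t1), 1)
})

test_that("stepwise simplification drops null interactions but keeps real main effects", {
  kept_main <- 0; dropped_int <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 400
    pe <- runif(n, 0, 20)
    mg <- sample(c("M", "P"), n, TRUE)
    mu <- exp(log(20) - 0.02 * pe)  # main effect only, no interaction
    rec <- data.frame(mean_ovarioles = rpois(n, mu), father_pe_cn = pe,
                      mother_genotype = mg)
    fit <- stepwise_simplify(rec,
                             mean_ovarioles ~ mother_genotype * father_pe_cn,
                             family = "poisson")
    if ("father_pe_cn" %in% fit$terms) kept_main <- kept_main + 1
    if (!"mother_genotype:father_pe_cn" %in% fit$terms)
      dropped_int <- dropped_int + 1
  }
  expect_gte(kept_main, 19)
  expect_gte(dropped_int, 15)
  # intercept-only truth reduces to intercept-only most of the time
  reduced <- 0
  for (s in 1:10) {
    rec <- sim_pois_records(300, b_pe = 0, seed = 720 + s)
    fit <- stepwise_simplify(rec, mean_ovarioles ~ father_pe_cn,
                             family = "poisson")
    if (length(fit$terms) == 0) reduced <- reduced + 1
  }
  expect_gte(reduced, 8)
})

test_that("fisher-pitman exact p equals brute-force enumeration", {
  # independent oracle: centred mean-difference over all label assignments
  fp_oracle <- function(x, y) {
    a <- c(x, y); n1 <- length(x); N <- length(a)
    md <- function(ix) abs(mean(a[ix]) - mean(a[-ix]))
    obs <- md(seq_len(n1))
    sets <- combn(N, n1)
    mean(apply(sets, 2, md) >= obs - 1e-12)
  }
  set.seed(72)
  for (i in 1:5) {
    x <- rnorm(4, 1); y <- rnorm(5)
    got <- fisher_pitman(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, fp_oracle(x, y), tolerance = 1e-12)
  }
  # constant data: p = 1
  expect_equal(fisher_pitman(rep(3, 4), rep(3, 5))$p, 1)
  # strong shift is detected decisively
  set.seed(73)
  big <- fisher_pitman(rnorm(50, 5), rnorm(50), n_permutations = 5000,
                       seed = 74)
  expect_lt(big$p, 0.001)
  expect_error(fisher_pitman(rnorm(20), rnorm(20), n_permutations = 50),
               "at least 100")
  expect_lt(HD_ALPHA, 0.05 / 6 + 1e-12)
})

test_that("senescence comparison recovers slope differences between crosses", {
  # identical decline in both crosses: contrast near zero
  set.seed(75)
  age <- rep(c(4, 9, 14, 19, 24, 29), each = 80)
  n <- length(age)
  make <- function(slope_b) {
    cross <- rep(c("MxM", "MxP"), n / 2)
    slope <- ifelse(cross == "MxM", -0.004, slope_b)
    data.frame(age = age, cross = cross,
               mean_ovarioles = rpois(n, exp(log(20) + slope * age)))
  }
  eq <- senescence_compare(make(-0.004))
  expect_lt(abs(diff(eq$slopes$slope)), 0.004)
  expect_gt(eq$lrt$p, 0.001)
  # one cross senescing twice as fast at the study's scale of 1920 records
  set.seed(76)
  age <- rep(c(4, 9, 14, 19, 24, 29), each = 320)
  n <- length(age)
  fast <- senescence_compare(make(-0.010))
  expect_lt(fast$lrt$p, 0.05)
  expect_lt(fast$slopes$slope[fast$slopes$cross == "MxP"],
            fast$slopes$slope[fast$slopes$cross == "MxM"])
  expect_error(senescence_compare(
    data.frame(age = 4, cross = c("a", "b"), mean_ovarioles = 20)),
    "2 ages")
})

test_that("deviance explained follows its definition on a hand-checked instance", {
  rec <- data.frame(mean_ovarioles = c(18, 22, 19, 21, 25, 15, 20, 20, 24, 16),
                    father_pe_cn = c(0, 2, 4, 6, 8, 10, 12, 14, 16, 18))
  fit <- fit_poisson(rec, mean_ovarioles ~ father_pe_cn)
  # hand-computed deviances from the Poisson deviance formula
  y <- rec$mean_ovarioles
  dev <- function(mu) 2 * sum(y * log(y / mu) - (y - mu))
  null_dev <- dev(mean(y))
  res_dev <- dev(fitted(fit$fit))
  expect_equal(dsquared(fit), (null_dev - res_dev) / null_dev,
               tolerance = 1e-8)
  # intercept-only fit explains nothing
  f0 <- fit_poisson(rec, mean_ovarioles ~ 1)
  expect_equal(dsquared(f0), 0, tolerance = 1e-12)
})

test_that("bootstrap D-squared comparison is null on identical inputs and detects real differences", {
  # same records and model on both sides: the two bootstrap distributions
  # estimate the same quantity, so the median difference is negligible
  # relative to the bootstrap spread
  rec <- sim_pois_records(300, b_pe = -0.03, seed = 77)
  nullres <- bootstrap_r2_compare(rec, mean_ovarioles ~ father_pe_cn,
                                  rec, mean_ovarioles ~ father_pe_cn,
                                  n_boot = 120, n_permutations = 400,
                                  seed = 78)
  expect_lt(abs(nullres$observed), sd(nullres$d2_a))
  expect_gt(nullres$p, 0.01)
  expect_length(nullres$d2_a, 120)
  # clearly different explanatory power
  strong <- sim_pois_records(200, b_pe = -0.08, seed = 79)
  weak <- sim_pois_records(200, b_pe = 0, seed = 80)
  alt <- bootstrap_r2_compare(strong, mean_ovarioles ~ father_pe_cn,
                              weak, mean_ovarioles ~ father_pe_cn,
                              n_boot = 120, n_permutations = 400,
                              seed = 81)
  expect_lt(alt$p, 0.01)
  expect_gt(median(alt$d2_a), median(alt$d2_b))
  expect_error(bootstrap_r2_compare(a, mean_ovarioles ~ 1, b,
                                    mean_ovarioles ~ 1, n_boot = 10),
               "n_boot")
})

test_that("parameter recovery: fitted coefficients fall within two standard errors", {
  # multinomial with known logits
  set.seed(82)
  n <- 2000
  pe <- runif(n, 0, 20)
  b0_true <- c(-3, 0.12)   # logit of 0 ovaries: intercept, pe slope
  b1_true <- c(-2, 0.05)
  l0 <- b0_true[1] + b0_true[2] * pe
  l1 <- b1_true[1] + b1_true[2] * pe
  den <- 1 + exp(l0) + exp(l1)
  u <- runif(n)
  ov <- ifelse(u < exp(l0) / den, 0L, ifelse(u < (exp(l0) + exp(l1)) / den, 1L, 2L))
  rec <- data.frame(ovary_count = ov, father_pe_cn = pe)
  fit <- fit_multinomial(rec, ovary_count ~ father_pe_cn)
  sm <- summary(fit$fit)
  est <- coef(sm); se <- sm$standard.errors
  expect_lt(abs(est["0", "father_pe_cn"] - 0.12) /
              se["0", "father_pe_cn"], 2)
  expect_lt(abs(est["1", "father_pe_cn"] - 0.05) /
              se["1", "father_pe_cn"], 2)
  # poisson slope at the scale reported for copy-number effects
  rec2 <- sim_pois_records(1000, b_pe = -0.07, seed = 83)
  fit2 <- fit_poisson(rec2, mean_ovarioles ~ father_pe_cn)
  sm2 <- summary(fit2$fit)$coefficients
  expect_lt(abs(sm2["father_pe_cn", "Estimate"] - (-0.07)) /
              sm2["father_pe_cn", "Std. Error"], 2)
})

test_that("cross summaries count dysgenic females correctly", {
  rec <- data.frame(
    mother_genotype = rep("M", 50), father_pe_cn = 10, temperature = 29,
    ovary_count = c(rep(0, 4), rep(1, 6), rep(2, 40)),
    mean_ovarioles = c(rep(NA, 4), rpois(46, 20)))
  s <- hd_summary(rec)
  expect_equal(s$dysgenic_fraction, 0.2)
  expect_equal(s$n_ovary0, 4)
  expect_equal(s$father_class, "P")
  rec$ovary_count <- 2
  expect_equal(hd_summary(rec)$dysgenic_fraction, 0)
})
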