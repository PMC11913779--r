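test_that("irRECIST categories follow the response and progression thresholds", {
    r <- classifyResponse(bestChange = c(-100, -30, 5, 10, -29.9),
                          worstChange = c(-100, -30, 5, 25, 19.9))
    expect_equal(as.character(r$category),
                 c("irCR", "irPR", "irSD", "irPD", "irSD"))
    expect_equal(r$responder, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    # new lesions force progression; response takes precedence as BOR
    rl <- classifyResponse(bestChange = c(3, -45), newLesions = TRUE)
    expect_equal(as.character(rl$category), c("irPD", "irPR"))
    # clinical progression without scans is irPD; otherwise not assessable
    expect_warning(
        rn <- classifyResponse(bestChange = c(NA, NA),
                               clinicalProgression = c(TRUE, FALSE)),
        "not assessable")
    expect_equal(as.character(rn$category), c("irPD", NA))
})

test_that("clinical benefit requires 12 months of PFS", {
    cb <- classifyCB(c(9.3, 14, 6, 12), c(1, 0, 0, 1))
    expect_equal(as.character(cb),
                 c("NCB", "CB", "not assessable", "CB"))
    expect_equal(as.character(classifyCB(20, 0, excluded = TRUE)),
                 "not assessable")
    # pure function: identical inputs give identical labels
    expect_identical(classifyCB(c(3, 15), c(1, 0)),
                     classifyCB(c(3, 15), c(1, 0)))
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
    km <- kmEstimate(1:5, rep(1, 5))
    expect_equal(km$curve$surv, c(0.8, 0.6, 0.4, 0.2, 0))
    expect_equal(km$median, 3)
    kmC <- kmEstimate(c(2, 4, 7), c(0, 0, 0))
    expect_true(all(kmC$curve$surv == 1))
    expect_true(is.na(kmC$median))
    # 8 subjects, mixed censoring: hand-computed product-limit oracle
    tm <- c(1, 2, 2, 3, 5, 6, 8, 9)
    ev <- c(1, 1, 0, 1, 0, 1, 1, 0)
    km8 <- kmEstimate(tm, ev, riskTimes = c(2, 6))
    # manual: t=1 S=7/8; t=2 (1 event, 1 censored) S=7/8*6/7=0.75;
    # t=3 S=0.75*4/5=0.6; t=6 S=0.6*2/3=0.4; t=8 S=0.4*1/2=0.2
    manual <- c(7 / 8, 0.75, 0.6, 0.4, 0.2)
    expect_equal(km8$curve$surv[km8$curve$nEvent > 0], manual,
                 tolerance = 1e-12)
    expect_equal(km8$median, 6)
    expect_equal(km8$riskTable$nRisk, c(7, 3))
    expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
    # S(0) = 1 and the curve is non-increasing
    expect_true(all(diff(km8$curve$surv) <= 0))
})

test_that("log-rank is null on duplicated groups and powered under HR 3", {
    tm <- c(1, 2, 3, 4, 6, 8)
    ev <- c(1, 1, 0, 1, 1, 0)
    lr0 <- logrankTest(rep(tm, 2), rep(ev, 2),
                       rep(c("a", "b"), each = 6))
    expect_equal(lr0$chisq, 0, tolerance = 1e-12)
    expect_equal(lr0$pvalue, 1, tolerance = 1e-12)
    # invariance to label swap
    g <- rep(c("a", "b"), 6)
    l1 <- logrankTest(rep(tm, 2), rep(ev, 2), g)
    l2 <- logrankTest(rep(tm, 2), rep(ev, 2),
                      ifelse(g == "a", "b", "a"))
    expect_equal(l1$chisq, l2$chisq)
    expect_error(logrankTest(tm, ev, rep("a", 6)), "groups")
    # power: two exponential arms, HR = 3, n = 200/arm
    set.seed(17)
    rej <- mean(replicate(100, {
        t1 <- rexp(200, 1); t2 <- rexp(200, 3)
        logrankTest(c(t1, t2), rep(1, 400),
                    rep(c("a", "b"), each = 200))$pvalue < 0.05
    }))
    expect_gt(rej, 0.95)
})

test_that("Cox fits match an independent partial-likelihood maximizer", {
    set.seed(18)
    n <- 40
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n, exp(0.8 * x))
    tm <- tm + runif(n, 0, 1e-6)          # break ties
    ev <- rbinom(n, 1, 0.85)
    cf <- suppressWarnings(coxFit(tm, ev, data.frame(x = x), scale = FALSE))
    # independent oracle: maximize the (no-ties) Cox partial likelihood
    pl <- function(beta) {
        ord <- order(tm)
        to <- tm[ord]; eo <- ev[ord]; xo <- x[ord]
        ll <- 0
        for (i in seq_len(n)) {
            if (eo[i] == 1) {
                risk <- which(to >= to[i])
                ll <- ll + beta * xo[i] - log(sum(exp(beta * xo[risk])))
            }
        }
        ll
    }
    opt <- optimize(pl, c(-5, 5), maximum = TRUE)
    expect_equal(cf$beta, opt$maximum, tolerance = 1e-4)
    # HR equivariance: scaling the covariate rescales beta, p unchanged
    cf10 <- suppressWarnings(coxFit(tm, ev, data.frame(x = 10 * x),
                                    scale = FALSE))
    expect_equal(cf10$beta, cf$beta / 10, tolerance = 1e-8)
    expect_equal(cf10$pvalue, cf$pvalue, tolerance = 1e-8)
    expect_error(coxFit(tm, ev, data.frame(x = rep(1, n))), "constant")
    # under the null the rejection rate stays near alpha
    set.seed(19)
    rej <- mean(replicate(50, {
        xx <- rnorm(80); tt <- rexp(80, 0.3)
        suppressWarnings(coxFit(tt, rep(1, 80),
                                data.frame(x = xx))$pvalue) < 0.05
    }))
    expect_lt(rej, 0.2)
})

test_that("median splits and quadrants follow the documented tie rules", {
    s4 <- medianSplit(c(1, 2, 3, 4))
    expect_equal(as.character(s4), c("low", "low", "high", "high"))
    s3 <- medianSplit(c(1, 2, 3))
    expect_equal(as.character(s3), c("low", "low", "high"))
    set.seed(20)
    tmb <- rlnorm(200); tmc <- rlnorm(200)
    tm <- rexp(200, 0.1); ev <- rbinom(200, 1, 0.8)
    qa <- quadrantAnalysis(tmb, tmc, tm, ev)
    expect_equal(sum(table(qa$labels)), 200)
    expect_true(all(table(qa$labels) >= 30))   # ~ n/4 per quadrant
    # labels invariant to monotone transforms of each marker
    qa2 <- quadrantAnalysis(log(tmb), sqrt(tmc), tm, ev)
    expect_identical(qa$labels, qa2$labels)
    expect_warning(quadrantAnalysis(c(tmb[1:199], NA), tmc, tm, ev),
                   "excluding")
})

test_that("double-high quadrant lives longest when both effects are active", {
    wins <- 0L
    for (i in 1:20) {
        set.seed(400L + i)
        n <- 120
        tmc <- plogis(rnorm(n, qlogis(0.05), 1))
        tmb <- rlnorm(n, log(5), 0.8)
        z <- function(x) (x - mean(x)) / sd(x)
        rate <- 0.05 * exp(-0.97 * z(log10(tmc)) - 0.69 * z(tmb))
        tm <- rexp(n, rate)
        qa <- quadrantAnalysis(tmb, tmc, tm, rep(1, n))
        med <- qa$medians
        if (!anyNA(med$medianSurvival) &&
            med$medianSurvival[med$quadrant == qa$doubleHigh] ==
            max(med$medianSurvival)) wins <- wins + 1L
    }
    expect_gte(wins, 18L)
})

test_that("two-proportion z-test matches the pooled-variance formula", {
    eq <- twoProportionTest(5, 10, 10, 20)
    expect_equal(eq$z, 0)
    expect_equal(eq$pvalue, 1)
    tp <- twoProportionTest(8, 12, 5, 20)
    expect_equal(tp$z, 2.3236, tolerance = 1e-4)
    expect_equal(tp$pvalue, 0.0201, tolerance = 1e-2)
    # cross-check against the chi-squared equivalence in prop.test
    pt <- prop.test(c(8, 5), c(12, 20), correct = FALSE)
    expect_equal(tp$z^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(tp$pvalue, pt$p.value, tolerance = 1e-10)
    # antisymmetry
    sw <- twoProportionTest(5, 20, 8, 12)
    expect_equal(sw$z, -tp$z)
    expect_error(twoProportionTest(1, 0, 1, 2), "n >= 1")
    expect_error(twoProportionTest(5, 4, 1, 2), "\\[0, n\\]")
})

test_that("cell-type screening singles out the monocyte effect", {
    ref <- simulateSingleCellReference(smallConfig(seed = 55L))
    hits <- 0L
    for (i in 1:20) {
        cfg <- smallConfig(nPatients = 80L, seed = 500L + i,
                           hazardTMB = 0)
        co <- simulateCohort(cfg, ref)
        comp <- makeComposition(co$truth$rnaFraction)
        sc <- suppressWarnings(
            screenCellTypes(comp, co$outcomes$osMonths,
                            co$outcomes$osEvent))
        if (sc$cellType[1] == "Monocyte") hits <- hits + 1L
    }
    expect_gte(hits, 18L)
    # BH correction in the screen matches the closed-form step-up oracle
    set.seed(21)
    mono <- plogis(rnorm(40, -3))
    comp2 <- makeComposition(cbind(Monocyte = mono, Rest = 1 - mono))
    sc2 <- suppressWarnings(
        screenCellTypes(comp2, rexp(40, 0.1), rbinom(40, 1, 0.8)))
    expect_equal(sc2$fdr, bhOracle(sc2$pvalue), tolerance = 1e-12)
})
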