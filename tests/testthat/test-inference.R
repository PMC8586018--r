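test_that("ANOSIM statistic hits its definitional extremes", {
  # all between-pair distances larger than all within-pair distances: R = 1
  d <- matrix(10, 6, 6)
  d[1:3, 1:3] <- 1
  d[4:6, 4:6] <- 1
  diag(d) <- 0
  g <- rep(c("A", "B"), each = 3)
  expect_equal(anosim(d, g, n_perm = 99, seed = 1)$R, 1)

  # all distances equal: R = 0
  d0 <- matrix(1, 6, 6)
  diag(d0) <- 0
  expect_equal(anosim(d0, g, n_perm = 99, seed = 1)$R, 0)

  expect_error(anosim(d, c("A", "A", "A", "A", "A", "B"), 99, 1),
               "single member")
})

test_that("sampled ANOSIM p matches exhaustive enumeration on 6 individuals", {
  withr::with_seed(91, {
    for (r in 1:3) {
      x <- matrix(rnorm(12), 6, 2)
      x[4:6, ] <- x[4:6, ] + r - 1   # varying group separation
      d <- as.matrix(dist(x))
      g <- rep(c("A", "B"), each = 3)
      res <- anosim(d, g, n_perm = 999, seed = 5)
      exact <- exact_anosim_p(d, g)
      expect_equal(res$R, exact$R, tolerance = 1e-12)
      expect_lt(abs(res$p - exact$p), 0.06)
      expect_gte(res$p, 1 / 1000)
    }
  })
})

test_that("ANOSIM agrees with an independent implementation and is rank-invariant", {
  withr::with_seed(93, {
    x <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 1.5), 5, 2))
    d <- as.matrix(dist(x))
    g <- rep(c("A", "B"), each = 5)
    ours <- anosim(d, g, n_perm = 199, seed = 3)
    ref <- vegan::anosim(as.dist(d), g, permutations = 199)
    expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-10)

    # invariant to any strictly monotone transform of the distances
    mono <- anosim(sqrt(d) + d^2, g, n_perm = 199, seed = 3)
    expect_equal(mono$R, ours$R)
    expect_equal(mono$p, ours$p)

    # identical seed: identical p
    expect_equal(anosim(d, g, 199, seed = 3)$p, ours$p)
  })
})

test_that("pairwise ANOSIM covers all dyads and BH-adjusts step-up", {
  withr::with_seed(95, {
    x <- do.call(rbind, lapply(0:4, function(k) {
      matrix(rnorm(6, 3 * k), 3, 2)
    }))
    d <- as.matrix(dist(x))
    g <- rep(LETTERS[1:5], each = 3)
    tab <- pairwise_anosim(d, g, n_perm = 99, seed = 2)
    expect_equal(nrow(tab), choose(5, 2))
    expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))

    # single dyad: adjusted equals raw
    tab1 <- pairwise_anosim(d[1:6, 1:6], g[1:6], n_perm = 99, seed = 2)
    expect_equal(tab1$p_adj, tab1$p)
  })
})

test_that("BH step-up with monotonicity enforcement matches the worked example", {
  # step-up on m = 4: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  raw <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(raw, "BH"), rep(0.04, 4))
  # independent step-up oracle on random vectors
  withr::with_seed(97, {
    for (r in 1:5) {
      p <- runif(7)
      m <- length(p)
      o <- order(p, decreasing = TRUE)
      adj <- pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
      expect_equal(p.adjust(p, "BH"), adj)
    }
  })
})

test_that("dispersion homogeneity detects scale differences and agrees with PCoA reference", {
  withr::with_seed(99, {
    x <- rbind(matrix(rnorm(20, 0, 1), 10, 2),
               matrix(rnorm(20, 0, 4), 10, 2))  # one group 4x dispersed
    d <- as.matrix(dist(x))
    g <- rep(c("A", "B"), each = 10)
    res <- dispersion_homogeneity(d, g, n_perm = 999, seed = 4)
    expect_lt(res$p, 0.05)

    bd <- vegan::betadisper(as.dist(d), g, type = "centroid")
    expect_equal(unname(res$distances), unname(bd$distances),
                 tolerance = 1e-8)
    expect_equal(res$F, anova(bd)$`F value`[1], tolerance = 1e-8)

    # zero dispersion in every group: F undefined
    y <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
    dz <- as.matrix(dist(y))
    expect_error(dispersion_homogeneity(dz, rep(c("A", "B"), each = 5),
                                        99, 1), "undefined|failed")
  })
})

test_that("the GLMM reduces to IRLS logistic regression at zero random variance", {
  withr::with_seed(81, {
    n_ind <- 40
    n_per <- 12
    df <- data.frame(
      individual = rep(sprintf("b%02d", 1:n_ind), each = n_per),
      distance_km = runif(n_ind * n_per, 2, 40),
      sex = rep(sample(c("female", "male"), n_ind, TRUE), each = n_per),
      colony = rep(sample(c("A", "B"), n_ind, TRUE), each = n_per))
    eta <- 1.5 - 0.15 * df$distance_km + 0.3 * (df$sex == "male") -
      0.2 * (df$colony == "B")
    df$used <- rbinom(nrow(df), 1, plogis(eta))
    g1 <- fit_binomial_glmm(df, individual = "individual")
    g0 <- glm(used ~ distance_km + sex + colony, binomial, df)
    expect_lt(g1$ranvar, 1e-6)
    expect_lt(max(abs(g1$fixef - coef(g0))), 1e-3)

    df$used <- 0
    expect_error(fit_binomial_glmm(df, individual = "individual"),
                 "separation")
  })
})

test_that("likelihood-ratio tests: identical models and a strong effect", {
  withr::with_seed(83, {
    n_ind <- 30
    df <- data.frame(
      individual = rep(sprintf("b%02d", 1:n_ind), each = 10),
      distance_km = runif(n_ind * 10, 2, 40),
      sex = rep(sample(c("female", "male"), n_ind, TRUE), each = 10),
      colony = "A")
    df$used <- rbinom(nrow(df), 1,
                      plogis(2 - 0.2 * df$distance_km +
                               rep(rnorm(n_ind, 0, 0.5), each = 10)))
    h1 <- fit_binomial_glmm(df, individual = "individual")
    h0 <- fit_binomial_glmm(df, individual = "individual",
                            include_distance = FALSE)
    same <- lrt(h1, h1)
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)
    strong <- lrt(h0, h1)
    expect_equal(strong$df, 1)
    expect_lt(strong$p, 0.001)
    expect_error(lrt(h1, h0), "nested")
  })
})

test_that("conditional R-squared follows the latent-scale variance formula", {
  withr::with_seed(85, {
    n_ind <- 30
    df <- data.frame(
      individual = rep(sprintf("b%02d", 1:n_ind), each = 10),
      distance_km = runif(n_ind * 10, 2, 40),
      sex = "female", colony = "A")
    b <- rep(rnorm(n_ind, 0, 1.2), each = 10)
    df$used <- rbinom(nrow(df), 1, plogis(0.5 - 0.12 * df$distance_km + b))
    g <- fit_binomial_glmm(df, individual = "individual")
    # independent recomputation of the Nakagawa components
    X <- model.matrix(~distance_km, df)
    vf <- var(as.numeric(X %*% g$fixef))
    vr <- g$ranvar
    expect_equal(conditional_r2(g), (vf + vr) / (vf + vr + pi^2 / 3),
                 tolerance = 1e-10)
    expect_true(conditional_r2(g) > 0 && conditional_r2(g) < 1)

    # monotone in the random-effect variance at fixed fixed-effect variance
    g_lo <- g
    g_lo$ranvar <- 0.1
    g_hi <- g
    g_hi$ranvar <- 2
    expect_lt(conditional_r2(g_lo), conditional_r2(g_hi))
  })
})

test_that("the dispersion check is calibrated under the model and flags misfit", {
  withr::with_seed(87, {
    n_ind <- 40
    df <- data.frame(
      individual = rep(sprintf("b%02d", 1:n_ind), each = 12),
      distance_km = runif(n_ind * 12, 2, 40),
      sex = "female", colony = "A")
    df$used <- rbinom(nrow(df), 1,
                      plogis(1.2 - 0.12 * df$distance_km +
                               rep(rnorm(n_ind, 0, 0.6), each = 12)))
    g <- fit_binomial_glmm(df, individual = "individual")
    p_null <- overdispersion_check(g, n_sim = 200, seed = 3)
    expect_gt(p_null, 0.05)
    expect_lte(p_null, 1)
    expect_error(overdispersion_check(g, n_sim = 0), "n_sim")

    # events where the fitted gradient expects none inflate the Pearson
    # dispersion: small p
    p_floor <- 0.05 + 0.9 * plogis(4 - 0.35 * df$distance_km)
    df$used <- rbinom(nrow(df), 1, p_floor)
    g2 <- fit_binomial_glmm(df, individual = "individual")
    expect_lt(overdispersion_check(g2, n_sim = 200, seed = 3), 0.05)
  })
})

test_that("MRM recovers a noiseless linear relation exactly", {
  withr::with_seed(89, {
    n <- 12
    x <- matrix(runif(n * n), n, n)
    xp <- (x + t(x)) / 2
    diag(xp) <- 0
    y <- 3 + 2 * xp
    diag(y) <- 0
    res <- mrm(y, list(pred = xp), n_perm = 199, seed = 6)
    expect_equal(res$r_squared, 1, tolerance = 1e-12)
    expect_equal(res$coefficients$estimate,
                 c(3, 2), tolerance = 1e-10)
    expect_equal(res$p_F, 1 / 200)
    expect_equal(res$coefficients$p[2], 1 / 200)

    expect_error(mrm(y, list(ok = xp, bad = xp[1:5, 1:5]), 99, 1), "bad")
    # identical seed: identical permutation p
    res2 <- mrm(y + 0, list(pred = xp), n_perm = 199, seed = 6)
    expect_identical(res2$coefficients$p, res$coefficients$p)
  })
})

test_that("MRM recovers known coefficients with the expected significance pattern", {
  withr::with_seed(101, {
    n <- 40
    sym <- function(m) {
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    }
    dh <- sym(matrix(runif(n * n), n, n))
    dist_m <- sym(matrix(runif(n * n, 0, 40000), n, n))
    size_m <- sym(matrix(runif(n * n, 0, 4000), n, n))
    noise <- sym(matrix(rnorm(n * n, 0, 0.08), n, n))
    y <- 0.2 + 0.4 * dh + 2e-5 * dist_m + 0 * size_m + noise
    res <- mrm(y, list(size = size_m, separation = dist_m, dh = dh),
               n_perm = 199, seed = 8)
    cf <- res$coefficients
    expect_lt(cf$p[cf$term == "dh"], 0.05)
    expect_gt(cf$estimate[cf$term == "dh"], 0)
    expect_lt(cf$p[cf$term == "separation"], 0.05)
    expect_gt(cf$p[cf$term == "size"], 0.05)
  })
})

test_that("predictor matrices use Manhattan size and Euclidean separation", {
  colonies <- kongsfjorden_colonies()
  ind <- data.frame(individual_id = c("i1", "i2", "i3"),
                    colony_id = c("BLM", "OBS", "OBS"))
  pm <- build_predictor_matrices(ind, colonies, KONGS_CENTRE)
  # same-colony pair: both zero
  expect_equal(pm$size["i2", "i3"], 0)
  expect_equal(pm$separation["i2", "i3"], 0)
  # Blomstrand (908) vs Observasjonsholmen (141) breeding pairs
  expect_equal(pm$size["i1", "i2"], 767)
  # projected separation tracks the great-circle distance within 0.5%
  gc_m <- great_circle_km(c(colonies$lon[colonies$id == "BLM"],
                            colonies$lat[colonies$id == "BLM"]),
                          c(colonies$lon[colonies$id == "OBS"],
                            colonies$lat[colonies$id == "OBS"])) * 1000
  expect_equal(pm$separation["i1", "i2"], gc_m, tolerance = 5e-3)

  expect_error(build_predictor_matrices(
    data.frame(individual_id = "x", colony_id = "NOPE"), colonies,
    KONGS_CENTRE), "NOPE")
})
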