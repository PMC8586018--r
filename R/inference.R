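# Permutation and mixed-model inference for the segregation analysis:
# ANOSIM (global and pairwise with Benjamini-Hochberg correction),
# homogeneity of multivariate dispersion, the binomial GLMM of glacier-front
# use against colony-front distance, likelihood-ratio tests, conditional
# R-squared, a simulation-based dispersion check, and multiple regression on
# distance matrices.
#
# Every permutation engine uses the (1 + #{null >= observed}) / (1 + n_perm)
# estimator, so the smallest attainable p at 999 permutations is 0.001, and
# takes a mandatory seed.

.check_dist_matrix <- function(d, name = "dist") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(name, " must be square")
  if (max(abs(d - t(d))) > 1e-8) stop(name, " must be symmetric")
  d
}

.anosim_stat <- function(rk, within, n) {
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All off-diagonal distances are
#' ranked with midranks for ties;
#' `R = (mean between-rank - mean within-rank) / (n(n-1)/4)`, in
#' \[-1, 1\]. Significance by permuting group labels.
#'
#' @param dist symmetric dissimilarity matrix.
#' @param groups group label per row (>= 2 groups, each >= 2 members).
#' @param n_perm number of permutations, default 999.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `"anosim_result"`: `R`, `p`, `n_perm`, `groups`.
#' @export
anosim <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- .check_dist_matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) {
    stop("group(s) with a single member: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  lower <- lower.tri(d)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(d[lower])  # midranks for ties
  same <- outer(groups, groups, "==")
  obs <- .anosim_stat(rk[lower], same[lower], n)
  perm_ge <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      g <- sample(groups)
      sm <- outer(g, g, "==")
      .anosim_stat(rk[lower], sm[lower], n) >= obs
    }, TRUE))
  })
  structure(list(R = obs, p = (1 + perm_ge) / (1 + n_perm),
                 n_perm = n_perm, groups = groups),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<ANOSIM: R = %.3f, p = %.4g (%d permutations)>\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise ANOSIM over all group dyads with BH correction
#'
#' One ANOSIM per pair of groups, with Benjamini-Hochberg step-up adjusted
#' p-values over all dyads. Meant to follow a significant global test.
#' Dyads whose test fails (e.g. a single-member group) are reported with
#' `NA` and the error message; the rest proceed.
#'
#' @inheritParams anosim
#' @return data frame: `group1`, `group2`, `R`, `p`, `p_adj`, `note`.
#' @export
pairwise_anosim <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- .check_dist_matrix(dist)
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  pairs <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    g1 <- pairs[1, q]
    g2 <- pairs[2, q]
    idx <- which(groups %in% c(g1, g2))
    res <- tryCatch(
      anosim(d[idx, idx, drop = FALSE], groups[idx], n_perm,
             seed = seed + q),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(group1 = g1, group2 = g2, R = NA_real_, p = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(group1 = g1, group2 = g2, R = res$R, p = res$p, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("group1", "group2", "R", "p", "p_adj", "note")]
}

#' Homogeneity of multivariate dispersion
#'
#' Embeds the dissimilarity matrix by principal coordinates (negative
#' eigenvalues kept on imaginary axes, the standard split), measures each
#' point's distance to its group centroid in that space, and tests equality
#' of mean dispersion across groups with a one-way F statistic whose null
#' distribution comes from permuting group labels.
#'
#' @inheritParams anosim
#' @return list with `F`, `df` (between, within), `p`, `distances`.
#' @export
dispersion_homogeneity <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- .check_dist_matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-8
  pos <- ev$values > tol
  neg <- ev$values < -tol
  if (!any(pos)) stop("principal-coordinate embedding failed")
  U_pos <- ev$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev$values[pos]), sum(pos))
  U_neg <- if (any(neg)) {
    ev$vectors[, neg, drop = FALSE] %*% diag(sqrt(-ev$values[neg]), sum(neg))
  } else matrix(0, n, 0)
  centroid_dist <- function(g) {
    out <- numeric(n)
    for (gg in unique(g)) {
      idx <- which(g == gg)
      cp <- colMeans(U_pos[idx, , drop = FALSE])
      dp <- rowSums(sweep(U_pos[idx, , drop = FALSE], 2, cp)^2)
      dn <- 0
      if (ncol(U_neg)) {
        cn <- colMeans(U_neg[idx, , drop = FALSE])
        dn <- rowSums(sweep(U_neg[idx, , drop = FALSE], 2, cn)^2)
      }
      out[idx] <- sqrt(pmax(dp - dn, 0))
    }
    out
  }
  fstat <- function(z, g) {
    gm <- mean(z)
    means <- tapply(z, g, mean)
    ni <- table(g)
    ssb <- sum(ni * (means - gm)^2)
    ssw <- sum((z - means[g])^2)
    dfb <- length(ni) - 1
    dfw <- length(z) - length(ni)
    if (ssw <= 1e-10 * max(1, ssb)) {
      stop("zero within-group dispersion: F undefined")
    }
    (ssb / dfb) / (ssw / dfw)
  }
  z <- centroid_dist(groups)
  obs <- fstat(z, groups)
  perm_ge <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      g <- sample(groups)
      fstat(centroid_dist(g), g) >= obs
    }, TRUE))
  })
  list(F = obs, df = c(length(tab) - 1, n - length(tab)),
       p = (1 + perm_ge) / (1 + n_perm), distances = z)
}

#' Binomial GLMM of glacier-front use
#'
#' Fits `used ~ distance + sex + colony (+ distance:sex) + (1 | individual)`
#' with a logit link by Laplace approximation (adaptive Gauss-Hermite
#' quadrature available through `nAGQ`). Reference levels: female for sex,
#' first colony alphabetically. When the estimated random-intercept
#' variance is zero the fixed effects coincide with a plain logistic
#' regression.
#'
#' @param data data frame with columns `used` (0/1), `distance_km`, `sex`,
#'   `colony`, `individual` (or as remapped by the arguments below).
#' @param response,distance,sex,colony,individual column names.
#' @param interaction include the distance-by-sex interaction, default
#'   FALSE.
#' @param include_sex,include_colony drop terms for nested null models.
#' @param include_distance drop the distance term for its null model.
#' @param nAGQ quadrature points (1 = Laplace), default 1.
#' @return object of class `"glmm_result"`: `fixef`, `ranvar`
#'   (individual-intercept variance), `loglik`, `n`, `formula`, and the
#'   underlying `fit`.
#' @export
fit_binomial_glmm <- function(data, response = "used",
                              distance = "distance_km", sex = "sex",
                              colony = "colony", individual = "individual",
                              interaction = FALSE, include_sex = TRUE,
                              include_colony = TRUE, include_distance = TRUE,
                              nAGQ = 1) {
  y <- data[[response]]
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2) {
    stop("complete separation: all outcomes identical")
  }
  sx <- factor(data[[sex]])
  if ("female" %in% levels(sx)) sx <- stats::relevel(sx, ref = "female")
  data[[sex]] <- sx
  data[[colony]] <- factor(data[[colony]])
  terms <- character(0)
  if (include_distance) terms <- c(terms, distance)
  if (include_sex && nlevels(data[[sex]]) > 1) terms <- c(terms, sex)
  if (include_colony && nlevels(data[[colony]]) > 1) {
    terms <- c(terms, colony)
  }
  if (interaction && nlevels(data[[sex]]) > 1) {
    terms <- c(terms, paste0(distance, ":", sex))
  }
  if (!length(terms)) terms <- "1"
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + "),
                                 "+ (1 |", individual, ")"))
  fit <- lme4::glmer(fml, data = data, family = stats::binomial(),
                     nAGQ = nAGQ,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  vc <- lme4::VarCorr(fit)
  structure(list(
    fixef = lme4::fixef(fit),
    ranvar = as.numeric(vc[[individual]][1]),
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(data), formula = fml, fit = fit), class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat("<binomial GLMM:", deparse(x$formula), ">\n")
  print(round(x$fixef, 4))
  cat(sprintf("individual-intercept variance %.4f, loglik %.2f, n = %d\n",
              x$ranvar, x$loglik, x$n))
  invisible(x)
}

#' Likelihood-ratio test of nested models
#'
#' @param model_h0,model_h1 nested `"glmm_result"` fits on the same data
#'   (H0 inside H1).
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt <- function(model_h0, model_h1) {
  if (model_h0$n != model_h1$n) stop("models fitted to different data")
  df <- length(model_h1$fixef) - length(model_h0$fixef)
  if (df < 0) stop("H0 has more parameters than H1; models not nested")
  chi2 <- 2 * (model_h1$loglik - model_h0$loglik)
  if (chi2 < -1e-6) {
    stop("H1 log-likelihood below H0: optimization failure")
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Conditional R-squared of a binomial GLMM
#'
#' Nakagawa's latent-scale formula for a logit model:
#' `(var_fixed + var_random) / (var_fixed + var_random + pi^2 / 3)`, where
#' `var_fixed` is the variance of the fixed-effect linear predictor.
#'
#' @param glmm a `"glmm_result"`.
#' @return conditional R-squared in \[0, 1\].
#' @export
conditional_r2 <- function(glmm) {
  X <- lme4::getME(glmm$fit, "X")
  eta_fixed <- as.numeric(X %*% glmm$fixef)
  var_f <- stats::var(eta_fixed)
  var_r <- glmm$ranvar
  (var_f + var_r) / (var_f + var_r + pi^2 / 3)
}

#' Simulation-based dispersion check for a binomial GLMM
#'
#' Simulates response sets from the fitted model and compares the variance
#' of the observed Pearson residuals with its simulated distribution;
#' two-sided p by rank with the +1 convention. A small p signals over- or
#' under-dispersion relative to the fitted binomial mixed model.
#'
#' @param glmm a `"glmm_result"`.
#' @param n_sim number of simulated response sets, default 250.
#' @param seed RNG seed.
#' @return two-sided p-value.
#' @export
overdispersion_check <- function(glmm, n_sim = 250, seed = 1L) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  fit <- glmm$fit
  mu <- stats::fitted(fit)
  y <- lme4::getME(fit, "y")
  pearson_var <- function(yy) stats::var((yy - mu) / sqrt(mu * (1 - mu)))
  obs <- pearson_var(y)
  sims <- withr::with_seed(seed, {
    ys <- stats::simulate(fit, nsim = n_sim,
                          use.u = TRUE)
    vapply(ys, pearson_var, 0)
  })
  p_hi <- (1 + sum(sims >= obs)) / (1 + n_sim)
  p_lo <- (1 + sum(sims <= obs)) / (1 + n_sim)
  min(1, 2 * min(p_hi, p_lo))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the vectorized lower triangle of the response
#' matrix on those of the predictor matrices. Per-coefficient and overall-F
#' significance come from simultaneously permuting rows and columns of the
#' response matrix (predictors fixed) and refitting.
#'
#' @param response symmetric response matrix (e.g. the segregation matrix).
#' @param predictors named list of symmetric predictor matrices with the
#'   same dimension and ordering.
#' @param n_perm permutations, default 999.
#' @param seed RNG seed.
#' @return object of class `"mrm_result"`: `coefficients` (with permutation
#'   p per coefficient), `r_squared`, `F`, `p_F`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1L) {
  y_m <- .check_dist_matrix(response, "response")
  n <- nrow(y_m)
  preds <- lapply(seq_along(predictors), function(k) {
    nm <- names(predictors)[k]
    if (is.null(nm) || nm == "") nm <- paste0("X", k)
    p <- .check_dist_matrix(predictors[[k]], nm)
    if (nrow(p) != n) {
      stop("predictor matrix '", nm, "' dimension mismatch (",
           nrow(p), " vs ", n, ")")
    }
    p
  })
  nms <- names(predictors)
  if (is.null(nms)) nms <- paste0("X", seq_along(preds))
  nms[nms == ""] <- paste0("X", which(nms == ""))
  lower <- lower.tri(y_m)
  X <- cbind(intercept = 1, vapply(preds, function(p) p[lower],
                                   numeric(sum(lower))))
  colnames(X) <- c("intercept", nms)
  fit_ols <- function(yv) {
    f <- stats::lm.fit(X, yv)
    b <- f$coefficients
    rss <- sum(f$residuals^2)
    tss <- sum((yv - mean(yv))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    k <- ncol(X) - 1
    dfres <- length(yv) - ncol(X)
    Fv <- if (rss > 0) (r2 / k) / ((1 - r2) / dfres) else Inf
    list(b = b, r2 = r2, F = Fv)
  }
  obs <- fit_ols(y_m[lower])
  cnt_b <- rep(0, length(obs$b))
  cnt_F <- 0
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pr <- sample.int(n)
      yp <- y_m[pr, pr][lower]
      pm <- fit_ols(yp)
      cnt_b <- cnt_b + (abs(pm$b) >= abs(obs$b))
      cnt_F <- cnt_F + (pm$F >= obs$F)
    }
  })
  coefs <- data.frame(term = colnames(X), estimate = unname(obs$b),
                      p = (1 + cnt_b) / (1 + n_perm),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, r_squared = obs$r2, F = obs$F,
                 p_F = (1 + cnt_F) / (1 + n_perm), n_perm = n_perm),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("<MRM: R^2 = %.3f, F = %.2f, p = %.4g (%d permutations)>\n",
              x$r_squared, x$F, x$p_F, x$n_perm))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Individual-level predictor matrices for the MRM
#'
#' Colony-size difference (Manhattan / L1 distance on breeding pairs) and
#' colony separation (Euclidean distance between projected colony
#' centroids; zero for same-colony pairs) for every pair of individuals.
#'
#' @param individuals data frame with `individual_id` and `colony_id`.
#' @param colonies data frame with `id`, `lon`, `lat`, `size`.
#' @param centre projection centre `c(lon, lat)`.
#' @return list with `size` and `separation` matrices (individual ids as
#'   dimnames; separation in metres).
#' @export
build_predictor_matrices <- function(individuals, colonies, centre) {
  idx <- match(individuals$colony_id, colonies$id)
  if (anyNA(idx)) {
    stop("unknown colony id: ",
         paste(unique(individuals$colony_id[is.na(idx)]), collapse = ", "))
  }
  sizes <- colonies$size[idx]
  xy <- to_local_xy(cbind(colonies$lon, colonies$lat), centre)[idx, ,
                                                              drop = FALSE]
  ids <- individuals$individual_id
  size_m <- abs(outer(sizes, sizes, "-"))
  sep_m <- as.matrix(stats::dist(xy))
  dimnames(size_m) <- dimnames(sep_m) <- list(ids, ids)
  list(size = size_m, separation = sep_m)
}
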