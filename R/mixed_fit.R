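#' Per-probe linear mixed model with a random sow intercept
#'
#' Fits, by maximum likelihood, the model
#' \deqn{y = X\beta + S_{sow} + \varepsilon,\qquad
#'   S_k \sim N(0, \sigma^2_{sow}),\ \varepsilon \sim N(0, \sigma^2_e),}
#' the per-probe model of the reciprocal-cross analysis: fixed effects for
#' gestational age, fetal genotype and their interaction (or any nested
#' subset, or the parental-genotype term set) plus a random intercept shared
#' by littermates. The likelihood is profiled over the variance ratio
#' \eqn{\lambda = \sigma^2_{sow}/\sigma^2_e}: for fixed \eqn{\lambda} the
#' marginal covariance is block diagonal by sow, \eqn{V_0 = I + \lambda
#' Z Z^\top}, so data can be whitened in closed form
#' (\eqn{V_0^{-1/2}} shrinks each litter mean by
#' \eqn{(1+\lambda n_k)^{-1/2}}) and GLS reduces to OLS on the whitened
#' data. The profile is maximised over a dense grid on \eqn{\log\lambda}
#' (including the boundary \eqn{\lambda = 0}) followed by safeguarded
#' parabolic refinement.
#'
#' ML (not REML) is used throughout so that the same likelihoods feed both
#' the F-type tests and BIC comparisons across sub-models with different
#' fixed effects.
#'
#' @param y Numeric vector of log2 expression, aligned with `design` rows.
#' @param design A design tibble as returned by [complete_design()] (the
#'   `sow_id` column defines the random intercept).
#' @param fixed Fixed-effect structure: a one-sided formula in the design
#'   columns (e.g. `~ age * fetal_genotype`) or one of the shorthands
#'   `"full"` (age + genotype + interaction), `"additive"`, `"age"`,
#'   `"genotype"`, `"null"` (intercept only), `"parental"`
#'   (age + maternal + paternal genotypes, their pairwise interactions with
#'   age, and the maternal x paternal interaction).
#' @param estimator How the variance ratio is profiled: `"ml"` (default;
#'   the scale on which BIC sub-model comparisons are made) or `"reml"`
#'   (restricted likelihood, which removes the downward bias of the ML sow
#'   variance caused by the between-sow fixed effects; the F-testing
#'   routines use REML covariance estimates). The reported `loglik_ml` is
#'   always the ML profile log-likelihood evaluated at the selected ratio.
#' @return An object of class `mixed_fit`: a list with elements `beta`
#'   (named fixed-effect estimates, log2 units), `sigma2_sow`,
#'   `sigma2_resid` (variance components, log2^2 units), `lambda`
#'   (their ratio), `loglik_ml`, `n_params` (fixed-effect rank + 2 variance
#'   components), `rank`, `n`, `fitted`, `not_testable` (TRUE when the
#'   response is constant, in which case no test is meaningful), and the
#'   ingredients needed by [ftest_vs_reduced()].
#' @seealso [ftest_vs_reduced()], [bic()], [dge_test()] for the batched
#'   whole-matrix interface.
#' @examples
#' set.seed(1)
#' des <- simulate_design(sim_config(seed = 1))
#' y <- 8 + (des$age == "d110") + rnorm(nrow(des), sd = 0.5)
#' fit <- fit_mixed(y, des, fixed = ~ age * fetal_genotype)
#' glance(fit)
#' @export
fit_mixed <- function(y, design, fixed = ~ age * fetal_genotype,
                      estimator = c("ml", "reml")) {
  estimator <- match.arg(estimator)
  design <- as_tibble(design)
  if (length(y) != nrow(design)) {
    abort("length(y) must equal nrow(design)")
  }
  if (anyNA(y) || any(!is.finite(y))) abort("y must be finite and complete")
  X <- fixed_design_matrix(fixed, design)
  if (nrow(X) < ncol(X)) {
    abort("fewer observations than fixed-effect columns")
  }
  str <- sow_structure(design$sow_id)
  Y <- matrix(as.numeric(y), ncol = 1)

  if (sd(y) == 0) {
    # constant response: every model fits exactly, nothing is testable
    b <- lm.fit(X, Y[, 1])
    fit <- list(
      beta = coef_full(b, colnames(X)), sigma2_sow = 0, sigma2_resid = 0,
      lambda = 0, loglik_ml = Inf, rank = b$rank, n_params = b$rank + 2,
      n = length(y), fitted = b$fitted.values, rss = 0,
      not_testable = TRUE, X = X, y = Y[, 1], sow = str,
      formula = attr(X, "mn_formula"), xlevels = attr(X, "mn_xlevels"),
      design_frame = design
    )
    class(fit) <- "mixed_fit"
    return(fit)
  }

  mf <- fit_mixed_matrix(Y, X, str, criterion = estimator)
  fit <- list(
    estimator = estimator,
    beta = mf$beta[, 1],
    sigma2_sow = mf$sigma2_sow[1], sigma2_resid = mf$sigma2_resid[1],
    lambda = mf$lambda[1], loglik_ml = mf$loglik[1],
    rank = mf$rank, n_params = mf$rank + 2, n = length(y),
    fitted = drop(X %*% ifelse(is.na(mf$beta[, 1]), 0, mf$beta[, 1])),
    rss = mf$rss[1], not_testable = FALSE,
    X = X, y = Y[, 1], sow = str,
    formula = attr(X, "mn_formula"), xlevels = attr(X, "mn_xlevels"),
    design_frame = design
  )
  class(fit) <- "mixed_fit"
  fit
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed fit (ML), random sow intercept\n")
  cat(sprintf(
    "  n = %d, fixed rank = %d, loglik = %.4f\n", x$n, x$rank, x$loglik_ml
  ))
  cat(sprintf(
    "  sigma2_sow = %.4g, sigma2_resid = %.4g\n", x$sigma2_sow, x$sigma2_resid
  ))
  invisible(x)
}

# ---- fixed-effect design matrices -------------------------------------------

fixed_term_shorthands <- list(
  full     = ~ age * fetal_genotype,
  additive = ~ age + fetal_genotype,
  age      = ~ age,
  genotype = ~ fetal_genotype,
  null     = ~ 1,
  parental = ~ age + maternal_genotype + paternal_genotype +
    age:maternal_genotype + age:paternal_genotype +
    maternal_genotype:paternal_genotype
)

fixed_design_matrix <- function(fixed, design) {
  if (is.character(fixed)) {
    if (!fixed %in% names(fixed_term_shorthands)) {
      abort(paste0(
        "unknown fixed-term shorthand '", fixed, "'; use one of ",
        paste(names(fixed_term_shorthands), collapse = ", ")
      ))
    }
    fixed <- fixed_term_shorthands[[fixed]]
  }
  vars <- all.vars(fixed)
  missing_cols <- setdiff(vars, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  X <- model.matrix(fixed, data = design)
  attr(X, "mn_formula") <- fixed
  attr(X, "mn_xlevels") <- lapply(
    design[intersect(vars, names(design))],
    function(v) if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
  )
  X
}

coef_full <- function(lmfit, nm) {
  # lm.fit returns NA for aliased columns already in original order
  b <- lmfit$coefficients
  names(b) <- nm
  b
}

# ---- sow blocking structure -------------------------------------------------

sow_structure <- function(sow_id) {
  f <- factor(as.character(sow_id))
  idx <- as.integer(f)
  sizes <- tabulate(idx, nbins = nlevels(f))
  list(index = idx, sizes = sizes, k = nlevels(f), levels = levels(f))
}

# whiten columns of M by V0^{-1/2} for a scalar lambda:
# within each litter, x -> x + ((1 + lambda*n_k)^{-1/2} - 1) * litter_mean(x)
whiten_scalar <- function(M, str, lambda) {
  if (lambda == 0) return(M)
  gm <- rowsum(M, str$index, reorder = TRUE) / str$sizes
  shrink <- 1 / sqrt(1 + lambda * str$sizes) - 1
  M + shrink[str$index] * gm[str$index, , drop = FALSE]
}

logdet_v0 <- function(str, lambda) sum(log1p(lambda * str$sizes))

ll_from_rss <- function(rss, n, logdet) {
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) - logdet / 2
}

# ---- batched profile-ML fit -------------------------------------------------

default_lambda_grid <- function() c(0, exp(seq(-12, 8, by = 0.05)))

# profile objective for each probe (columns of Y) at its own lambda:
# the ML profile log-likelihood, or the REML criterion (which adds the
# -log|X' V^-1 X|/2 term and profiles sigma2 on n - p degrees of freedom)
pll_each <- function(lambda_vec, Y, X, str, rank, criterion = "ml") {
  n <- nrow(Y)
  gm_y <- rowsum(Y, str$index, reorder = TRUE) / str$sizes
  gm_x <- rowsum(X, str$index, reorder = TRUE) / str$sizes
  out <- numeric(ncol(Y))
  for (g in seq_len(ncol(Y))) {
    lam <- lambda_vec[g]
    shrink <- 1 / sqrt(1 + lam * str$sizes) - 1
    sv <- shrink[str$index]
    yw <- Y[, g] + sv * gm_y[str$index, g]
    Xw <- X + sv * gm_x[str$index, , drop = FALSE]
    f <- .lm.fit(Xw, yw)
    rss <- sum(f$residuals^2)
    if (criterion == "reml") {
      ldx <- sum(log(diag(f$qr)[seq_len(rank)]^2))
      out[g] <- -(n - rank) / 2 * log(rss) - logdet_v0(str, lam) / 2 - ldx / 2
    } else {
      out[g] <- ll_from_rss(rss, n, logdet_v0(str, lam))
    }
  }
  out
}

# Fit of every column of Y against the same X, profiling each probe's own
# variance ratio over a shared log-lambda grid, then refining by
# safeguarded parabolic interpolation. The ratio is chosen by the ML
# profile likelihood or by the REML criterion; reported log-likelihoods are
# always ML profile values at the selected ratio (so BIC comparisons stay
# on the ML scale), while REML-selected fits divide the whitened RSS by
# n - p when reporting variance components.
fit_mixed_matrix <- function(Y, X, str, grid = default_lambda_grid(),
                             refine_iter = 12L,
                             criterion = c("ml", "reml")) {
  criterion <- match.arg(criterion)
  n <- nrow(Y)
  ng <- ncol(Y)
  rank <- qr(X)$rank
  tgrid <- ifelse(grid == 0, -Inf, log(grid))

  ll <- matrix(NA_real_, nrow = length(grid), ncol = ng)
  for (i in seq_along(grid)) {
    Yw <- whiten_scalar(Y, str, grid[i])
    Xw <- whiten_scalar(X, str, grid[i])
    qrx <- qr(Xw)
    res <- qr.resid(qrx, Yw)
    rss <- colSums(res^2)
    if (criterion == "reml") {
      ldx <- sum(log(diag(qr.R(qrx))[seq_len(rank)]^2))
      ll[i, ] <- -(n - rank) / 2 * log(rss) -
        logdet_v0(str, grid[i]) / 2 - ldx / 2
    } else {
      ll[i, ] <- ll_from_rss(rss, n, logdet_v0(str, grid[i]))
    }
  }

  # prefer the smallest lambda among near-ties so that flat profiles
  # (e.g. one fetus per sow) collapse to sigma2_sow = 0
  best <- integer(ng)
  for (g in seq_len(ng)) {
    best[g] <- which(ll[, g] >= max(ll[, g]) - 1e-7)[1]
  }
  lambda_hat <- grid[best]
  interior <- which(best > 1L & best < length(grid))
  if (length(interior) > 0 && refine_iter > 0) {
    a <- tgrid[best[interior] - 1L]
    b <- tgrid[best[interior]]
    cc <- tgrid[best[interior] + 1L]
    fb <- ll[cbind(best[interior], interior)]
    # golden/parabolic refinement of t = log(lambda) within [a, c]
    fa <- ll[cbind(best[interior] - 1L, interior)]
    fc <- ll[cbind(best[interior] + 1L, interior)]
    for (it in seq_len(refine_iter)) {
      num <- (b - a)^2 * (fb - fc) - (b - cc)^2 * (fb - fa)
      den <- (b - a) * (fb - fc) - (b - cc) * (fb - fa)
      tstar <- ifelse(
        is.finite(num / den) & abs(den) > 0,
        b - 0.5 * num / den,
        (a + cc) / 2
      )
      # keep the probe strictly inside its bracket
      lo <- pmin(a, cc); hi <- pmax(a, cc)
      eps <- 1e-10 + 1e-8 * abs(b)
      tstar <- pmin(pmax(tstar, lo + eps), hi - eps)
      tstar <- ifelse(abs(tstar - b) < 1e-12, (lo + hi) / 2, tstar)
      fstar <- pll_each(exp(tstar), Y[, interior, drop = FALSE], X, str,
                        rank, criterion)
      left <- tstar < b
      take <- fstar >= fb
      # shrink the bracket around the better of (b, tstar)
      a_new <- ifelse(take, ifelse(left, a, b), ifelse(left, tstar, a))
      c_new <- ifelse(take, ifelse(left, b, cc), ifelse(left, cc, tstar))
      fa_new <- ifelse(take, ifelse(left, fa, fb), ifelse(left, fstar, fa))
      fc_new <- ifelse(take, ifelse(left, fb, fc), ifelse(left, fc, fstar))
      b_new <- ifelse(take, tstar, b)
      fb_new <- ifelse(take, fstar, fb)
      a <- a_new; cc <- c_new; b <- b_new
      fa <- fa_new; fc <- fc_new; fb <- fb_new
    }
    lambda_hat[interior] <- exp(b)
  }

  # final exact pass at lambda_hat: coefficients and whitened RSS
  gm_y <- rowsum(Y, str$index, reorder = TRUE) / str$sizes
  gm_x <- rowsum(X, str$index, reorder = TRUE) / str$sizes
  beta <- matrix(NA_real_, nrow = ncol(X), ncol = ng,
                 dimnames = list(colnames(X), colnames(Y)))
  rss <- numeric(ng)
  for (g in seq_len(ng)) {
    shrink <- 1 / sqrt(1 + lambda_hat[g] * str$sizes) - 1
    sv <- shrink[str$index]
    yw <- Y[, g] + sv * gm_y[str$index, g]
    Xw <- X + sv * gm_x[str$index, , drop = FALSE]
    f <- lm.fit(Xw, yw)
    beta[, g] <- f$coefficients
    rss[g] <- sum(f$residuals^2)
  }
  loglik <- ll_from_rss(rss, n, vapply(lambda_hat, function(l) {
    logdet_v0(str, l)
  }, numeric(1)))
  sigma2_resid <- rss / if (criterion == "reml") n - rank else n
  list(
    lambda = lambda_hat, loglik = loglik, rss = rss,
    sigma2_resid = sigma2_resid, sigma2_sow = lambda_hat * sigma2_resid,
    beta = beta, rank = rank, n = n, criterion = criterion
  )
}

# RSS of a reduced design under per-probe whitening at the full model's
# lambda (the GLS F-test numerator ingredient)
rss_at_lambda <- function(Y, Xred, str, lambda_vec) {
  gm_y <- rowsum(Y, str$index, reorder = TRUE) / str$sizes
  gm_x <- rowsum(Xred, str$index, reorder = TRUE) / str$sizes
  out <- numeric(ncol(Y))
  for (g in seq_len(ncol(Y))) {
    shrink <- 1 / sqrt(1 + lambda_vec[g] * str$sizes) - 1
    sv <- shrink[str$index]
    yw <- Y[, g] + sv * gm_y[str$index, g]
    Xw <- Xred + sv * gm_x[str$index, , drop = FALSE]
    out[g] <- sum(.lm.fit(Xw, yw)$residuals^2)
  }
  out
}

# ---- F-type test ------------------------------------------------------------

#' F-type test of a full mixed fit against a nested reduced model
#'
#' Compares two nested fixed-effect structures sharing the random sow
#' intercept. The data are whitened by the *full* model's estimated
#' covariance (its profiled variance ratio), and the classical
#' extra-sum-of-squares F statistic is computed on the whitened scale:
#' \deqn{F = \frac{(RSS_{red} - RSS_{full})/\Delta p}{RSS_{full}/(N - p_{full})}}
#' with p-value from the F distribution on \eqn{(\Delta p,\ N - p_{full})}
#' degrees of freedom (residual/containment convention). When the sow
#' variance is estimated at zero this reduces exactly to the ordinary
#' two-way ANOVA F test.
#'
#' @param full A `mixed_fit` for the full model.
#' @param reduced A `mixed_fit` for the reduced model, or a one-sided
#'   formula / shorthand (see [fit_mixed()]) describing its fixed effects;
#'   only its design matrix is used.
#' @return A one-row tibble: `F_stat`, `df_num`, `df_den`, `p_raw`,
#'   `not_testable`. A degenerate full fit (zero residual sum of squares)
#'   returns `not_testable = TRUE`; an empty term difference returns
#'   `F = 0, p = 1`.
#' @examples
#' des <- simulate_design(sim_config(seed = 2))
#' y <- 8 + (des$age == "d110") + rnorm(nrow(des), sd = 0.5)
#' full <- fit_mixed(y, des, "full")
#' ftest_vs_reduced(full, "null")
#' @export
ftest_vs_reduced <- function(full, reduced) {
  stopifnot(inherits(full, "mixed_fit"))
  if (inherits(reduced, "mixed_fit")) {
    Xred <- reduced$X
  } else {
    Xred <- fixed_design_matrix(reduced, stats_design_frame(full))
  }
  if (isTRUE(full$not_testable) || full$rss <= 0) {
    return(tibble(
      F_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
      p_raw = NA_real_, not_testable = TRUE
    ))
  }
  rank_red <- qr(Xred)$rank
  df_num <- full$rank - rank_red
  df_den <- full$n - full$rank
  if (df_num < 0) abort("reduced model must be nested in the full model")
  if (df_num == 0) {
    return(tibble(
      F_stat = 0, df_num = 0L, df_den = as.integer(df_den),
      p_raw = 1, not_testable = FALSE
    ))
  }
  rss_red <- rss_at_lambda(
    matrix(full$y, ncol = 1), Xred, full$sow, full$lambda
  )
  F_stat <- max(0, (rss_red - full$rss) / df_num) / (full$rss / df_den)
  tibble(
    F_stat = F_stat, df_num = as.integer(df_num),
    df_den = as.integer(df_den),
    p_raw = pf(F_stat, df_num, df_den, lower.tail = FALSE),
    not_testable = FALSE
  )
}

stats_design_frame <- function(fit) fit$design_frame

#' Bayesian information criterion of a mixed fit
#'
#' `BIC = -2 loglik_ML + k log(n)` with `k` = fixed-effect rank + 2 variance
#' components and `n` = number of fetuses (observations). Because both
#' variance components are present in every candidate sub-model, BIC
#' differences between sub-models reduce to their fixed-effect complexity.
#'
#' @param fit A `mixed_fit`.
#' @param n Sample size; defaults to the number of observations in the fit.
#' @return BIC value (smaller is better).
#' @export
bic <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "mixed_fit"))
  -2 * fit$loglik_ml + fit$n_params * log(n)
}
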