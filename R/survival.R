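#' Scale covariates for survival modelling
#'
#' Continuous covariates are z-scored (mean 0, SD 1); binary 0/1 covariates
#' are left as-is for interpretability unless `scale_all = TRUE`. Columns
#' with zero variance are dropped with a warning. The scaling parameters
#' are returned for back-transformation of coefficients.
#'
#' @param X numeric matrix or data.frame of covariates.
#' @param scale_all also z-score binary covariates.
#' @return List: `X` (scaled matrix), `center`, `scale` (per retained
#'   column; 0/1 for untouched columns), `dropped` (names).
#' @export
scale_covariates <- function(X, scale_all = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0) {
    warning("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  is_binary <- apply(X, 2, function(x) all(x %in% c(0, 1)))
  do_scale <- if (scale_all) rep(TRUE, ncol(X)) else !is_binary
  center <- ifelse(do_scale, colMeans(X), 0)
  scl <- ifelse(do_scale, apply(X, 2, stats::sd), 1)
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  list(X = Xs, center = stats::setNames(center, colnames(X)),
       scale = stats::setNames(scl, colnames(X)), dropped = dropped)
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function
#' as a table plus the median (first time at which the survival curve
#' drops to 0.5 or below; NA when the curve never reaches 0.5).
#'
#' @param time survival times (> 0).
#' @param event event indicators (TRUE = event, FALSE = censored).
#' @return List: `table` (time, n_risk, n_event, surv), `median`, `fit`
#'   (the underlying `survfit` object).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  below <- tab$time[tab$surv <= 0.5 + 1e-12]
  med <- if (length(below) > 0 && any(tab$n_event > 0)) min(below) else NA_real_
  if (all(tab$surv > 0.5)) med <- NA_real_
  list(table = tab, median = med, fit = fit)
}

# Negative penalized Weibull AFT log-likelihood and its gradient.
# theta = (b0, beta_1..p, log sigma); y = log t; penalty = lambda * ||beta||^2
# (intercept and shape unpenalized).
aft_negloglik <- function(theta, y, event, X, lambda) {
  p <- ncol(X)
  b0 <- theta[1]
  beta <- theta[seq_len(p) + 1]
  sigma <- exp(theta[p + 2])
  z <- (y - b0 - drop(X %*% beta)) / sigma
  ez <- exp(z)
  ll <- sum(event * (-log(sigma) + z) - ez)
  -ll + lambda * sum(beta^2)
}

aft_gradient <- function(theta, y, event, X, lambda) {
  p <- ncol(X)
  b0 <- theta[1]
  beta <- theta[seq_len(p) + 1]
  sigma <- exp(theta[p + 2])
  z <- (y - b0 - drop(X %*% beta)) / sigma
  g <- event - exp(z)
  # gradient of the NEGATIVE penalized log-likelihood
  gb0 <- sum(g) / sigma
  gbeta <- drop(crossprod(X, g)) / sigma + 2 * lambda * beta
  glogs <- sum(event + z * g)
  c(gb0, gbeta, glogs)
}

#' Penalized Weibull accelerated failure time regression
#'
#' Fits `log T = b0 + x' beta + sigma W` with `W` standard minimum Gumbel
#' (so `T` is Weibull with shape `k = 1/sigma`), by maximizing the
#' log-likelihood with an L2 (ridge) penalty `lambda * ||beta||^2` on the
#' covariate coefficients (intercept and shape unpenalized). Hazard ratios
#' use the Weibull AFT-PH equivalence `HR_j = exp(-k * beta_j)`; Wald
#' standard errors come from the inverse Hessian of the penalized
#' objective, and the AIC is computed from the unpenalized log-likelihood
#' at the penalized estimates.
#'
#' @param time survival times (> 0).
#' @param event event indicators.
#' @param X covariate matrix (scale first via [scale_covariates()]).
#' @param lambda L2 penalizer (>= 0).
#' @param report `"hr"` (hazard ratios via the PH conversion, default) or
#'   `"time_ratio"` (acceleration factors `exp(beta_j)`).
#' @return An `aft_fit` list: `coefficients` (log-time scale), `intercept`,
#'   `sigma`, `shape`, `lambda`, `loglik` (unpenalized), `aic`, `se`,
#'   `table` (data.frame: covariate, coef, se, effect estimate + 95% CI on
#'   the chosen scale, p), `converged`.
#' @export
fit_weibull_aft <- function(time, event, X, lambda = 0,
                            report = c("hr", "time_ratio")) {
  report <- match.arg(report)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(all(time > 0), lambda >= 0, nrow(X) == length(time))
  event <- as.numeric(event)
  if (sum(event) < 2) stop("need at least 2 events to fit the AFT model")
  y <- log(time)
  p <- ncol(X)
  theta0 <- c(mean(y), rep(0, p), log(max(stats::sd(y), 0.1)))
  opt <- stats::optim(theta0, aft_negloglik, gr = aft_gradient,
                      y = y, event = event, X = X, lambda = lambda,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("Weibull AFT fit did not converge (optim code ",
         opt$convergence, ")")
  }
  theta <- opt$par
  H <- stats::optimHess(theta, aft_negloglik, gr = aft_gradient,
                        y = y, event = event, X = X, lambda = lambda)
  cov <- tryCatch(solve(H), error = function(e) {
    warning("singular Hessian; standard errors unavailable ",
            "(possible separation)")
    matrix(NA_real_, length(theta), length(theta))
  })
  se <- sqrt(pmax(diag(cov), 0))
  beta <- theta[seq_len(p) + 1]
  sigma <- exp(theta[p + 2])
  k <- 1 / sigma
  # log-likelihood on the time scale (include the d log t Jacobian for
  # events), matching the usual parametric-survival convention
  ll <- -aft_negloglik(theta, y, event, X, lambda = 0) - sum(event * y)
  n_par <- p + 2
  se_beta <- se[seq_len(p) + 1]
  zstat <- beta / se_beta
  pval <- 2 * stats::pnorm(-abs(zstat))
  ci_lo_b <- beta - stats::qnorm(0.975) * se_beta
  ci_hi_b <- beta + stats::qnorm(0.975) * se_beta
  if (report == "hr") {
    est <- exp(-k * beta)
    lo <- exp(-k * ci_hi_b)
    hi <- exp(-k * ci_lo_b)
    eff <- "hr"
  } else {
    est <- exp(beta)
    lo <- exp(ci_lo_b)
    hi <- exp(ci_hi_b)
    eff <- "time_ratio"
  }
  tab <- data.frame(covariate = colnames(X), coef = beta, se = se_beta,
                    estimate = est, ci_lo = lo, ci_hi = hi, p = pval,
                    stringsAsFactors = FALSE)
  names(tab)[names(tab) == "estimate"] <- eff
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 intercept = theta[1], sigma = sigma, shape = k,
                 lambda = lambda, loglik = ll,
                 aic = 2 * n_par - 2 * ll,
                 se = stats::setNames(se_beta, colnames(X)),
                 table = tab, report = report,
                 converged = TRUE),
            class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("<aft_fit> Weibull AFT, shape ", formatC(x$shape, digits = 3),
      ", penalizer ", x$lambda, ", AIC ", formatC(x$aic, digits = 6),
      "\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' Select the L2 penalizer by AIC
#'
#' Fits the Weibull AFT model at each penalizer in the grid and returns the
#' one minimizing AIC, where the AIC is computed with the unpenalized
#' log-likelihood at the penalized estimates. Ties break to the smallest
#' penalizer; grid order is irrelevant.
#'
#' @param time,event,X as in [fit_weibull_aft()].
#' @param grid penalizer grid (default `c(0, 0.001, 0.01, 0.1, 1)`).
#' @param report effect scale, see [fit_weibull_aft()].
#' @return List: `lambda` (selected), `fit` (the winning `aft_fit`),
#'   `aic_path` (data.frame lambda x AIC).
#' @export
select_penalizer <- function(time, event, X,
                             grid = c(0, 0.001, 0.01, 0.1, 1),
                             report = "hr") {
  stopifnot(length(grid) >= 1)
  grid <- sort(unique(grid))
  fits <- lapply(grid, function(l) {
    tryCatch(fit_weibull_aft(time, event, X, lambda = l, report = report),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("every penalized fit failed")
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  lam_ok <- grid[ok]
  best <- which(aics <= min(aics) + 1e-9)[1] # ties -> smallest lambda
  list(lambda = lam_ok[best], fit = fits[ok][[best]],
       aic_path = data.frame(lambda = lam_ok, aic = aics))
}

#' Multivariate survival analysis of a cohort
#'
#' Builds the standard covariate set (MSI clonality in FFPE and LB,
#' IHC-vs-genomic discordance, age, sex, metastatic disease, primary
#' detection method), scales continuous covariates, drops patients with
#' any missing covariate (listwise), selects the penalizer by AIC and fits
#' the Weibull AFT model.
#'
#' @param cohort an [msi_cohort()] (needs a `primary_method` column for
#'   the detection-method covariate; otherwise that covariate is omitted).
#' @param grid penalizer grid.
#' @param report effect scale.
#' @return List: `fit`, `lambda`, `aic_path`, `n_used`, `km` (overall
#'   Kaplan-Meier), `scaling`.
#' @export
cohort_survival_analysis <- function(cohort,
                                     grid = c(0, 0.001, 0.01, 0.1, 1),
                                     report = "hr") {
  m <- ratings_matrix(cohort)
  disc <- apply(m, 1, function(r)
    discordance_flag(r["IHC"], r[c("PCR", "NGS_FFPE", "NGS_LB")]))
  X <- data.frame(
    clonality_ffpe = cohort$clonality_ffpe,
    clonality_lb = cohort$clonality_lb,
    discordance = as.numeric(disc),
    age = cohort$age,
    sex_female = as.numeric(cohort$sex == "female"),
    metastatic = as.numeric(cohort$stage == "IV"))
  if (!is.null(cohort$primary_method)) {
    X$method_ihc <- as.numeric(cohort$primary_method == "IHC")
  }
  keep <- stats::complete.cases(X)
  if (sum(keep) < ncol(X) + 3) {
    stop("too few complete cases (", sum(keep), ") for the multivariate model")
  }
  sc <- scale_covariates(X[keep, , drop = FALSE])
  sel <- select_penalizer(cohort$pfs_time[keep], cohort$event[keep], sc$X,
                          grid = grid, report = report)
  list(fit = sel$fit, lambda = sel$lambda, aic_path = sel$aic_path,
       n_used = sum(keep),
       km = kaplan_meier(cohort$pfs_time, cohort$event),
       scaling = sc[c("center", "scale", "dropped")])
}
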