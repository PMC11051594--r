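#' @keywords internal
#' Joint negative log-likelihood of the zero-inflated Gaussian model.
#' Each observation is an exact zero with probability pi (logit-linear in
#' the zi covariates) or, with probability 1 - pi, Gaussian with mean X beta
#' and variance sigma^2.  With AR(1), consecutive non-zero observations
#' within a group are correlated phi^|dt| (gap-aware Markov conditioning,
#' exact for a stationary AR(1)); the zero component carries no
#' correlation.
zig_nll_factory <- function(y, X, Z, group, times, ar1) {
  zeros <- y == 0
  p <- ncol(X)
  q <- if (is.null(Z)) 0L else ncol(Z)
  glist <- split(seq_along(y), group)
  function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1L])
    phi <- if (ar1) tanh(theta[p + 2L]) else 0
    gamma <- if (q) theta[(p + 1L + ar1 + 1L):(p + 1L + ar1 + q)] else NULL
    mu <- drop(X %*% beta)
    ll <- 0
    if (q) {
      eta <- drop(Z %*% gamma)
      ll <- sum(stats::plogis(eta[zeros], log.p = TRUE)) +
        sum(stats::plogis(-eta[!zeros], log.p = TRUE))
    }
    for (ix in glist) {
      ix <- ix[order(times[ix])]
      nz <- ix[!zeros[ix]]
      if (!length(nz)) next
      if (!ar1 || length(nz) == 1L || phi == 0) {
        ll <- ll + sum(stats::dnorm(y[nz], mu[nz], sigma, log = TRUE))
      } else {
        ll <- ll + stats::dnorm(y[nz[1L]], mu[nz[1L]], sigma, log = TRUE)
        for (k in 2:length(nz)) {
          i <- nz[k]; j <- nz[k - 1L]
          r <- phi^(times[i] - times[j])
          ll <- ll + stats::dnorm(y[i], mu[i] + r * (y[j] - mu[j]),
                                  sigma * sqrt(1 - r^2), log = TRUE)
        }
      }
    }
    -ll
  }
}

zig_fit <- function(formula, data, zi_formula = ~1, ar1 = FALSE,
                    group = "ceeNum", times = "times") {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  zeros <- y == 0
  zi_unident <- FALSE
  Z <- NULL
  if (!is.null(zi_formula)) {
    if (!any(zeros)) {
      warning("no exact zeros in the response; zero-inflation part is ",
              "unidentifiable, fitting a plain Gaussian model",
              call. = FALSE)
      zi_unident <- TRUE
    } else {
      Z <- stats::model.matrix(zi_formula, data)
      if (nrow(Z) != n) stop("zi covariates do not match the data",
                             call. = FALSE)
    }
  }
  if (all(zeros)) stop("response is identically zero", call. = FALSE)
  grp <- if (ar1) {
    if (!group %in% names(data)) stop("missing group column `", group, "`",
                                      call. = FALSE)
    as.character(data[[group]])
  } else rep("g", n)
  tms <- if (ar1) {
    if (!times %in% names(data)) stop("missing times column `", times, "`",
                                      call. = FALSE)
    as.numeric(data[[times]])
  } else seq_len(n)

  nll <- zig_nll_factory(y, X, Z, grp, tms, ar1)

  nzi <- which(!zeros)
  beta0 <- tryCatch(stats::coef(stats::lm.fit(X[nzi, , drop = FALSE],
                                              y[nzi])),
                    error = function(e) rep(0, ncol(X)))
  beta0[is.na(beta0)] <- 0
  res0 <- y[nzi] - drop(X[nzi, , drop = FALSE] %*% beta0)
  start <- c(beta0, log(max(stats::sd(res0), 1e-3)))
  if (ar1) start <- c(start, 0)
  if (!is.null(Z)) {
    g0 <- tryCatch(
      stats::coef(stats::glm.fit(Z, as.numeric(zeros),
                                 family = stats::binomial())),
      error = function(e) rep(0, ncol(Z)))
    g0[is.na(g0)] <- 0
    start <- c(start, g0)
  }

  opt <- stats::nlminb(start, nll, control = list(iter.max = 500,
                                                  eval.max = 1000))
  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(V) && all(diag(V) > 0)) sqrt(diag(V)) else
    rep(NA_real_, length(opt$par))

  p <- ncol(X); q <- if (is.null(Z)) 0L else ncol(Z)
  est <- opt$par
  sigma <- exp(est[p + 1L])
  phi <- if (ar1) tanh(est[p + 2L]) else NA_real_
  phi_se <- if (ar1) (1 - phi^2) * se[p + 2L] else NA_real_
  if (ar1 && is.finite(phi) && abs(phi) > 0.99)
    warning("AR(1) coefficient estimate at the boundary (|phi| ~ 1)",
            call. = FALSE)

  coef_tab <- data.frame(
    component = c(rep("cond", p), if (q) rep("zi", q)),
    term = c(colnames(X), if (q) colnames(Z)),
    estimate = c(est[seq_len(p)], if (q) est[(p + 1L + ar1 + 1L):
                                               (p + 1L + ar1 + q)]),
    se = c(se[seq_len(p)], if (q) se[(p + 1L + ar1 + 1L):
                                       (p + 1L + ar1 + q)]))
  coef_tab$z <- coef_tab$estimate / coef_tab$se
  coef_tab$p <- 2 * stats::pnorm(-abs(coef_tab$z))

  ll <- -opt$objective
  df <- length(est)
  structure(list(
    coefficients = coef_tab, sigma = sigma, sigma2 = sigma^2,
    phi = phi, phi_se = phi_se, logLik = ll, df = df,
    AIC = -2 * ll + 2 * df,
    converged = opt$convergence == 0 && all(is.finite(se)),
    n_obs = n, n_zero = sum(zeros), zi_unidentifiable = zi_unident,
    formula = formula,
    zi_formula = if (is.null(Z)) NULL else zi_formula,
    family = if (is.null(Z)) "gaussian" else "zi-gaussian",
    ar1 = ar1, nll = nll, par = est),
    class = "cee_fit")
}

#' Zero-inflated Gaussian model for ping-change records
#'
#' Maximum-likelihood fit of a mixture in which each observation is an exact
#' zero with probability `pi` (logit link, linear in the `zi_formula`
#' covariates) or Gaussian otherwise.  The per-second count differences
#' around pings are roughly normal but carry excess exact zeros (quiet
#' stretches where before and after counts tie), which this mixture
#' absorbs.  When the response contains no exact zeros, the zero-inflation
#' part is dropped with a warning and a plain Gaussian model is fitted
#' (whose coefficient estimates coincide with ordinary least squares).
#'
#' @param formula conditional model formula (e.g. `pingChange ~ ceeType +
#'   medWhist`).
#' @param data data frame of ping-change records with covariates.
#' @param zi_formula one-sided formula for the zero-inflation linear
#'   predictor (default `~ medWhist`); `NULL` disables zero inflation.
#' @return An object of class `cee_fit`: coefficient table (conditional and
#'   zero-inflation components, Wald `z`/two-sided `p`), `sigma`, `logLik`,
#'   `df`, `AIC` (= −2 logLik + 2 df), convergence flag, and sample sizes.
#' @export
fit_zi_gaussian <- function(formula, data, zi_formula = ~medWhist) {
  zig_fit(formula, data, zi_formula, ar1 = FALSE)
}

#' Zero-inflated Gaussian model with AR(1) correlation
#'
#' As [fit_zi_gaussian()], but successive *non-zero* observations within a
#' group (CEE) are correlated `phi^|dt|`, with `dt` the difference in the
#' ping order index — lag effects ripple through consecutive ping cycles.
#' The likelihood uses exact gap-aware AR(1) conditioning, so a group with a
#' single observation contributes exactly the marginal Gaussian term and the
#' model reduces to [fit_zi_gaussian()] when `phi = 0`.  Estimates of `phi`
#' near ±1 trigger a boundary warning.
#'
#' @inheritParams fit_zi_gaussian
#' @param group name of the grouping column (default `"ceeNum"`).
#' @param times name of the ordered within-group time index column (default
#'   `"times"`, the ping order).
#' @return A `cee_fit`, with `phi` and `phi_se` filled in.
#' @export
fit_zi_gaussian_ar1 <- function(formula, data, zi_formula = ~medWhist,
                                group = "ceeNum", times = "times") {
  zig_fit(formula, data, zi_formula, ar1 = TRUE, group = group,
          times = times)
}

#' Negative-binomial (mixed) model for period differences
#'
#' Wraps `glmmTMB` with the `nbinom2` family (log link; variance `mu +
#' mu^2 / theta`) for the broad-scale period-difference response.  The
#' response must be non-negative; non-integer values (medians of counts can
#' end in .5) are rounded half-to-even to counts, with a message, before
#' fitting.  Random intercepts (e.g. `(1 | ceeNum)`) are supported through
#' the formula.
#'
#' @param formula model formula, e.g. `periodDiff ~ ceeType`.
#' @param data data frame of period-difference records.
#' @return A `cee_fit`; `sigma` holds the overdispersion parameter, and the
#'   underlying `glmmTMB` fit is kept in `$fit`.
#' @export
fit_nb_glmm <- function(formula, data) {
  resp <- all.vars(formula)[1]
  y <- data[[resp]]
  if (any(y < 0)) stop("negative response values", call. = FALSE)
  if (any(y != round(y))) {
    message("rounding non-integer `", resp, "` values half-to-even for ",
            "the negative-binomial fit")
    data[[paste0(resp, "_raw")]] <- y
    data[[resp]] <- round(y)
  }
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(formula, data = data, family = glmmTMB::nbinom2()))
  sm <- summary(fit)
  ct <- sm$coefficients$cond
  coef_tab <- data.frame(component = "cond", term = rownames(ct),
                         estimate = ct[, 1], se = ct[, 2], z = ct[, 3],
                         p = ct[, 4], row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  df <- attr(stats::logLik(fit), "df")
  # a non-positive-definite Hessian with finite coefficient SEs is the
  # overdispersion parameter at its Poisson boundary (theta -> Inf), not a
  # failed fit; the fixed-effect Wald block is unaffected
  conv <- isTRUE(fit$fit$convergence == 0) && all(is.finite(ct[, 2]))
  if (!conv) warning("negative-binomial fit did not converge cleanly",
                     call. = FALSE)
  structure(list(
    coefficients = coef_tab, sigma = stats::sigma(fit),
    sigma2 = stats::sigma(fit), phi = NA_real_, phi_se = NA_real_,
    logLik = ll, df = df, AIC = -2 * ll + 2 * df, converged = conv,
    n_obs = stats::nobs(fit), n_zero = sum(y == 0),
    zi_unidentifiable = NA, formula = formula, zi_formula = NULL,
    family = "nbinom2", ar1 = FALSE, fit = fit), class = "cee_fit")
}

#' @export
print.cee_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cee_fit %s%s: logLik %.2f, AIC %.2f, df %d, n %d%s>\n",
              x$family, if (isTRUE(x$ar1)) " + ar1" else "",
              x$logLik, x$AIC, x$df, x$n_obs,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (isTRUE(x$ar1)) cat(sprintf("phi = %.3f (se %.3f)\n", x$phi, x$phi_se))
  invisible(x)
}

#' @export
logLik.cee_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
AIC.cee_fit <- function(object, ..., k = 2) -2 * object$logLik + k * object$df

#' Backward model selection by AIC or likelihood-ratio test
#'
#' Starting from the full fixed-effect term set, the term whose removal most
#' lowers the AIC is dropped, repeatedly.  With `criterion = "aic"`
#' (default) elimination stops when no removal lowers the AIC; with
#' `criterion = "lrt"` a term is droppable while its likelihood-ratio test
#' (chi-squared reference) is non-significant at `alpha`, the analysis-of-
#' variance flavour of backward elimination.  The AIC rule retains a truly
#' inert term with probability about P(chi2_1 > 2) = 0.16, so the stricter
#' LRT rule is the one to use when spurious retention matters.
#' Any candidate that fails to converge is skipped with a message.  The
#' result reports every fitted candidate in a model-comparison table
#' (conditional formula, zero-inflation formula, family, AIC, ΔAIC relative
#' to the best model, degrees of freedom, dispersion) plus likelihood-ratio
#' tests for each accepted nested drop.
#'
#' @param data data frame of records.
#' @param response response column name.
#' @param full_terms character vector of fixed-effect terms of the full
#'   model.
#' @param engine `"nb"` ([fit_nb_glmm()]), `"zi"` ([fit_zi_gaussian()]) or
#'   `"zi_ar1"` ([fit_zi_gaussian_ar1()]).
#' @param zi_formula zero-inflation formula for the `zi*` engines.
#' @param random optional random-effect / correlation terms appended
#'   verbatim to the formula and never dropped (e.g. `"(1 | ceeNum)"`).
#' @param group,times passed to [fit_zi_gaussian_ar1()].
#' @param criterion stopping rule, `"aic"` or `"lrt"`.
#' @param alpha significance level for the `"lrt"` rule.
#' @return A list of class `cee_selection`: `best` (the chosen `cee_fit`),
#'   `best_terms`, `table` (comparison table sorted by AIC), `lrt`
#'   (likelihood-ratio tests of the accepted drops), `fits`.
#' @export
backward_select <- function(data, response, full_terms,
                            engine = c("nb", "zi", "zi_ar1"),
                            zi_formula = ~medWhist, random = NULL,
                            group = "ceeNum", times = "times",
                            criterion = c("aic", "lrt"), alpha = 0.05) {
  engine <- match.arg(engine)
  criterion <- match.arg(criterion)
  fit_one <- function(terms) {
    rhs <- c(if (length(terms)) terms else "1", random)
    f <- stats::reformulate(rhs, response = response)
    switch(engine,
           nb = fit_nb_glmm(f, data),
           zi = fit_zi_gaussian(f, data, zi_formula),
           zi_ar1 = fit_zi_gaussian_ar1(f, data, zi_formula,
                                        group = group, times = times))
  }
  label <- function(terms) {
    paste(response, "~", paste(c(if (length(terms)) terms else "1",
                                 random), collapse = " + "))
  }
  fits <- list()
  record <- function(terms, fit) {
    fits[[label(terms)]] <<- list(terms = terms, fit = fit)
  }
  current <- full_terms
  cur_fit <- fit_one(current)
  record(current, cur_fit)
  lrt <- NULL
  repeat {
    if (!length(current)) break
    cand <- lapply(seq_along(current), function(i) {
      terms <- current[-i]
      f <- tryCatch(suppressWarnings(fit_one(terms)),
                    error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$converged)) {
        message("candidate dropping `", current[i],
                "` skipped (no convergent fit)")
        return(NULL)
      }
      list(dropped = current[i], terms = terms, fit = f)
    })
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) break
    if (criterion == "aic") {
      aics <- vapply(cand, function(z) z$fit$AIC, 0)
      k <- which.min(aics)
      accept <- aics[k] < cur_fit$AIC
    } else {
      ps <- vapply(cand, function(z) {
        ddf <- max(cur_fit$df - z$fit$df, 1L)
        stats::pchisq(max(2 * (cur_fit$logLik - z$fit$logLik), 0), ddf,
                      lower.tail = FALSE)
      }, 0)
      k <- which.max(ps)   # least significant term goes first
      accept <- ps[k] > alpha
    }
    if (!accept) {
      for (z in cand) record(z$terms, z$fit)
      break
    }
    ddf <- cur_fit$df - cand[[k]]$fit$df
    chisq <- 2 * (cur_fit$logLik - cand[[k]]$fit$logLik)
    lrt <- rbind(lrt, data.frame(
      dropped = cand[[k]]$dropped, chisq = max(chisq, 0), df = ddf,
      p = stats::pchisq(max(chisq, 0), ddf, lower.tail = FALSE)))
    for (z in cand) record(z$terms, z$fit)
    current <- cand[[k]]$terms
    cur_fit <- cand[[k]]$fit
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]$fit
    data.frame(conditional = nm,
               zi = if (is.null(f$zi_formula)) "none" else
                 deparse(f$zi_formula),
               family = paste0(f$family,
                               if (isTRUE(f$ar1)) " + ar1" else ""),
               AIC = f$AIC, df = f$df, dispersion = f$sigma2,
               converged = f$converged)
  }))
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  structure(list(best = cur_fit, best_terms = current, table = tab,
                 lrt = lrt, fits = fits), class = "cee_selection")
}

#' @export
print.cee_selection <- function(x, ...) {
  cat("Backward AIC selection; best model:\n  ",
      x$table$conditional[1], "\n", sep = "")
  print(x$table[, c("conditional", "zi", "family", "dAIC", "df",
                    "dispersion")], row.names = FALSE)
  invisible(x)
}

#' Two-sample t test (pooled or Welch)
#'
#' Unpaired two-sample t test comparing, e.g., per-CEE changepoint
#' differences between control and sonar experiments.  The default pooled
#' form has `df = n1 + n2 - 2`.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param var_equal `TRUE` (default) for the pooled-variance test, `FALSE`
#'   for Welch.
#' @return A list of class `cee_ttest`: group means, SDs and sizes, `t`,
#'   `df`, `p`.
#' @export
pooled_t_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two observations per group", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(
    mean_x = mean(x), mean_y = mean(y),
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    n_x = length(x), n_y = length(y),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, var_equal = var_equal), class = "cee_ttest")
}

#' @export
print.cee_ttest <- function(x, ...) {
  cat(sprintf("%s t test: t(%.4g) = %.3f, p = %.3g\n",
              if (x$var_equal) "Pooled" else "Welch", x$df, x$t, x$p))
  cat(sprintf("  group 1: mean %.3f, sd %.3f, n %d\n", x$mean_x, x$sd_x,
              x$n_x))
  cat(sprintf("  group 2: mean %.3f, sd %.3f, n %d\n", x$mean_y, x$sd_y,
              x$n_y))
  invisible(x)
}
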