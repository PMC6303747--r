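# Binomial logit mixed model with an observation-level random effect (OLRE).
#
# Model: y_i ~ Binomial(n_i, pi_i), logit(pi_i) = x_i' beta + sigma * u_i,
# u_i ~ N(0, 1) iid per observation. Because the random effect is
# observation-specific the marginal likelihood factorizes exactly into
# per-observation one-dimensional integrals,
#   L = prod_i  INT Binom(y_i | n_i, plogis(eta_i + sigma u)) phi(u) du,
# each evaluated by adaptive Gauss-Hermite quadrature centred at the
# conditional mode. An optional shared group intercept (e.g. generation) is
# handled by a Laplace approximation nested outside the OLRE integrals.
# The OLRE absorbs extra-binomial variation (overdispersion), restoring
# honest Wald inference on the fixed effects.

gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  gh_cache[[key]]
}

# Conditional mode and curvature of h(u) = log Binom(y|n, plogis(eta+s*u))
# + log phi(u), vectorized over observations. Damped Newton; h is strictly
# concave so this converges quickly.
olre_modes <- function(eta, sigma, y, n, max_iter = 30L, tol = 1e-10) {
  u <- rep(0, length(eta))
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta + sigma * u)
    g <- sigma * (y - n * mu) - u
    H <- -(sigma^2 * n * mu * (1 - mu) + 1)
    step <- g / H
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  mu <- stats::plogis(eta + sigma * u)
  list(u = u, neg_curv = sigma^2 * n * mu * (1 - mu) + 1)
}

#' Marginal log-likelihood of the OLRE binomial model
#'
#' Evaluates the exact-factorized marginal log-likelihood by per-observation
#' adaptive Gauss-Hermite quadrature (nodes centred and scaled at each
#' observation's conditional mode; log-sum-exp accumulation). With
#' `sigma = 0` it reduces exactly to the plain binomial log-likelihood.
#'
#' @param beta fixed-effect coefficients (logit scale).
#' @param log_sigma log of the OLRE standard deviation; `-Inf` for a plain
#'   binomial likelihood.
#' @param X design matrix.
#' @param y successes (second-male egg counts).
#' @param n binomial totals (eggs laid after the second mating).
#' @param n_nodes number of quadrature nodes (odd, >= 3; default 31).
#' @param offset optional per-observation offset added to the linear
#'   predictor (used internally for the shared group intercept).
#' @return the marginal log-likelihood (includes the binomial normalizing
#'   constant).
#' @export
olre_loglik <- function(beta, log_sigma, X, y, n, n_nodes = 31L,
                        offset = NULL) {
  if (n_nodes < 3 || n_nodes %% 2 == 0)
    stop("n_nodes must be odd and >= 3", call. = FALSE)
  if (any(n <= 0))
    stop("binomial totals must be positive", call. = FALSE)
  if (any(y > n) || any(y < 0))
    stop("successes must lie in [0, totals]", call. = FALSE)
  eta <- drop(X %*% beta)
  if (!is.null(offset)) eta <- eta + offset
  const <- sum(lchoose(n, y))
  sigma <- exp(log_sigma)
  if (sigma == 0) {
    mu <- stats::plogis(eta)
    return(const + sum(y * log(mu) + (n - y) * log1p(-mu)))
  }
  gh <- gh_nodes(n_nodes)
  md <- olre_modes(eta, sigma, y, n)
  tau <- 1 / sqrt(md$neg_curv)
  # u-grid: one row per observation, one column per node
  U <- outer(md$u, rep(1, n_nodes)) +
    sqrt(2) * tau %o% gh$x
  Eta <- eta + sigma * U
  # log integrand + log GH weight + node Jacobian, summed by log-sum-exp
  logf <- y * Eta - n * log1p(exp(Eta)) - U^2 / 2 - 0.5 * log(2 * pi)
  # guard the log1p(exp()) overflow for large Eta
  big <- Eta > 30
  if (any(big))
    logf[big] <- (y * Eta - n * Eta - U^2 / 2 - 0.5 * log(2 * pi))[big]
  logw <- matrix(log(gh$w) + gh$x^2, nrow(X), n_nodes, byrow = TRUE)
  M <- logf + logw
  mmax <- apply(M, 1, max)
  li <- mmax + log(rowSums(exp(M - mmax))) + log(sqrt(2) * tau)
  const + sum(li)
}

# per-group marginal loglik with a shared intercept v ~ N(0, sigma_g^2),
# integrated by Laplace outside the (analytically factorized) OLRE integrals
group_loglik <- function(beta, log_sigma, log_sigma_g, X, y, n, group,
                         n_nodes) {
  sigma_g <- exp(log_sigma_g)
  idx <- split(seq_along(y), group)
  total <- 0
  for (ix in idx) {
    q <- function(v)
      olre_loglik(beta, log_sigma, X[ix, , drop = FALSE], y[ix], n[ix],
                  n_nodes, offset = rep(v, length(ix))) +
        stats::dnorm(v, 0, sigma_g, log = TRUE)
    opt <- stats::optimize(q, interval = c(-6, 6) * max(sigma_g, 0.25),
                           maximum = TRUE)
    v0 <- opt$maximum
    h <- 1e-4
    curv <- (q(v0 + h) - 2 * opt$objective + q(v0 - h)) / h^2
    if (!is.finite(curv) || curv >= 0) curv <- -1 / sigma_g^2
    total <- total + opt$objective + 0.5 * log(2 * pi) - 0.5 * log(-curv)
  }
  total
}

#' Fit a binomial GLMM with an observation-level random effect
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood over
#' `(beta, log sigma)` by quasi-Newton (BFGS), starting from a plain
#' binomial fit and `sigma = 0.5`. Wald standard errors come from the
#' numerical Hessian at the optimum. The default model is the final paternity
#' model: `~ mating_order + interval_h` with an OLRE.
#'
#' @param data data frame of attributed paternity estimates (or any data with
#'   the response columns below).
#' @param fixed_terms character vector of predictor column names; categorical
#'   columns are dummy-coded with treatment contrasts.
#' @param successes,totals names of the response columns (defaults
#'   `"eggs_m2"`, `"eggs_total"`).
#' @param olre include the observation-level random effect (default TRUE;
#'   FALSE fits a plain binomial regression by the same optimizer).
#' @param shared_group optional name of a grouping column (e.g.
#'   `"generation"`) adding a shared random intercept via a nested Laplace
#'   approximation. Off by default.
#' @param n_nodes quadrature nodes (default 31).
#' @return a `glmm_fit`: list with `coef`, `se`, `z_stat`, `p_value`,
#'   `sigma_olre`, `sigma_group`, `loglik`, `aic`, `vcov`, `n_obs`,
#'   `converged`, `n_quad_nodes`, plus model metadata used by
#'   [marginal_means()].
#' @export
fit_olre_binomial_glmm <- function(data,
                                   fixed_terms = c("mating_order",
                                                   "interval_h"),
                                   successes = "eggs_m2",
                                   totals = "eggs_total",
                                   olre = TRUE,
                                   shared_group = NULL,
                                   n_nodes = 31L) {
  term_cols <- setdiff(fixed_terms, "1")
  miss <- setdiff(c(term_cols, successes, totals, shared_group),
                  names(data))
  if (length(miss))
    stop("column(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- data[[successes]]
  n <- data[[totals]]
  if (any(n <= 0)) stop("rows with zero totals must be removed",
                        call. = FALSE)
  mf <- data[term_cols]
  for (cl in term_cols)
    if (is.character(mf[[cl]]) || all(mf[[cl]] %in% c(0, 24, 48)) &&
        length(unique(mf[[cl]])) <= 3)
      mf[[cl]] <- factor(mf[[cl]])
  rhs <- if (length(term_cols)) paste(term_cols, collapse = " + ") else "1"
  form <- stats::as.formula(paste("~", rhs))
  trm <- stats::terms(form)
  X <- stats::model.matrix(trm, mf)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  xlev <- lapply(mf[vapply(mf, is.factor, logical(1))], levels)

  pnames <- colnames(X)
  k_beta <- ncol(X)
  start_glm <- stats::glm.fit(X, cbind(y, n - y),
                              family = stats::binomial())
  beta0 <- stats::coef(start_glm)

  if (!olre && is.null(shared_group)) {
    negll <- function(par) -olre_loglik(par, -Inf, X, y, n, n_nodes)
    par0 <- beta0
    trans <- function(par) list(beta = par, ls = -Inf, lsg = NULL)
  } else if (is.null(shared_group)) {
    negll <- function(par)
      -olre_loglik(par[seq_len(k_beta)], par[k_beta + 1], X, y, n, n_nodes)
    par0 <- c(beta0, log(0.5))
    trans <- function(par) list(beta = par[seq_len(k_beta)],
                                ls = par[k_beta + 1], lsg = NULL)
  } else {
    grp <- data[[shared_group]]
    ls_olre <- if (olre) NULL else -Inf
    negll <- function(par) {
      ls <- if (olre) par[k_beta + 1] else -Inf
      lsg <- par[k_beta + 1 + olre]
      -group_loglik(par[seq_len(k_beta)], ls, lsg, X, y, n, grp, n_nodes)
    }
    par0 <- c(beta0, if (olre) log(0.5), log(0.3))
    trans <- function(par) list(beta = par[seq_len(k_beta)],
                                ls = if (olre) par[k_beta + 1] else -Inf,
                                lsg = par[k_beta + 1 + olre])
  }

  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = FALSE)
  # the profile in log sigma flattens as sigma -> 0; if a line search
  # overshoots down that asymptote, restart from the best grid point
  if (olre && is.null(shared_group)) {
    for (pass in 1:2) {
      ls_grid <- seq(-3, 1.5, by = 0.25)
      prof <- vapply(ls_grid, function(ls)
        negll(c(opt$par[seq_len(k_beta)], ls)), numeric(1))
      if (min(prof) < opt$value - 1e-8) {
        opt <- stats::optim(c(opt$par[seq_len(k_beta)],
                              ls_grid[which.min(prof)]),
                            negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12))
      } else break
    }
  }
  opt$hessian <- stats::optimHess(opt$par, negll)
  est <- trans(opt$par)
  vcov_all <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  if (!all(is.finite(diag(vcov_all)[seq_len(k_beta)])) ||
      any(diag(vcov_all)[seq_len(k_beta)] <= 0)) {
    # near-boundary variance component: fall back to the beta block
    vb <- tryCatch(
      solve(opt$hessian[seq_len(k_beta), seq_len(k_beta), drop = FALSE]),
      error = function(e) matrix(NA_real_, k_beta, k_beta))
    vcov_all[seq_len(k_beta), seq_len(k_beta)] <- vb
  }
  vcov_beta <- vcov_all[seq_len(k_beta), seq_len(k_beta), drop = FALSE]
  dimnames(vcov_beta) <- list(pnames, pnames)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  beta <- stats::setNames(est$beta, pnames)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  loglik <- -opt$value
  k <- length(opt$par)
  if (any(abs(beta) > 15))
    warning("|beta| > 15: possible separation", call. = FALSE)

  fit <- list(
    coef = beta, se = stats::setNames(se, pnames),
    z_stat = stats::setNames(z, pnames),
    p_value = stats::setNames(pval, pnames),
    sigma_olre = if (is.finite(est$ls)) exp(est$ls) else 0,
    sigma_group = if (!is.null(est$lsg)) exp(est$lsg) else 0,
    loglik = loglik, aic = 2 * k - 2 * loglik,
    vcov = vcov_beta, n_obs = nrow(X),
    converged = opt$convergence == 0 && all(is.finite(se)),
    n_quad_nodes = as.integer(n_nodes),
    terms = trm, xlevels = xlev, fixed_terms = fixed_terms,
    model_frame = mf
  )
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial logit mixed model (observation-level random effect)\n")
  cat(sprintf("  n = %d, logLik = %.3f, AIC = %.2f, sigma_OLRE = %.3f%s\n",
              x$n_obs, x$loglik, x$aic, x$sigma_olre,
              if (x$sigma_group > 0)
                sprintf(", sigma_group = %.3f", x$sigma_group) else ""))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  tab <- data.frame(Estimate = x$coef, `Std.Error` = x$se,
                    z = x$z_stat, `p` = x$p_value,
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Ranks candidate fits by AIC and flags those within `delta` of the best
#' (conventionally, models within 2 AIC units are competitive).
#'
#' @param ... named fitted models with an `aic` element (e.g. `glmm_fit`s).
#' @param delta AIC window for "competitive" (default 2).
#' @return data frame sorted by AIC with `dAIC` and `competitive`.
#' @export
compare_aic <- function(..., delta = 2) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  out <- data.frame(model = names(fits), aic = aic)
  out <- out[order(out$aic), ]
  out$dAIC <- out$aic - out$aic[1]
  out$competitive <- out$dAIC < delta
  rownames(out) <- NULL
  out
}
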