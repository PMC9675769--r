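# Multinomial logit models of diel category (day / twilight / night) with
# protected-area random intercepts.
#
# Model: for event i in area a with covariate row x_i,
#   log(p_night/p_day)    = x_i' beta_n + b_n[a],  b_n[a] ~ N(0, sigma_n^2)
#   log(p_twilight/p_day) = x_i' beta_t + b_t[a],  b_t[a] ~ N(0, sigma_t^2)
# with independent intercepts across the two non-reference categories.
# The marginal likelihood integrates the per-area intercepts out with a
# Laplace approximation: the integrand factorises over areas, so each area
# contributes a 2-D mode found by damped Newton iteration (the conditional
# log-posterior is strictly concave). Estimation is plain ML; there is no
# standard REML analogue for this model, and the `stage` field records "ML".

DIEL_LEVELS <- c("day", "twilight", "night")

# aggregate event-level data to multinomial cells (unique covariate x area)
.mnl_cells <- function(data, formula) {
  y <- factor(data$diel_category, levels = DIEL_LEVELS)
  if (anyNA(y)) stop("diel_category must be day/twilight/night")
  tot <- table(y)
  if (any(tot == 0)) {
    stop("empty diel category: ", paste(names(tot)[tot == 0], collapse = ", "))
  }
  vars <- all.vars(formula)
  key <- if (length(vars)) {
    do.call(paste, c(data[c("protected_area", vars)], sep = "\r"))
  } else {
    as.character(data$protected_area)
  }
  first <- !duplicated(key)
  idx <- match(key, key[first])
  X <- stats::model.matrix(formula, data[first, , drop = FALSE])
  Y <- unname(as.matrix(table(factor(idx, levels = seq_len(sum(first))), y)))
  area <- factor(data$protected_area[first])
  list(X = X, Y = Y, area = area, ai = as.integer(area),
       xlevels = stats::.getXlevels(stats::terms(formula),
                                    stats::model.frame(formula, data)))
}

# Per-area mode of the conditional log-posterior (damped 2-D Newton; the
# objective is strictly concave so the iteration is safe) plus the
# quantities shared by the objective and its gradient. `cache` warm-starts
# the modes across optimizer evaluations.
.mnl_inner <- function(theta, X, Y, ai, A, cache, newton_tol = 1e-10) {
  p <- ncol(X)
  bn_f <- theta[seq_len(p)]
  bt_f <- theta[p + seq_len(p)]
  sn <- exp(theta[2 * p + 1]); st <- exp(theta[2 * p + 2])
  eta_n0 <- drop(X %*% bn_f)
  eta_t0 <- drop(X %*% bt_f)
  yd <- Y[, 1]; yt <- Y[, 2]; yn <- Y[, 3]
  N <- yd + yt + yn
  bn <- cache$bn; bt <- cache$bt
  scale_g <- max(N)
  for (it in seq_len(200)) {
    en <- exp(eta_n0 + bn[ai]); et <- exp(eta_t0 + bt[ai])
    D <- 1 + en + et
    pn <- en / D; pt <- et / D
    gn <- drop(rowsum(yn - N * pn, ai)) - bn / sn^2
    gt <- drop(rowsum(yt - N * pt, ai)) - bt / st^2
    if (max(abs(c(gn, gt))) < newton_tol * scale_g) break
    hnn <- drop(rowsum(N * pn * (1 - pn), ai)) + 1 / sn^2
    htt <- drop(rowsum(N * pt * (1 - pt), ai)) + 1 / st^2
    hnt <- -drop(rowsum(N * pn * pt, ai))
    det <- hnn * htt - hnt^2
    dbn <- (htt * gn - hnt * gt) / det
    dbt <- (hnn * gt - hnt * gn) / det
    step <- pmin(1, 2 / pmax(abs(dbn), abs(dbt)))  # damping for large steps
    bn <- bn + step * dbn
    bt <- bt + step * dbt
  }
  cache$bn <- bn; cache$bt <- bt
  en <- exp(eta_n0 + bn[ai]); et <- exp(eta_t0 + bt[ai])
  D <- 1 + en + et
  pn <- en / D; pt <- et / D
  wnn <- N * pn * (1 - pn); wtt <- N * pt * (1 - pt); wnt <- -N * pn * pt
  g11 <- drop(rowsum(wnn, ai)) + 1 / sn^2
  g22 <- drop(rowsum(wtt, ai)) + 1 / st^2
  g12 <- drop(rowsum(wnt, ai))
  list(p = p, sn = sn, st = st, bn = bn, bt = bt,
       eta_n = eta_n0 + bn[ai], eta_t = eta_t0 + bt[ai],
       yn = yn, yt = yt, N = N, pn = pn, pt = pt,
       wnn = wnn, wtt = wtt, wnt = wnt,
       g11 = g11, g12 = g12, g22 = g22, det = g11 * g22 - g12^2)
}

# negative Laplace-approximated marginal log-likelihood
.mnl_negll <- function(theta, X, Y, ai, A, cache) {
  s <- .mnl_inner(theta, X, Y, ai, A, cache)
  cond <- sum(s$yn * s$eta_n + s$yt * s$eta_t -
                s$N * log(1 + exp(s$eta_n) + exp(s$eta_t)))
  ll <- cond - sum(s$bn^2) / (2 * s$sn^2) - sum(s$bt^2) / (2 * s$st^2) -
    A * (log(s$sn) + log(s$st)) - 0.5 * sum(log(s$det))
  -ll
}

# exact analytic gradient of .mnl_negll: envelope term for the conditional
# likelihood plus the log-determinant correction, which needs the third
# derivatives of the multinomial log-likelihood and the implicit response of
# the per-area modes (db/dtheta = G^{-1} d2q/db dtheta).
.mnl_negll_grad <- function(theta, X, Y, ai, A, cache) {
  s <- .mnl_inner(theta, X, Y, ai, A, cache)
  p <- s$p
  pn <- s$pn; pt <- s$pt; N <- s$N
  # third-derivative cell weights
  c1 <- N * pn * (1 - pn) * (1 - 2 * pn)       # dwnn/deta_n
  c2 <- -N * pn * pt * (1 - 2 * pn)            # dwnn/deta_t = dwnt/deta_n
  c3 <- -N * pn * pt * (1 - 2 * pt)            # dwtt/deta_n = dwnt/deta_t
  c4 <- N * pt * (1 - pt) * (1 - 2 * pt)       # dwtt/deta_t
  rs <- function(v) drop(rowsum(v, ai))
  rsX <- function(v) rowsum(X * v, ai)
  U <- rsX(s$yn - N * pn); V <- rsX(s$yt - N * pt)
  WnnX <- rsX(s$wnn); WntX <- rsX(s$wnt); WttX <- rsX(s$wtt)
  C1X <- rsX(c1); C2X <- rsX(c2); C3X <- rsX(c3); C4X <- rsX(c4)
  C1s <- rs(c1); C2s <- rs(c2); C3s <- rs(c3); C4s <- rs(c4)
  # per-area inverse of G
  gi11 <- s$g22 / s$det; gi22 <- s$g11 / s$det; gi12 <- -s$g12 / s$det
  trace_term <- function(dG11, dG12, dG22) {
    gi11 * dG11 + 2 * gi12 * dG12 + gi22 * dG22
  }
  mode_shift <- function(r1, r2) {
    list(dbn = gi11 * r1 + gi12 * r2, dbt = gi12 * r1 + gi22 * r2)
  }
  grad <- numeric(2 * p + 2)
  for (j in seq_len(p)) {
    # night-category coefficient j: deta_n = x_j
    db <- mode_shift(-WnnX[, j], -WntX[, j])
    tr <- trace_term(C1X[, j] + C1s * db$dbn + C2s * db$dbt,
                     C2X[, j] + C2s * db$dbn + C3s * db$dbt,
                     C3X[, j] + C3s * db$dbn + C4s * db$dbt)
    grad[j] <- -(sum(U[, j]) - 0.5 * sum(tr))
    # twilight-category coefficient j: deta_t = x_j
    db <- mode_shift(-WntX[, j], -WttX[, j])
    tr <- trace_term(C2X[, j] + C1s * db$dbn + C2s * db$dbt,
                     C3X[, j] + C2s * db$dbn + C3s * db$dbt,
                     C4X[, j] + C3s * db$dbn + C4s * db$dbt)
    grad[p + j] <- -(sum(V[, j]) - 0.5 * sum(tr))
  }
  # variance parameters (on the log-sd scale)
  for (which_s in 1:2) {
    sig <- if (which_s == 1) s$sn else s$st
    b <- if (which_s == 1) s$bn else s$bt
    r1 <- if (which_s == 1) 2 * b / sig^3 else numeric(A)
    r2 <- if (which_s == 1) numeric(A) else 2 * b / sig^3
    db <- mode_shift(r1, r2)
    dG11 <- C1s * db$dbn + C2s * db$dbt
    dG12 <- C2s * db$dbn + C3s * db$dbt
    dG22 <- C3s * db$dbn + C4s * db$dbt
    if (which_s == 1) dG11 <- dG11 - 2 / sig^3 else dG22 <- dG22 - 2 / sig^3
    tr <- trace_term(dG11, dG12, dG22)
    dq <- sum(b^2) / sig^3
    grad[2 * p + which_s] <- -sig * (dq - A / sig - 0.5 * sum(tr))
  }
  grad
}

#' Fit a multinomial diel-activity model with protected-area random intercepts
#'
#' Fits `log(p_night/p_day)` and `log(p_twilight/p_day)` as linear functions
#' of the covariates in `formula` (typically guild, natural-log body mass and
#' their interaction), with an independent Gaussian random intercept per
#' protected area for each non-reference category, by Laplace-approximated
#' maximum likelihood. Day is the reference category, so the night equation's
#' coefficients read directly as nocturnality effects.
#'
#' @param data event-level data.frame with `diel_category` (values day /
#'   twilight / night), `protected_area`, and the covariates in `formula`
#'   (e.g. `guild`, `log_mass`).
#' @param formula one-sided covariate formula, default `~ log_mass * guild`.
#' @param epsilon convergence tolerance of the outer optimisation (relative
#'   tolerance passed to [stats::nlminb()]), default `1e-6`.
#' @return object of class `diel_model`: coefficient and SE matrices (rows
#'   `night`, `twilight`), fixed-effect covariance, random-intercept SDs,
#'   marginal log-likelihood, `AIC` (with `k` counting fixed effects plus the
#'   two variances), and prediction metadata.
#' @export
fit_diel_model <- function(data, formula = ~ log_mass * guild,
                           epsilon = 1e-6) {
  cells <- .mnl_cells(data, formula)
  X <- cells$X; Y <- cells$Y; ai <- cells$ai
  A <- nlevels(cells$area)
  p <- ncol(X)
  # fixed-effects initialiser / single-area fallback
  init_fit <- nnet::multinom(Y ~ X - 1, trace = FALSE, maxit = 400)
  beta0 <- unname(stats::coef(init_fit))            # 2 x p, rows twilight, night
  if (is.null(dim(beta0))) beta0 <- matrix(beta0, nrow = 2)
  if (any(abs(beta0) > 15)) {
    stop("fit is degenerate (complete separation in some covariate cell)")
  }
  lm_rng <- if ("log_mass" %in% names(data)) range(data$log_mass) else NULL
  if (A < 2) {
    warning("single protected area: random intercept not identifiable; ",
            "falling back to a fixed-effects multinomial fit")
    pr <- stats::fitted(init_fit)
    ll <- sum(Y * log(pmax(pr, 1e-300)))
    vc <- stats::vcov(init_fit)
    # nnet orders coefficients category-major in Y's column order (twi, night)
    se_all <- sqrt(diag(vc))
    coefm <- rbind(night = beta0[2, ], twilight = beta0[1, ])
    sem <- rbind(night = se_all[p + seq_len(p)], twilight = se_all[seq_len(p)])
    perm <- c(p + seq_len(p), seq_len(p))
    colnames(coefm) <- colnames(sem) <- colnames(X)
    return(structure(list(coefficients = coefm, se = sem,
                          vcov_fixed = vc[perm, perm],
                          sigma = c(night = NA_real_, twilight = NA_real_),
                          logLik = ll, k = 2 * p, AIC = 2 * (2 * p) - 2 * ll,
                          formula = formula, xlevels = cells$xlevels,
                          log_mass_range = lm_rng, n_events = nrow(data),
                          n_areas = A, stage = "ML", fixed_only = TRUE,
                          epsilon = epsilon, convergence = init_fit$convergence),
                     class = "diel_model"))
  }
  # centre/scale non-intercept columns for conditioning; M maps scaled
  # coefficients back to the original basis (beta = M beta_scaled)
  mns <- colMeans(X); sds <- apply(X, 2, stats::sd)
  intc <- which(colnames(X) == "(Intercept)")
  if (length(intc)) { mns[intc] <- 0; sds[intc] <- 1 }
  sds[sds < 1e-9] <- 1
  Xs <- sweep(sweep(X, 2, mns), 2, sds, "/")
  M <- diag(1 / sds, p)
  if (length(intc)) M[intc, ] <- -mns / sds + (seq_len(p) == intc)
  inits <- nnet::multinom(Y ~ Xs - 1, trace = FALSE, maxit = 400)
  b0s <- unname(stats::coef(inits))
  if (is.null(dim(b0s))) b0s <- matrix(b0s, nrow = 2)
  cache <- new.env()
  cache$bn <- numeric(A); cache$bt <- numeric(A)
  theta0 <- c(b0s[2, ], b0s[1, ], log(0.3), log(0.3))
  negll <- function(th) .mnl_negll(th, Xs, Y, ai, A, cache)
  grad <- function(th) .mnl_negll_grad(th, Xs, Y, ai, A, cache)
  opt <- stats::nlminb(theta0, negll, grad,
                       lower = c(rep(-50, 2 * p), -8, -8),
                       upper = c(rep(50, 2 * p), 3, 3),
                       control = list(iter.max = 1000, eval.max = 5000,
                                      rel.tol = min(epsilon, 1e-10)))
  H <- stats::optimHess(opt$par, negll, grad)
  vc_all <- tryCatch(solve(H), error = function(e) {
    warning("information matrix is singular; using pseudo-inverse for SEs")
    MASS::ginv(H)
  })
  fix_ix <- seq_len(2 * p)
  MM <- rbind(cbind(M, matrix(0, p, p)), cbind(matrix(0, p, p), M))
  vcf <- MM %*% vc_all[fix_ix, fix_ix, drop = FALSE] %*% t(MM)
  se <- sqrt(pmax(diag(vcf), 0))
  coefm <- rbind(night = drop(M %*% opt$par[seq_len(p)]),
                 twilight = drop(M %*% opt$par[p + seq_len(p)]))
  sem <- rbind(night = se[seq_len(p)], twilight = se[p + seq_len(p)])
  colnames(coefm) <- colnames(sem) <- colnames(X)
  ll <- -opt$objective
  k <- 2 * p + 2
  structure(list(coefficients = coefm, se = sem, vcov_fixed = vcf,
                 sigma = c(night = exp(opt$par[2 * p + 1]),
                           twilight = exp(opt$par[2 * p + 2])),
                 logLik = ll, k = k, AIC = 2 * k - 2 * ll,
                 formula = formula, xlevels = cells$xlevels,
                 log_mass_range = lm_rng, n_events = nrow(data),
                 n_areas = A, stage = "ML", fixed_only = FALSE,
                 epsilon = epsilon, convergence = opt$convergence,
                 ranef = cbind(night = cache$bn, twilight = cache$bt),
                 areas = levels(cells$area)),
            class = "diel_model")
}

#' @export
print.diel_model <- function(x, ...) {
  cat("Multinomial diel model (reference = day), stage:", x$stage, "\n")
  cat("formula:", deparse(x$formula), " | events:", x$n_events,
      "| areas:", x$n_areas, "\n")
  cat("logLik:", format(x$logLik), " AIC:", format(x$AIC), "\n")
  if (!x$fixed_only) {
    cat("random-intercept SD: night", signif(x$sigma[1], 3),
        ", twilight", signif(x$sigma[2], 3), "\n")
  }
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy coefficient table of a diel model
#' @param model a `diel_model`.
#' @return data.frame with `category`, `term`, `estimate`, `se`.
#' @export
coef_table <- function(model) {
  stopifnot(inherits(model, "diel_model"))
  data.frame(
    category = rep(rownames(model$coefficients), each = ncol(model$coefficients)),
    term = rep(colnames(model$coefficients), 2),
    estimate = as.vector(t(model$coefficients)),
    se = as.vector(t(model$se))
  )
}

#' Candidate model set for diel-activity selection
#'
#' The minimal nested set consistent with guild/mass model selection:
#' intercept-only, mass, guild, mass + guild, and mass x guild — each fitted
#' with the protected-area random intercepts.
#'
#' @return named list of one-sided formulas.
#' @export
candidate_set <- function() {
  list(intercept_only = ~1,
       mass = ~log_mass,
       guild = ~guild,
       mass_plus_guild = ~log_mass + guild,
       mass_by_guild = ~log_mass * guild)
}

#' Fit all candidate formulas
#'
#' Candidates whose fit is degenerate (e.g. complete separation in a sparse
#' guild x category cell) are dropped with a warning, mirroring the usual
#' practice of excluding non-converging models from the AIC ranking.
#'
#' @param data see [fit_diel_model()].
#' @param formulas named list of formulas, default [candidate_set()].
#' @param ... passed to [fit_diel_model()].
#' @return named list of `diel_model` fits (successful candidates only).
#' @export
fit_candidate_set <- function(data, formulas = candidate_set(), ...) {
  fits <- lapply(formulas, function(f) {
    tryCatch(fit_diel_model(data, f, ...), error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed)) {
    warning("dropping candidate model(s) that failed to fit: ",
            paste(sprintf("%s (%s)", names(fits)[failed],
                          vapply(fits[failed], conditionMessage, character(1))),
                  collapse = "; "))
  }
  if (all(failed)) stop("no candidate model could be fitted")
  fits[!failed]
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `diel_model` objects (>= 2).
#' @return data.frame sorted by AIC (ties broken by parameter count) with
#'   `model`, `k`, `logLik`, `AIC`, `dAIC` and `supported` (dAIC < 2, the
#'   conventional equal-support band).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("need at least two fitted models to rank")
  rk <- data.frame(model = names(fits),
                   k = vapply(fits, `[[`, numeric(1), "k"),
                   logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                   AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                   row.names = NULL)
  rk <- rk[order(rk$AIC, rk$k), , drop = FALSE]
  rk$dAIC <- rk$AIC - rk$AIC[1]
  rk$supported <- rk$dAIC < 2
  rownames(rk) <- NULL
  rk
}

#' Predicted diel-activity probabilities over a body-mass grid
#'
#' Probabilities come from the fixed-effects linear predictors at the
#' random-effect mode 0 (softmax over day/twilight/night, rows sum to 1);
#' 95% intervals come from `n_draws` draws of the coefficient vector from
#' its asymptotic normal sampling distribution (the delta method degrades
#' near 0 and 1). Masses outside the fitted range are flagged
#' `extrapolated`.
#'
#' @param model a `diel_model`.
#' @param guild guild label (scalar) used when the model contains `guild`.
#' @param mass_g numeric grid of body masses in grams.
#' @param level confidence level, default 0.95.
#' @param n_draws coefficient draws for the intervals, default 1000.
#' @param seed seed for the draws.
#' @return data.frame with `guild`, `mass_g`, `p_day`, `p_night`,
#'   `p_twilight`, their `_lo`/`_hi` bounds, and `extrapolated`.
#' @export
predict_probabilities <- function(model, guild = NULL, mass_g,
                                  level = 0.95, n_draws = 1000, seed = 1) {
  stopifnot(inherits(model, "diel_model"), all(mass_g > 0))
  vars <- all.vars(model$formula)
  nd <- data.frame(log_mass = log(mass_g))
  if ("guild" %in% vars) {
    if (is.null(guild)) stop("model contains guild; supply one")
    if (!guild %in% model$xlevels$guild) {
      stop("guild '", guild, "' absent from the fitted model")
    }
    nd$guild <- factor(guild, levels = model$xlevels$guild)
  }
  X <- stats::model.matrix(model$formula, nd, xlev = model$xlevels)
  p <- ncol(model$coefficients)
  # overflow-safe softmax over (0, eta_n, eta_t)
  softmax3 <- function(en, et) {
    m <- pmax(0, en, et)
    d0 <- exp(-m); dn <- exp(en - m); dt_ <- exp(et - m)
    D <- d0 + dn + dt_
    list(day = d0 / D, night = dn / D, twilight = dt_ / D)
  }
  pe <- softmax3(drop(X %*% model$coefficients["night", ]),
                 drop(X %*% model$coefficients["twilight", ]))
  pt_est <- cbind(day = pe$day, night = pe$night, twilight = pe$twilight)
  mu <- c(model$coefficients["night", ], model$coefficients["twilight", ])
  draws <- withr_seed(seed, MASS::mvrnorm(n_draws, mu, model$vcov_fixed))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lo <- hi <- matrix(NA_real_, nrow(X), 3,
                     dimnames = list(NULL, c("day", "night", "twilight")))
  en_d <- X %*% t(draws[, seq_len(p), drop = FALSE])        # grid x draws
  et_d <- X %*% t(draws[, p + seq_len(p), drop = FALSE])
  pd <- softmax3(en_d, et_d)
  for (j in c("day", "night", "twilight")) {
    qm <- t(apply(pd[[j]], 1, stats::quantile, probs = qs, names = FALSE))
    jj <- match(j, colnames(lo))
    lo[, jj] <- qm[, 1]; hi[, jj] <- qm[, 2]
  }
  extrap <- if (is.null(model$log_mass_range)) FALSE else
    log(mass_g) < model$log_mass_range[1] | log(mass_g) > model$log_mass_range[2]
  data.frame(guild = if (is.null(guild)) NA_character_ else guild,
             mass_g = mass_g,
             p_day = pt_est[, "day"], p_day_lo = lo[, "day"], p_day_hi = hi[, "day"],
             p_night = pt_est[, "night"], p_night_lo = lo[, "night"],
             p_night_hi = hi[, "night"],
             p_twilight = pt_est[, "twilight"], p_twilight_lo = lo[, "twilight"],
             p_twilight_hi = hi[, "twilight"],
             extrapolated = extrap)
}

#' Per-guild body-mass slopes of the night equation
#'
#' For a model containing `log_mass` (optionally interacting with `guild`),
#' returns each guild's total night-equation mass slope (base slope plus its
#' interaction term) with the standard error from the fixed-effect
#' covariance.
#'
#' @param model a `diel_model` fitted with `log_mass` in the formula.
#' @return data.frame with `guild`, `slope`, `se`.
#' @export
night_mass_slopes <- function(model) {
  stopifnot(inherits(model, "diel_model"))
  terms_ <- colnames(model$coefficients)
  if (!"log_mass" %in% terms_) stop("model has no log_mass term")
  p <- length(terms_)
  V <- model$vcov_fixed[seq_len(p), seq_len(p), drop = FALSE]  # night block
  beta <- model$coefficients["night", ]
  guilds <- if (is.null(model$xlevels$guild)) "(all)" else model$xlevels$guild
  out <- lapply(guilds, function(g) {
    w <- as.numeric(terms_ == "log_mass" |
                      terms_ == paste0("log_mass:guild", g) |
                      terms_ == paste0("guild", g, ":log_mass"))
    data.frame(guild = g, slope = sum(w * beta),
               se = sqrt(drop(t(w) %*% V %*% w)))
  })
  do.call(rbind, out)
}

#' Ratio of two nocturnality probabilities, reported to one decimal
#'
#' @param p_night_a,p_night_b probabilities in `(0, 1]`.
#' @return `round(p_night_a / p_night_b, 1)`.
#' @export
nocturnality_ratio <- function(p_night_a, p_night_b) {
  if (any(p_night_a <= 0 | p_night_a > 1) || any(p_night_b <= 0 | p_night_b > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  round(p_night_a / p_night_b, 1)
}
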