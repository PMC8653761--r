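#' Variance-component linear mixed models by maximum likelihood
#'
#' Fits a Gaussian linear mixed model with any number of random-intercept
#' grouping factors by full maximum likelihood (ML, not REML).  The model is
#' \deqn{y = X\beta + \sum_k Z_k u_k + e,\qquad u_k \sim N(0, \sigma^2_k I),
#' \quad e \sim N(0, \sigma^2_e I),}
#' the parameterization used throughout behavioural repeatability and
#' variance-partitioning studies.  Random terms are written in the formula as
#' `(1 | factor)`; nesting of one factor in another is expressed with the
#' interaction operator, e.g. `(1 | stimulus:year)` recodes stimulus levels as
#' (year, stimulus) pairs.
#'
#' Fixed effects and the residual variance are profiled out analytically, so
#' the numerical optimization runs only over the relative standard deviations
#' \eqn{\theta_k = \sigma_k/\sigma_e \ge 0}.  The optimizer (bounded
#' quasi-Newton via [stats::nlminb()]) is restarted from three fixed starting
#' points so that boundary solutions \eqn{\hat\sigma^2_k = 0} — common in song
#' data — are found reliably, and the fit is deterministic given the data.
#'
#' @param formula model formula with random intercepts in `lme4`-style
#'   `(1 | g)` notation, e.g. `rate ~ date + age + (1 | stimulus:year) + (1 | year)`.
#'   A formula without any `(1 | g)` term fits an ordinary Gaussian linear
#'   model by ML (used for reduced models in likelihood-ratio tests).
#' @param data a data frame containing all variables.
#' @param na.action how to treat missing values; the default drops incomplete
#'   rows listwise and records the number dropped in the fit
#'   (`$na.dropped`).
#' @param start optional numeric vector of starting values for the relative
#'   standard deviations, one per random factor; appended to the built-in
#'   multi-start set.
#' @param control a list from [vcmm_control()].
#'
#' @return an object of class `"vcmm"` with components `coefficients`,
#'   `varcomp` (named vector of variance components, residual last), `theta`,
#'   `logLik`, `deviance`, `fitted.values`, `residuals`, `ranef`,
#'   `converged`, `n`, `na.dropped` and the design information needed by
#'   [simulate.vcmm()], [vc_bootstrap()] and [cramers_v()].
#'
#' @seealso [varpart()] for the variance decomposition, [vc_bootstrap()] for
#'   parametric-bootstrap confidence intervals, [cramers_v()] for
#'   likelihood-ratio effect sizes.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(g = gl(10, 5))
#' d$y <- rnorm(10, sd = 1)[d$g] + rnorm(50, sd = 0.5)
#' fit <- vcmm(y ~ 1 + (1 | g), d)
#' varpart(fit)
#' @export
vcmm <- function(formula, data, na.action = stats::na.omit,
                 start = NULL, control = vcmm_control()) {
  cl <- match.call()
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("'formula' must be two-sided")
  bars <- .find_bars(formula[[3L]])
  fixed_rhs <- .drop_bars(formula[[3L]])
  if (is.null(fixed_rhs)) fixed_rhs <- 1
  fixed_formula <- stats::as.formula(
    call("~", formula[[2L]], fixed_rhs), env = environment(formula))

  group_exprs <- lapply(bars, function(b) {
    if (!identical(b[[2L]], 1) && !identical(b[[2L]], 1L))
      stop("only random intercepts '(1 | g)' are supported")
    b[[3L]]
  })
  group_names <- vapply(group_exprs, function(e) paste(deparse(e), collapse = ""),
                        character(1))

  all_rhs <- paste(c(deparse(fixed_rhs),
                     unlist(lapply(group_exprs, all.vars))), collapse = " + ")
  all_formula <- stats::as.formula(
    paste(deparse(formula[[2L]]), "~", all_rhs), env = environment(formula))

  n_in <- nrow(data)
  mf <- stats::model.frame(all_formula, data, na.action = na.action)
  na.dropped <- n_in - nrow(mf)
  if (nrow(mf) < 2L) stop("fewer than 2 complete observations")

  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  fixed_terms <- stats::terms(fixed_formula, data = mf)
  X <- stats::model.matrix(fixed_terms, mf)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design: collinear or redundant fixed terms")

  groups <- lapply(group_exprs, .eval_group, mf = mf)
  names(groups) <- group_names
  for (g in group_names)
    if (nlevels(groups[[g]]) < 2L)
      stop(sprintf("random factor '%s' has fewer than 2 levels", g))

  fit <- .vc_fit(X, y, groups, start = start, control = control)

  structure(c(fit, list(
    call = cl, formula = formula, fixed_formula = fixed_formula,
    terms = fixed_terms, xlevels = stats::.getXlevels(fixed_terms, mf),
    assign = attr(X, "assign"), model = mf,
    X = X, y = y, groups = groups, na.dropped = na.dropped)),
    class = "vcmm")
}

#' Control parameters for [vcmm()]
#'
#' @param rel.tol relative convergence tolerance passed to
#'   [stats::nlminb()].
#' @param iter.max,eval.max optimizer iteration/evaluation caps.
#' @param starts list of numeric starting values (relative SD scale) used for
#'   the deterministic multi-start; scalars are recycled over factors.
#' @return a list of class `"vcmm_control"`.
#' @export
vcmm_control <- function(rel.tol = 1e-10, iter.max = 500L, eval.max = 1000L,
                         starts = list(0.1, 1, 2)) {
  structure(list(rel.tol = rel.tol, iter.max = iter.max,
                 eval.max = eval.max, starts = starts),
            class = "vcmm_control")
}

# ---- formula machinery ------------------------------------------------------

.find_bars <- function(e) {
  if (!is.call(e)) return(list())
  if (identical(e[[1L]], as.name("|"))) return(list(e))
  if (identical(e[[1L]], as.name("(")) && length(e) == 2L)
    return(.find_bars(e[[2L]]))
  unlist(lapply(as.list(e)[-1L], .find_bars), recursive = FALSE)
}

.drop_bars <- function(e) {
  if (!is.call(e)) return(e)
  if (identical(e[[1L]], as.name("|"))) return(NULL)
  if (identical(e[[1L]], as.name("(")) && length(e) == 2L) {
    inner <- .drop_bars(e[[2L]])
    return(if (is.null(inner)) NULL else inner)
  }
  if (identical(e[[1L]], as.name("+")) && length(e) == 3L) {
    a <- .drop_bars(e[[2L]]); b <- .drop_bars(e[[3L]])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    return(call("+", a, b))
  }
  e
}

# A grouping expression is a single variable or a ':' chain; evaluated on the
# model frame so listwise deletion stays consistent with the fixed part.
.eval_group <- function(e, mf) {
  vars <- all.vars(e)
  cols <- lapply(vars, function(v) factor(mf[[v]]))
  f <- if (length(cols) == 1L) cols[[1L]]
       else interaction(rev(cols), drop = TRUE, sep = ":", lex.order = TRUE)
  droplevels(f)
}

# ---- numerical core ---------------------------------------------------------

# Precomputed design information: everything that does not depend on y.
.vc_make_pre <- function(X, groups) {
  K <- length(groups)
  if (K == 0L)
    return(list(K = 0L, n = nrow(X), X = X))
  qvec <- vapply(groups, nlevels, integer(1))
  gidx <- do.call(cbind, lapply(groups, as.integer))
  storage.mode(gidx) <- "integer"
  list(K = K, n = nrow(X), qvec = qvec, gidx = gidx, X = X,
       env = new.env(parent = emptyenv()))
}

# Design-side C++ cache, rebuilt transparently when the external pointer has
# gone stale (e.g. a fit object restored in a new session).
.vc_cache <- function(pre) {
  cache <- pre$env$cache
  if (is.null(cache) || !.vc_cache_ok_cpp(cache)) {
    cache <- .vc_cache_cpp(pre$X, pre$gidx, as.integer(pre$qvec))
    pre$env$cache <- cache
  }
  cache
}

# ML fit given precomputed design pieces and a response.  Returns the minimal
# fit components; shared by vcmm(), the parametric bootstrap and LRT refits.
.vc_fit_pre <- function(pre, y, start = NULL, control = vcmm_control(),
                        groups = NULL) {
  n <- pre$n
  if (pre$K == 0L) {
    qrX <- qr(pre$X)
    beta <- qr.coef(qrX, y)
    res <- y - drop(pre$X %*% beta)
    sigma2 <- sum(res^2) / n
    dev <- n * log(2 * pi * sigma2) + n
    return(list(coefficients = beta, theta = numeric(0),
                varcomp = c(Residual = sigma2), deviance = dev,
                logLik = -dev / 2, converged = TRUE, boundary = FALSE, n = n,
                fitted.values = drop(pre$X %*% beta), residuals = res,
                ranef = list(), cov_beta = sigma2 * chol2inv(qr.R(qrX)),
                opt = NULL))
  }
  cache <- .vc_cache(pre)
  # deviance and analytic gradient share one evaluation (memoized on theta)
  memo <- new.env(parent = emptyenv())
  eval_dg <- function(th) {
    if (is.null(memo$th) || !identical(th, memo$th)) {
      memo$res <- .vc_devgrad_cpp(cache, th, y)
      memo$th <- th
    }
    memo$res
  }
  obj <- function(th) eval_dg(th)$deviance
  grd <- function(th) eval_dg(th)$gradient

  starts <- lapply(control$starts, function(s) rep_len(s, pre$K))
  if (!is.null(start)) starts <- c(list(rep_len(start, pre$K)), starts)
  best <- NULL
  for (s in starts) {
    # upper cap on the relative SDs: a residual variance ~1e8 times smaller
    # than a component is an effective boundary zero; letting theta run to
    # infinity only breaks the covariance factorization
    op <- stats::nlminb(s, obj, gradient = grd, lower = 0, upper = 1e4,
                        control = list(rel.tol = control$rel.tol,
                                       iter.max = control$iter.max,
                                       eval.max = control$eval.max))
    if (is.null(best) || op$objective < best$objective - 1e-12) best <- op
  }
  theta <- pmax(best$par, 0)
  boundary <- any(theta >= 1e4 * 0.99)
  if (boundary)
    warning("residual variance estimated at the boundary (effectively zero)")
  converged <- is.finite(best$objective) && best$objective < 1e9 &&
    (best$convergence == 0L || boundary)
  if (!converged)
    warning("vcmm fit did not converge; inspect $converged and $opt")

  ex <- .vc_extract_cpp(cache, theta, y)
  beta <- drop(ex$beta)
  names(beta) <- colnames(pre$X)
  sigma2 <- ex$sigma2
  vc <- c(theta^2 * sigma2, sigma2)
  names(vc) <- c(names(pre$qvec), "Residual")

  u <- split(drop(ex$u), rep.int(seq_len(pre$K), pre$qvec))
  ranef <- Map(function(ui, f) stats::setNames(ui, levels(f)),
               u, groups %||% rep(list(NULL), pre$K))
  names(ranef) <- names(pre$qvec)

  ranpart <- rowSums(mapply(function(ui, k) ui[pre$gidx[, k]],
                            u, seq_len(pre$K)))
  fitted <- drop(pre$X %*% beta) + ranpart
  list(coefficients = beta, theta = theta, varcomp = vc,
       deviance = ex$deviance, logLik = -ex$deviance / 2,
       converged = converged, boundary = boundary, n = n,
       fitted.values = fitted, residuals = y - fitted, ranef = ranef,
       cov_beta = sigma2 * ex$cov_unscaled, opt = best)
}

.vc_fit <- function(X, y, groups, start = NULL, control = vcmm_control()) {
  pre <- .vc_make_pre(X, groups)
  pre$X <- X
  fit <- .vc_fit_pre(pre, y, start = start, control = control,
                     groups = groups)
  fit$pre <- pre
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- methods ----------------------------------------------------------------

#' @export
print.vcmm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Linear mixed model fit by maximum likelihood ('vcmm')\n")
  cat("Formula:", deparse(x$formula), "\n")
  cat(sprintf("N = %d%s, logLik = %.3f%s\n", x$n,
              if (x$na.dropped > 0)
                sprintf(" (%d rows dropped for missingness)", x$na.dropped)
              else "",
              x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("\nFixed effects:\n")
  print(round(x$coefficients, digits))
  cat("\nVariance components:\n")
  vp <- varpart(x)
  print(vp, digits = digits)
  invisible(x)
}

#' @export
summary.vcmm <- function(object, ...) {
  se <- sqrt(diag(object$cov_beta))
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `z value` = object$coefficients / se)
  structure(list(call = object$call, formula = object$formula,
                 coefficients = coefs, varpart = varpart(object),
                 logLik = object$logLik, n = object$n,
                 na.dropped = object$na.dropped,
                 converged = object$converged),
            class = "summary.vcmm")
}

#' @export
print.summary.vcmm <- function(x, digits = max(3L, getOption("digits") - 3L),
                               ...) {
  cat("Linear mixed model fit by maximum likelihood ('vcmm')\n")
  cat("Formula:", deparse(x$formula), "\n")
  cat(sprintf("N = %d, logLik = %.3f\n\n", x$n, x$logLik))
  cat("Fixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nVariance components:\n")
  print(x$varpart, digits = digits)
  invisible(x)
}

#' @export
coef.vcmm <- function(object, ...) object$coefficients

#' @export
logLik.vcmm <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + length(object$theta) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.vcmm <- function(object, ...) object$fitted.values

#' @export
residuals.vcmm <- function(object, ...) object$residuals

#' Random-effect modes (BLUPs) of a vcmm fit
#' @param object a [vcmm()] fit.
#' @param ... unused.
#' @return named list of per-level conditional modes, one vector per factor.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.vcmm <- function(object, ...) object$ranef

#' @export
predict.vcmm <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(re.form)) return(object$fitted.values)
    return(drop(object$X %*% object$coefficients))
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                           na.action = stats::na.pass)
  Xn <- stats::model.matrix(tt, mf)
  eta <- drop(Xn %*% object$coefficients)
  if (!is.null(re.form) && is.na(re.form)) return(eta)
  for (g in names(object$groups)) {
    lev <- .eval_group(str2lang(g), newdata)
    u <- object$ranef[[g]]
    add <- u[as.character(lev)]
    add[is.na(add)] <- 0
    eta <- eta + add
  }
  unname(eta)
}

#' Simulate responses from a fitted vcmm model
#'
#' Draws fully parametric replicates: new Gaussian random intercepts for every
#' grouping factor and new residuals, added to the fixed-effect predictor.
#' This is the simulation scheme underlying [vc_bootstrap()].
#'
#' @param object a converged [vcmm()] fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @param ... unused.
#' @return a data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.vcmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  pre <- object$pre
  eta <- drop(object$X %*% object$coefficients)
  vc <- object$varcomp
  K <- pre$K
  out <- matrix(NA_real_, object$n, nsim)
  for (b in seq_len(nsim)) {
    y <- eta + stats::rnorm(object$n, 0, sqrt(vc[["Residual"]]))
    if (K > 0L)
      for (k in seq_len(K)) {
        uk <- stats::rnorm(pre$qvec[k], 0, sqrt(vc[[k]]))
        y <- y + uk[pre$gidx[, k]]
      }
    out[, b] <- y
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.vcmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$fitted.values, x$residuals, xlab = "Fitted",
                 ylab = "Residuals", main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(x$residuals, main = "Normal Q-Q")
  stats::qqline(x$residuals)
  invisible(x)
}

# save/restore RNG so seeded helpers do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
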