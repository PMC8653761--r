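#' Variance partition of a mixed-model fit
#'
#' Expresses each random-effect variance component (and the residual) as a
#' percentage of the total phenotypic variance, the standard presentation for
#' repeatability and social-plasticity analyses of song traits.
#'
#' @param object a [vcmm()] fit, or a named numeric vector of variance
#'   components (residual included) as printed in published tables.
#' @param ... unused.
#' @return a data frame of class `"vcmm_varpart"` with columns `component`,
#'   `variance` and `percent`; percentages sum to 100.
#' @examples
#' varpart(c(`Focal male` = 1.798, Stimulus = 0.286, Year = 0.005,
#'           Residual = 1.492))
#' @export
varpart <- function(object, ...) UseMethod("varpart")

#' @export
varpart.vcmm <- function(object, ...) varpart(object$varcomp)

#' @export
varpart.numeric <- function(object, ...) {
  if (any(object < 0)) stop("variance components must be non-negative")
  total <- sum(object)
  if (total <= 0) stop("degenerate fit: all variance components are zero")
  out <- data.frame(component = names(object) %||% paste0("vc", seq_along(object)),
                    variance = as.numeric(object),
                    percent = 100 * as.numeric(object) / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("vcmm_varpart", "data.frame")
  out
}

#' @export
print.vcmm_varpart <- function(x, digits = 4, ...) {
  y <- x
  y$variance <- signif(y$variance, digits)
  y$percent <- sprintf("%.2f%%", y$percent)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for variance components
#'
#' Simulates `B` replicate responses from the fitted model (fresh random
#' intercepts for every grouping factor plus fresh residuals), refits each
#' replicate by maximum likelihood, and returns percentile confidence
#' intervals for the variance components and for their percentages of total
#' variance.  Replicates whose refit fails are dropped and counted; more than
#' 10% failures aborts with an error.
#'
#' @param object a converged [vcmm()] fit.
#' @param B number of bootstrap replicates (the study default is 1000).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param level confidence level (default 0.95).
#' @param control optional [vcmm_control()] for the refits; the default
#'   warm-starts each refit from the parent fit's variance ratios, which is
#'   markedly faster than the full multistart and agrees with it in practice.
#' @return an object of class `"vcmm_boot"`: percentile interval matrices
#'   `ci_variance` and `ci_percent` (rows: lower, upper), the replicate draws
#'   `t_variance` / `t_percent`, and bookkeeping fields `B`, `n_fail`.
#' @export
vc_bootstrap <- function(object, B = 1000L, seed = NULL, level = 0.95,
                         control = NULL) {
  stopifnot(inherits(object, "vcmm"))
  if (!is.numeric(B) || B < 1L) stop("'B' must be a positive integer")
  B <- as.integer(B)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  pre <- object$pre
  eta <- drop(object$X %*% object$coefficients)
  vc <- object$varcomp
  K <- pre$K
  nm <- names(vc)
  ctrl <- control %||% vcmm_control(starts = list(pmax(object$theta, 0.05)))

  t_var <- matrix(NA_real_, B, K + 1L, dimnames = list(NULL, nm))
  n_fail <- 0L
  for (b in seq_len(B)) {
    ystar <- .vc_simulate_once(eta, vc, pre)
    fit <- tryCatch(
      suppressWarnings(.vc_fit_pre(pre, ystar, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance) || fit$deviance >= 1e9) {
      n_fail <- n_fail + 1L
    } else {
      t_var[b, ] <- fit$varcomp
    }
  }
  if (n_fail > 0.1 * B)
    stop(sprintf("parametric bootstrap: %d of %d refits failed (>10%%)",
                 n_fail, B))
  t_var <- t_var[stats::complete.cases(t_var), , drop = FALSE]
  t_pct <- 100 * t_var / rowSums(t_var)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- function(m) apply(m, 2, stats::quantile, probs = probs, names = FALSE)
  structure(list(ci_variance = ci(t_var), ci_percent = ci(t_pct),
                 t_variance = t_var, t_percent = t_pct,
                 B = B, n_fail = n_fail, level = level,
                 estimate = vc, percent = 100 * vc / sum(vc)),
            class = "vcmm_boot")
}

.vc_simulate_once <- function(eta, vc, pre) {
  y <- eta + stats::rnorm(length(eta), 0, sqrt(vc[["Residual"]]))
  if (pre$K > 0L)
    for (k in seq_len(pre$K)) {
      uk <- stats::rnorm(pre$qvec[k], 0, sqrt(vc[[k]]))
      y <- y + uk[pre$gidx[, k]]
    }
  y
}

#' @export
print.vcmm_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric bootstrap, B = %d (%d refit failures), %.0f%% CIs\n",
              x$B, x$n_fail, 100 * x$level))
  tab <- data.frame(component = names(x$estimate),
                    variance = signif(x$estimate, digits),
                    lwr = signif(x$ci_variance[1, ], digits),
                    upr = signif(x$ci_variance[2, ], digits),
                    percent = sprintf("%.2f%%", x$percent))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Signed Cramer's V effect size for a fixed term
#'
#' Compares the models with and without one fixed term by a likelihood-ratio
#' test and converts the chi-square statistic to Cramer's V,
#' \eqn{V = \sqrt{\chi^2 / (n\,\mathrm{df})}} (capped at 1), signed by the
#' term's coefficient when the term uses a single degree of freedom.  At
#' df = 1 this effect size is equivalent to a correlation coefficient, so the
#' conventional small/intermediate/large anchors at 0.1/0.3/0.5 apply.
#' An optional parametric bootstrap under the full fitted model yields a
#' percentile confidence interval for the signed V.
#'
#' @param object a converged [vcmm()] fit.
#' @param term character, one entry of `attr(terms(object), "term.labels")`.
#' @param B bootstrap replicates for the CI; 0 skips the CI.
#' @param seed optional integer seed for the bootstrap.
#' @param level confidence level.
#' @return an object of class `"vcmm_effect"` with `chi2`, `df`, `V`,
#'   `signed_V`, `signed` (FALSE when df > 1, in which case V is reported
#'   unsigned), and `ci` when `B > 0`.
#' @export
cramers_v <- function(object, term, B = 0L, seed = NULL, level = 0.95) {
  stopifnot(inherits(object, "vcmm"))
  labs <- attr(object$terms, "term.labels")
  if (!term %in% labs)
    stop(sprintf("'%s' is not a fixed term of the model (have: %s)",
                 term, paste(labs, collapse = ", ")))
  drop_idx <- which(object$assign == match(term, labs))
  if (length(drop_idx) == 0L)
    stop(sprintf("term '%s' contributes no columns; reduced model would equal the full model", term))

  pre_red <- .vc_drop_columns(object$pre, drop_idx)
  fit_red <- suppressWarnings(.vc_fit_pre(pre_red, object$y))
  es <- .vc_effect_from_fits(object, fit_red, drop_idx)

  ci <- NULL; n_fail <- 0L
  if (B > 0L) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    pre <- object$pre
    eta <- drop(object$X %*% object$coefficients)
    ctrl <- vcmm_control(starts = list(pmax(object$theta, 0.05)))
    vs <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      ystar <- .vc_simulate_once(eta, object$varcomp, pre)
      v <- tryCatch({
        ff <- suppressWarnings(.vc_fit_pre(pre, ystar, control = ctrl))
        fr <- suppressWarnings(.vc_fit_pre(pre_red, ystar, control = ctrl))
        .vc_effect_from_fits(list(logLik = ff$logLik, n = object$n,
                                  coefficients = ff$coefficients),
                             fr, drop_idx)$signed_V
      }, error = function(e) NA_real_)
      if (is.na(v)) n_fail <- n_fail + 1L else vs[b] <- v
    }
    if (n_fail > 0.1 * B)
      stop(sprintf("effect-size bootstrap: %d of %d refits failed (>10%%)",
                   n_fail, B))
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- stats::quantile(vs, probs, na.rm = TRUE, names = FALSE)
  }
  structure(c(es, list(term = term, ci = ci, B = B, n_fail = n_fail,
                       level = level)),
            class = "vcmm_effect")
}

.vc_drop_columns <- function(pre, drop_idx) {
  keep <- setdiff(seq_len(ncol(pre$X)), drop_idx)
  out <- pre
  out$X <- pre$X[, keep, drop = FALSE]
  if (pre$K > 0L)
    out$env <- new.env(parent = emptyenv())  # reduced design: fresh cache
  out
}

.vc_effect_from_fits <- function(full, red, drop_idx) {
  chi2 <- max(0, 2 * (full$logLik - red$logLik))
  df <- length(drop_idx)
  n <- full$n
  V <- min(1, sqrt(chi2 / (n * df)))
  if (df == 1L) {
    s <- sign(full$coefficients[drop_idx])
    if (s == 0) s <- 1
    list(chi2 = chi2, df = df, V = V, signed_V = unname(s * V),
         signed = TRUE, n_obs = n)
  } else {
    list(chi2 = chi2, df = df, V = V, signed_V = NA_real_,
         signed = FALSE, n_obs = n)
  }
}

#' @export
print.vcmm_effect <- function(x, digits = 3, ...) {
  v <- if (x$signed) x$signed_V else x$V
  cat(sprintf("Cramer's V for '%s': %s%.*f (chi2 = %.*f, df = %d, n = %d)%s\n",
              x$term, if (x$signed) "" else "[unsigned] ", digits, v,
              digits, x$chi2, x$df, x$n_obs,
              if (!is.null(x$ci))
                sprintf(", %.0f%% CI [%.*f, %.*f]", 100 * x$level,
                        digits, x$ci[1], digits, x$ci[2])
              else ""))
  invisible(x)
}

#' Variance inflation factors for the fixed-effect design
#'
#' Standard collinearity diagnostic on the non-intercept columns of the fixed
#' design matrix: \eqn{VIF_j = 1/(1 - R^2_j)} from regressing each column on
#' the others, computed as the diagonal of the inverse correlation matrix.
#'
#' @param object a [vcmm()] fit, or a formula (with `data`) whose fixed part
#'   is diagnosed.
#' @param data data frame, required when `object` is a formula.
#' @return named numeric vector of VIFs, one per non-intercept column.
#' @export
vif_fixed <- function(object, data = NULL) {
  if (inherits(object, "vcmm")) {
    X <- object$X
  } else if (inherits(object, "formula")) {
    bars_removed <- .drop_bars(object[[length(object)]])
    f <- stats::as.formula(call("~", bars_removed %||% 1))
    X <- stats::model.matrix(f, stats::model.frame(f, data))
  } else stop("'object' must be a vcmm fit or a formula")
  icpt <- which(colnames(X) == "(Intercept)")
  if (length(icpt)) X <- X[, -icpt, drop = FALSE]
  if (ncol(X) < 2L)
    stop("VIF needs at least two non-intercept fixed terms")
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || max(diag(inv)) > 1e12)
    stop("perfect collinearity among fixed terms: VIF is infinite")
  stats::setNames(diag(inv), colnames(X))
}
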