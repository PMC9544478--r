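#' One-random-effect linear mixed model of aridity on SNP dosage
#'
#' Fits `aridity = mu + beta * dosage + u_group + e`, with
#' `u_group ~ N(0, sigma2_g)` for the admixture group (population-structure
#' correction) and `e ~ N(0, sigma2_e)`, by maximum likelihood: the variance
#' ratio `lambda = sigma2_g / sigma2_e` is profiled in one dimension, with
#' generalized-least-squares fixed effects at each ratio (the one-factor
#' random effect makes the GLS weights diagonal after a within/between-group
#' rotation, so each profile evaluation is a small weighted least-squares
#' fit). The SNP effect gets a Wald p-value, and the variance explained by
#' the SNP is reported as the fixed-effect share of total model variance:
#' `VE = 100 * beta^2 * Var(dosage) / (beta^2 * Var(dosage) + sigma2_g +
#' sigma2_e)`.
#'
#' @param panel A [genotype_panel()] with `groups` and `aridity` attached.
#' @param snp_id SNP to test.
#' @return An object of class `lmm_fit` with `beta`, `se`, `p_value`,
#'   `intercept`, `sigma2_g`, `sigma2_e`, `variance_explained`, `loglik`,
#'   `n`, `n_groups`. Has [tidy()] and [glance()] methods.
#' @examples
#' panel <- synth_genotype_aridity(n_ecotypes = 200, n_snps = 3,
#'                                 causal_ve = 10, seed = 1)$panel
#' glance(fit_lmm_snp(panel, colnames(panel$dosages)[1]))
#' @export
fit_lmm_snp <- function(panel, snp_id) {
  if (is.null(panel$groups) || is.null(panel$aridity)) {
    abort("Panel needs both `groups` and `aridity` for the mixed model.")
  }
  if (!snp_id %in% colnames(panel$dosages)) {
    abort(sprintf("SNP '%s' not in panel.", snp_id))
  }
  df <- tibble::tibble(ecotype = rownames(panel$dosages),
                       dosage = panel$dosages[, snp_id]) %>%
    dplyr::inner_join(panel$groups, by = "ecotype") %>%
    dplyr::inner_join(panel$aridity, by = "ecotype") %>%
    dplyr::filter(!is.na(.data$dosage), !is.na(.data$aridity))
  if (dplyr::n_distinct(df$group) < 2) {
    abort("Need >= 2 admixture groups for the random effect.")
  }
  if (dplyr::n_distinct(df$dosage) < 2) {
    abort(sprintf("SNP '%s' has constant dosage after filtering.", snp_id))
  }
  y <- df$aridity
  X <- cbind(`(Intercept)` = 1, dosage = df$dosage)
  fit <- lmm_profile_ml(y, X, factor(df$group))
  ve_num <- fit$beta[["dosage"]]^2 * var(df$dosage)
  structure(list(
    beta = fit$beta[["dosage"]], se = fit$se[["dosage"]],
    p_value = 2 * pnorm(-abs(fit$beta[["dosage"]] / fit$se[["dosage"]])),
    intercept = fit$beta[["(Intercept)"]],
    sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
    variance_explained = 100 * ve_num / (ve_num + fit$sigma2_g + fit$sigma2_e),
    loglik = fit$loglik, n = nrow(df),
    n_groups = dplyr::n_distinct(df$group),
    snp_id = snp_id, data = df), class = "lmm_fit")
}

# ML profile fit of y = X b + Zu + e with one grouping factor.
# Rotation: within-group deviations have unit GLS weight; per-group mean
# components sqrt(n_g) * xbar_g have variance sigma2_e * (1 + lambda * n_g).
# Centering is an orthogonal projection, so OLS on the centered rows plus the
# weighted group-mean rows reproduces the GLS normal equations and RSS.
lmm_profile_ml <- function(y, X, group) {
  n <- length(y)
  gi <- split(seq_len(n), group)
  gi <- gi[lengths(gi) > 0]
  ng <- lengths(gi)
  ybar <- vapply(gi, function(i) mean(y[i]), 0)
  Xbar <- t(vapply(gi, function(i) colMeans(X[i, , drop = FALSE]),
                   numeric(ncol(X))))
  yc <- y - ybar[as.integer(factor(group, levels = names(gi)))]
  Xc <- X - Xbar[as.integer(factor(group, levels = names(gi))), , drop = FALSE]

  neg2ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (1 + lam * ng)
    ya <- c(yc, sqrt(w * ng) * ybar)
    Xa <- rbind(Xc, sqrt(w * ng) * Xbar)
    f <- lm.fit(Xa, ya)
    rss <- sum(f$residuals^2)
    s2 <- rss / n
    n * log(2 * pi * s2) + sum(log(1 + lam * ng)) + n
  }
  opt <- optimize(neg2ll, interval = c(-25, 15), tol = 1e-9)
  # the profile can be maximised at the sigma2_g = 0 boundary
  lam <- if (neg2ll(-Inf) <= opt$objective) 0 else exp(opt$minimum)

  w <- 1 / (1 + lam * ng)
  ya <- c(yc, sqrt(w * ng) * ybar)
  Xa <- rbind(Xc, sqrt(w * ng) * Xbar)
  f <- lm.fit(Xa, ya)
  rss <- sum(f$residuals^2)
  s2e <- rss / n
  XtX_inv <- chol2inv(chol(crossprod(Xa)))
  se <- sqrt(diag(XtX_inv) * s2e)
  names(se) <- colnames(X)
  beta <- f$coefficients
  names(beta) <- colnames(X)
  loglik <- -0.5 * (n * log(2 * pi * s2e) + sum(log(1 + lam * ng)) + n)
  list(beta = beta, se = se, sigma2_e = s2e, sigma2_g = lam * s2e,
       lambda = lam, loglik = loglik)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s: beta = %.4g (se %.3g, P = %.3g); VE = %.2f%%; sigma2_g = %.3g, sigma2_e = %.3g (n = %d, %d groups)\n",
              x$snp_id, x$beta, x$se, x$p_value, x$variance_explained,
              x$sigma2_g, x$sigma2_e, x$n, x$n_groups))
  invisible(x)
}

#' @rdname fit_lmm_snp
#' @param x,object An `lmm_fit` object.
#' @param ... Unused.
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "dosage"),
                 estimate = c(x$intercept, x$beta),
                 std.error = c(NA_real_, x$se),
                 p.value = c(NA_real_, x$p_value))
}

#' @rdname fit_lmm_snp
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, p.value = x$p_value,
                 variance.explained = x$variance_explained,
                 sigma2.group = x$sigma2_g, sigma2.resid = x$sigma2_e,
                 logLik = x$loglik, nobs = x$n, n.groups = x$n_groups)
}

#' @rdname fit_lmm_snp
#' @export
autoplot.lmm_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = factor(.data$dosage), y = .data$aridity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$group), width = 0.15,
                         alpha = 0.5) +
    ggplot2::labs(x = sprintf("%s dosage", object$snp_id), y = "Aridity",
                  title = sprintf("VE = %.1f%% (P = %.2g)",
                                  object$variance_explained, object$p_value)) +
    ggplot2::theme_minimal()
}
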