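#' Random-intercept linear mixed model with cluster-robust inference
#'
#' Fits `y = X beta + u_g + e` with `u_g ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma_e^2)` - the random-intercept form of a
#' compound-symmetry covariance structure (non-negative intra-class
#' correlation).  The variance-component ratio `rho = sigma_b^2 /
#' sigma_e^2` is estimated by REML through a one-dimensional profiled
#' search, with `beta` solved by generalized least squares at each
#' candidate; `sigma_b^2` is floored at zero.  Fixed-effect standard
#' errors are reported both model-based and empirical (cluster-robust
#' sandwich over groups with a `G/(G-1)` correction); Wald confidence
#' intervals and p-values use the empirical standard errors with a
#' t reference on `G - 1` degrees of freedom, the usual small-sample
#' guard when the number of clusters is modest.
#'
#' @param formula fixed-effects formula, e.g.
#'   `count ~ mode + position + cycle + compression_pct +
#'   mode:compression_pct`.
#' @param data data frame; rows with missing values in the model
#'   variables are dropped.
#' @param group name of the clustering column (e.g. cross-section id).
#' @return an object of class `lmm_fit` with elements `beta`,
#'   `se_model`, `se_empirical`, `sigma_b2`, `sigma_e2`, `ci95`
#'   (empirical), `p_values`, `n_obs`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(formula, data, group) {
    stopifnot(is.character(group), group %in% names(data))
    vars <- unique(c(all.vars(formula), group))
    data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
    mf <- model.frame(formula, data)
    y <- model.response(mf)
    X <- model.matrix(formula, mf)
    g <- factor(data[[group]])
    n <- length(y)
    p <- ncol(X)
    G <- nlevels(g)
    if (G < 2L) stop("at least 2 groups are required", call. = FALSE)
    if (qr(X)$rank < p)
        stop("design matrix is rank deficient after dummy coding", call. = FALSE)
    gi <- split(seq_len(n), g)
    ng <- lengths(gi)

    # sufficient statistics per group for Woodbury-form GLS:
    # W^-1 = I - rho/(1 + n_g rho) * J  (per group), V = sigma_e^2 W
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
    yty <- sum(y * y)
    Sx <- t(vapply(gi, function(ii) colSums(X[ii, , drop = FALSE]),
                   numeric(p)))        # G x p group sums of X
    if (p == 1L) Sx <- matrix(Sx, ncol = 1L)
    Sy <- vapply(gi, function(ii) sum(y[ii]), numeric(1))

    gls_parts <- function(rho) {
        cg <- rho / (1 + ng * rho)
        A <- XtX - crossprod(Sx * cg, Sx)
        b <- Xty - crossprod(Sx * cg, Sy)
        yWy <- yty - sum(cg * Sy^2)
        beta <- solve(A, b)
        rss <- drop(yWy - crossprod(b, beta))
        list(A = A, beta = beta, rss = rss)
    }
    reml_crit <- function(rho) {
        gp <- gls_parts(rho)
        (n - p) * log(gp$rss) + sum(log1p(ng * rho)) +
            determinant(gp$A, logarithm = TRUE)$modulus
    }
    opt <- optimize(function(lr) reml_crit(exp(lr)),
                    interval = c(-12, 8), tol = 1e-8)
    rho <- exp(opt$minimum)
    if (reml_crit(0) <= opt$objective) rho <- 0   # boundary: sigma_b^2 = 0
    gp <- gls_parts(rho)
    sigma_e2 <- gp$rss / (n - p)
    sigma_b2 <- rho * sigma_e2
    beta <- drop(gp$beta)
    names(beta) <- colnames(X)
    A_inv <- solve(gp$A)
    se_model <- sqrt(diag(A_inv) * sigma_e2)

    # cluster-robust sandwich: bread = (X'V^-1X)^-1 = sigma_e2 * A^-1,
    # meat = sum_g s_g s_g' with s_g = X_g' V_g^-1 e_g
    e <- y - X %*% gp$beta
    cg <- rho / (1 + ng * rho)
    Se <- vapply(gi, function(ii) sum(e[ii]), numeric(1))
    meat <- matrix(0, p, p)
    for (k in seq_along(gi)) {
        ii <- gi[[k]]
        s_g <- (crossprod(X[ii, , drop = FALSE], e[ii]) -
                cg[k] * Sx[k, ] * Se[k]) / sigma_e2
        meat <- meat + tcrossprod(s_g)
    }
    bread <- sigma_e2 * A_inv
    vc_emp <- bread %*% meat %*% bread * G / (G - 1)
    se_emp <- sqrt(diag(vc_emp))
    z <- stats::qt(0.975, df = G - 1)
    ci95 <- cbind(lower = beta - z * se_emp, upper = beta + z * se_emp)
    p_values <- pmax(2 * stats::pt(-abs(beta / se_emp), df = G - 1),
                     .Machine$double.xmin)
    structure(list(beta = beta, se_model = se_model, se_empirical = se_emp,
                   sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                   ci95 = ci95, p_values = p_values,
                   vcov_empirical = vc_emp,
                   n_obs = n, n_groups = G, rho = rho,
                   converged = TRUE, formula = formula, group = group),
              class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
    cat(sprintf("lmm_fit: %d obs in %d groups; sigma_b^2 = %.4g, sigma_e^2 = %.4g\n",
                x$n_obs, x$n_groups, x$sigma_b2, x$sigma_e2))
    tab <- data.frame(estimate = x$beta, se_empirical = x$se_empirical,
                      ci_lower = x$ci95[, 1], ci_upper = x$ci95[, 2],
                      p = x$p_values)
    print(round(tab, 4))
    invisible(x)
}

#' Slope-difference contrast from an interaction coefficient
#'
#' Extracts the mode-by-compression interaction (the difference between
#' the UHR and NR slopes against compression percentage) with its
#' empirical confidence interval and Wald p-value.
#'
#' @param fit an [fit_lmm()] result.
#' @param interaction_term coefficient name of the interaction.
#' @return list with `difference`, `ci95`, `p_value`, `term`.
#' @export
slope_contrast <- function(fit, interaction_term) {
    stopifnot(inherits(fit, "lmm_fit"))
    if (!interaction_term %in% names(fit$beta))
        stop(sprintf("term `%s` not present in the model (have: %s)",
                     interaction_term,
                     paste(names(fit$beta), collapse = ", ")),
             call. = FALSE)
    list(difference = unname(fit$beta[interaction_term]),
         ci95 = unname(fit$ci95[interaction_term, ]),
         p_value = unname(fit$p_values[interaction_term]),
         term = interaction_term)
}

#' Per-group ordinary least-squares regression lines
#'
#' Descriptive overlays: one OLS slope and intercept per group.
#'
#' @param data data frame.
#' @param x,y,group_by column names.
#' @return data frame with `group`, `slope`, `intercept`, `n`.
#' @export
group_regression_lines <- function(data, x, y, group_by) {
    stopifnot(all(c(x, y, group_by) %in% names(data)))
    parts <- split(data, data[[group_by]])
    out <- do.call(rbind, lapply(names(parts), function(gname) {
        d <- parts[[gname]]
        d <- d[is.finite(d[[x]]) & is.finite(d[[y]]), , drop = FALSE]
        if (length(unique(d[[x]])) < 2L)
            stop(sprintf("group `%s` has fewer than 2 distinct x values", gname),
                 call. = FALSE)
        cf <- coef(lm(d[[y]] ~ d[[x]]))
        data.frame(group = gname, slope = unname(cf[2]),
                   intercept = unname(cf[1]), n = nrow(d))
    }))
    rownames(out) <- NULL
    out
}
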