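#' Compile dwell times into an empirical cumulative distribution
#'
#' Dwell times below `max_dwell_s` (default 120 s) are compiled into an
#' ECDF evaluated at each unique dwell value: ties are tallied, so each
#' distinct dwell contributes one fitting point.  Longer dwells are dropped
#' and counted as truncated.
#'
#' @param dwells Numeric vector of dwell times in seconds, or a dwell table
#'   from [extract_dwells()] (column `dwell_s`).
#' @param max_dwell_s Upper truncation limit, seconds; dwells must be
#'   strictly below it to enter the ECDF.
#' @return Object of class `dwell_ecdf`: list with `t` (sorted unique dwell
#'   values), `F` (cumulative fraction at each `t`, ending at 1), `n`
#'   (number of dwells used) and `n_truncated`.
#' @export
build_ecdf <- function(dwells, max_dwell_s = 120) {
  if (is.data.frame(dwells)) dwells <- dwells$dwell_s
  stopifnot(is.numeric(dwells))
  if (!length(dwells)) stop("no dwell times supplied", call. = FALSE)
  keep <- dwells < max_dwell_s
  if (!any(keep)) {
    stop(sprintf("all %d dwells are >= %g s: no fittable data",
                 length(dwells), max_dwell_s), call. = FALSE)
  }
  d <- sort(dwells[keep])
  t <- unique(d)
  F <- cumsum(tabulate(match(d, t))) / length(d)
  structure(list(t = t, F = F, n = length(d),
                 n_truncated = sum(!keep)),
            class = "dwell_ecdf")
}

#' @export
print.dwell_ecdf <- function(x, ...) {
  cat(sprintf("dwell ECDF: %d events (%d truncated), %d unique values, t in [%g, %g] s\n",
              x$n, x$n_truncated, length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

l1_loss <- function(tau, c, t, F) sum(abs(F - (1 - exp(-t / tau) + c)))

#' Fit the exponential dwell-time model to an ECDF
#'
#' Fits `F(t) = 1 - exp(-t/tau) + c` with the offset bounded at
#' `|c| <= c_bound` (default 0.025), minimizing the sum of absolute
#' residuals over the ECDF points.  The L1 objective is handled by
#' iteratively reweighted least squares — weights `1/max(|resid|, 1e-6)`,
#' each weighted subproblem solved by box-constrained quasi-Newton — started
#' from `tau = ` the ECDF's mean dwell and `c = 0`, declared converged when
#' the relative change in `tau` drops below `tol`.  If IRLS fails to
#' converge, a derivative-free Nelder-Mead search on the L1 objective takes
#' over.  `r2` is the coefficient of determination of the final model over
#' the ECDF points (uniform weights).
#'
#' @param ecdf A `dwell_ecdf` from [build_ecdf()] with at least 3 distinct
#'   dwell values.
#' @param c_bound Bound on the offset error term.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative convergence tolerance on `tau`.
#' @return Object of class `dwell_fit`: list with `tau_s`, `c`, `r2`,
#'   `n_events`, `n_truncated`, `converged`, `n_iter`, `method` and
#'   `at_bound` (`TRUE` if `tau` ran into a numerical bound).
#' @export
fit_exponential_cdf <- function(ecdf, c_bound = 0.025, max_iter = 100L,
                                tol = 1e-8) {
  stopifnot(inherits(ecdf, "dwell_ecdf"))
  t <- ecdf$t
  F <- ecdf$F
  if (length(t) < 3L) {
    stop("need at least 3 distinct dwell values to fit", call. = FALSE)
  }
  mass <- diff(c(0, F))
  # work on a normalized time axis so the optimizer's stopping rules see
  # the same problem whatever the dwell units; this makes tau-hat exactly
  # equivariant under rescaling of the dwells
  t_scale <- sum(t * mass) # mean dwell of the compiled distribution
  ts <- t / t_scale
  tau <- 1
  cc <- 0
  tau_lo <- 1e-9
  tau_hi <- 1e6 * max(ts)
  converged <- FALSE
  n_iter <- 0L
  method <- "irls"
  for (it in seq_len(max_iter)) {
    n_iter <- it
    resid <- F - (1 - exp(-ts / tau) + cc)
    w <- 1 / pmax(abs(resid), 1e-6)
    wls <- function(p) sum(w * (F - (1 - exp(-ts / p[1]) + p[2]))^2)
    opt <- optim(c(tau, cc), wls, method = "L-BFGS-B",
                 lower = c(tau_lo, -c_bound), upper = c(tau_hi, c_bound))
    tau_new <- opt$par[1]
    cc <- opt$par[2]
    if (abs(tau_new - tau) / tau < tol) {
      tau <- tau_new
      converged <- TRUE
      break
    }
    tau <- tau_new
  }
  if (!converged) {
    # simplex fallback on the raw L1 objective (offset clamped to its box)
    method <- "nelder_mead"
    obj <- function(p) {
      l1_loss(max(p[1], tau_lo), max(-c_bound, min(c_bound, p[2])), ts, F)
    }
    opt <- optim(c(tau, cc), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-12))
    tau <- max(opt$par[1], tau_lo)
    cc <- max(-c_bound, min(c_bound, opt$par[2]))
    converged <- opt$convergence == 0L
  }
  at_bound <- tau <= tau_lo * (1 + 1e-9) || tau >= tau_hi * (1 - 1e-9)
  tau <- tau * t_scale
  model <- 1 - exp(-t / tau) + cc
  ss_res <- sum((F - model)^2)
  ss_tot <- sum((F - mean(F))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  structure(list(tau_s = tau, c = cc, r2 = r2, n_events = ecdf$n,
                 n_truncated = ecdf$n_truncated, converged = converged,
                 n_iter = n_iter, method = method, at_bound = at_bound),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("exponential dwell fit: tau = %.3f s, c = %+.4f, r2 = %.4f (n = %d, %s%s)\n",
              x$tau_s, x$c, x$r2, x$n_events, x$method,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Compare fitted dwell times across conditions
#'
#' Standard inferential wrappers for replicate `tau` estimates: two groups
#' are compared with a two-sample t test; three or more with one-way ANOVA
#' followed by all-pairs Tukey honestly-significant-difference comparisons.
#' When `bonferroni_m` is given, the per-contrast significance threshold is
#' `alpha / bonferroni_m` (planned pairwise contrasts).
#'
#' @param groups Named list: condition -> numeric vector of replicate tau
#'   estimates.  Groups with fewer than 2 replicates are dropped with a
#'   warning.
#' @param alpha Family significance level.
#' @param bonferroni_m Optional number of planned contrasts for a
#'   Bonferroni-adjusted threshold.
#' @return List with `method`, `summary` (mean, sd, n per group),
#'   `comparisons` (pairwise estimates and p-values with a `significant`
#'   flag), `alpha` and `alpha_per_contrast`.
#' @export
compare_taus <- function(groups, alpha = 0.05, bonferroni_m = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) {
    warning(sprintf("dropping group(s) with < 2 replicates: %s",
                    paste(names(groups)[sizes < 2L], collapse = ", ")),
            call. = FALSE)
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) {
    stop("need at least two groups with >= 2 replicates", call. = FALSE)
  }
  thr <- if (is.null(bonferroni_m)) alpha else alpha / bonferroni_m
  smry <- data.frame(condition = names(groups),
                     n = vapply(groups, length, 1L),
                     mean = vapply(groups, mean, 1),
                     sd = vapply(groups, sd, 1))
  rownames(smry) <- NULL
  if (length(groups) == 2L) {
    a <- groups[[1]]
    b <- groups[[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      # degenerate: constant replicates; difference is exact
      est <- mean(a) - mean(b)
      p <- if (est == 0) 1 else 0
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      est <- unname(diff(rev(tt$estimate)))
      p <- tt$p.value
    }
    comparisons <- data.frame(contrast = paste(names(groups)[1], "-",
                                               names(groups)[2]),
                              estimate = est, p_value = p,
                              significant = p < thr)
    method <- "two-sample t test"
  } else {
    cond <- factor(rep(names(groups), times = vapply(groups, length, 1L)),
                   levels = names(groups))
    df <- data.frame(tau = unlist(groups, use.names = FALSE), cond = cond)
    fit <- aov(tau ~ cond, data = df)
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cond
    comparisons <- data.frame(contrast = rownames(tk),
                              estimate = tk[, "diff"],
                              p_value = tk[, "p adj"],
                              significant = tk[, "p adj"] < thr)
    rownames(comparisons) <- NULL
    method <- "one-way ANOVA + Tukey HSD"
  }
  list(method = method, summary = smry, comparisons = comparisons,
       alpha = alpha, alpha_per_contrast = thr)
}
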