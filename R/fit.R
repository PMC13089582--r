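#' Akaike information criterion
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters.
#' @return `2k - 2*loglik`.
#' @export
aic <- function(loglik, k) 2 * k - 2 * loglik

.model_fit <- function(kind, loglik, k, estimates, convergence, P,
                       extra = list()) {
  structure(c(list(kind = kind, loglik = loglik, k = k,
                   AIC = aic(loglik, k), estimates = estimates,
                   convergence = convergence, P = P), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Codon model fit [%s]: logL = %.4f, k = %d, AIC = %.4f\n",
              x$kind, x$loglik, x$k, x$AIC))
  est <- x$estimates
  flat <- unlist(est[setdiff(names(est),
                             c("freqs", "branch_lengths", "mixture"))])
  cat("  ", paste(sprintf("%s = %.4g", names(flat), flat), collapse = ", "),
      "\n")
  if (!is.null(est$mixture)) {
    cat("  class proportions:",
        paste(sprintf("%.4f", est$mixture$prop), collapse = " / "), "\n")
  }
  if (!is.null(x$convergence) && !isTRUE(x$convergence$converged)) {
    cat("  WARNING: optimizer did not converge cleanly\n")
  }
  invisible(x)
}

# shared optimizer driver: minimise nll(theta) within [lower, upper] with
# jittered restarts; returns best optim result + diagnostics
.optimise_restarts <- function(nll, start, lower, upper, restarts, seed,
                               extra_starts = list()) {
  set.seed(seed)
  starts <- list(start)
  if (restarts > 1) {
    for (r in seq_len(restarts - 1)) {
      s <- start + stats::rnorm(length(start), 0, 0.5)
      starts[[r + 1]] <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
    }
  }
  starts <- c(starts, lapply(extra_starts, function(s) {
    pmin(pmax(s, lower + 1e-6), upper - 1e-6)
  }))
  best <- NULL
  codes <- integer(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e7,
                                                 maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  best$diagnostics <- list(converged = any(codes == 0),
                           restart_codes = codes)
  best
}

#' Fit the branch variant of the property-partitioned codon model
#'
#' Fits a null model with a single radical rate gamma shared by all branches
#' and an alternative model with separate `gamma_fg` / `gamma_bg` for
#' foreground and background branches; `kappa` and `omega` are free in both.
#' Codon frequencies are taken empirically (F3X4 by default) and not counted
#' as free parameters. Branch lengths are fixed at the input tree's values
#' by default; with `estimate_branch_lengths = TRUE` they are optimised
#' jointly and counted in `k`.
#'
#' @param aln A `codon_alignment`.
#' @param tree A [tagged_tree()] with at least one fg branch for the
#'   alternative model to be meaningful.
#' @param partition A [build_partition()] result.
#' @param freqs Codon frequencies (default F3X4 from the alignment).
#' @param estimate_branch_lengths Optimise branch lengths jointly.
#' @param restarts Optimizer restarts with jittered starts (default 3).
#' @param seed Seed for the restart jitter.
#' @param init Optional named start values (`kappa`, `omega`, `gamma`).
#' @return List with elements `null` and `alternative`, both `model_fit`
#'   objects.
#' @export
fit_branch_model <- function(aln, tree, partition,
                             freqs = codon_frequencies(aln),
                             estimate_branch_lengths = FALSE,
                             restarts = 3, seed = 1,
                             init = c(kappa = 2, omega = 0.5, gamma = 0.5)) {
  pat <- .aln_patterns(aln)
  ts <- .tree_struct(tree, rownames(aln))
  pi <- .check_freqs(freqs)
  ne <- nrow(ts$edge)
  base_lens <- ts$lens

  make_nll <- function(two_gamma) {
    npar <- if (two_gamma) 4L else 3L
    function(theta) {
      th <- exp(theta)
      ts2 <- ts
      if (length(theta) > npar) ts2$lens <- th[(npar + 1):length(th)]
      g <- if (two_gamma) c(fg = th[3], bg = th[4])
           else c(fg = th[3], bg = th[3])
      ll <- .loglik_single(pat, ts2, th[1], th[2], g, partition, pi)
      v <- -sum(ll * pat$weights)
      if (!is.finite(v)) 1e10 else v
    }
  }

  fit_one <- function(two_gamma) {
    start <- log(c(init[["kappa"]], init[["omega"]],
                   if (two_gamma) rep(init[["gamma"]], 2)
                   else init[["gamma"]]))
    lower <- c(log(1e-3), rep(log(1e-6), length(start) - 1))
    upper <- rep(log(1e3), length(start))
    k <- length(start)
    if (estimate_branch_lengths) {
      start <- c(start, log(pmax(base_lens, 1e-6)))
      lower <- c(lower, rep(log(1e-8), ne))
      upper <- c(upper, rep(log(50), ne))
      k <- k + ne
    }
    o <- .optimise_restarts(make_nll(two_gamma), start, lower, upper,
                            restarts, seed)
    th <- exp(o$par)
    est <- list(kappa = th[1], omega = th[2])
    if (two_gamma) {
      est$gamma_fg <- th[3]; est$gamma_bg <- th[4]
    } else est$gamma <- th[3]
    if (estimate_branch_lengths) {
      est$branch_lengths <- th[-seq_len(if (two_gamma) 4 else 3)]
    }
    est$freqs <- pi
    .model_fit(if (two_gamma) "branch-alternative" else "branch-null",
               -o$value, k, est, o$diagnostics, partition$P)
  }

  null <- fit_one(FALSE)
  alt <- fit_one(TRUE)
  if (alt$loglik < null$loglik - 1e-4) {
    # nested models: refit the alternative from the null's optimum
    init2 <- c(kappa = null$estimates$kappa, omega = null$estimates$omega,
               gamma = null$estimates$gamma)
    alt2 <- tryCatch(
      fit_branch_model(aln, tree, partition, freqs,
                       estimate_branch_lengths, restarts = 1, seed = seed,
                       init = init2)$alternative,
      error = function(e) NULL)
    if (!is.null(alt2) && alt2$loglik > alt$loglik) alt <- alt2
  }
  list(null = null, alternative = alt)
}

# softmax with an implicit 0 for the first class
.softmax_props <- function(free) {
  e <- exp(c(0, free))
  e / sum(e)
}

#' Fit the site-mixture variant of the property-partitioned codon model
#'
#' The alternative model mixes four site classes combining
#' `omega0 <= 1 < omega1` with `gamma0 <= 1 < gamma1`:
#' (i) (omega0, gamma0), (ii) (omega0, gamma1), (iii) (omega1, gamma0),
#' (iv) (omega1, gamma1). The null model allows only the gamma0 classes
#' (i) and (iii). Empirical-Bayes posterior class probabilities per site are
#' returned, along with the per-site probability of the gamma1 classes
#' (ii) + (iv) used by the convergence screen.
#'
#' @inheritParams fit_branch_model
#' @return List with `null` and `alternative` (`model_fit` objects; the
#'   alternative's `estimates$mixture` is the fitted class table) and
#'   `posterior` (data frame: site, p_i..p_iv, p_gamma1).
#' @export
fit_site_model <- function(aln, tree, partition,
                           freqs = codon_frequencies(aln),
                           estimate_branch_lengths = FALSE,
                           restarts = 3, seed = 1) {
  pat <- .aln_patterns(aln)
  ts <- .tree_struct(tree, rownames(aln))
  pi <- .check_freqs(freqs)
  ne <- nrow(ts$edge)
  base_lens <- ts$lens

  # theta layout, alt:  log kappa, log w0, log w1, log g0, log g1, f2, f3, f4
  #              null:  log kappa, log w0, log w1, log g0, f3
  mix_from_theta <- function(th, alt) {
    if (alt) {
      props <- .softmax_props(th[6:8])
      data.frame(omega = exp(th[c(2, 2, 3, 3)]),
                 gamma = exp(th[c(4, 5, 4, 5)]),
                 prop = props[c(1, 2, 3, 4)])
      # class order (i),(ii),(iii),(iv)
    } else {
      props <- .softmax_props(th[5])
      data.frame(omega = exp(th[c(2, 3)]), gamma = exp(th[c(4, 4)]),
                 prop = props)
    }
  }
  make_nll <- function(alt, npar) {
    function(theta) {
      ts2 <- ts
      if (length(theta) > npar) {
        ts2$lens <- exp(theta[(npar + 1):length(theta)])
      }
      mix <- mix_from_theta(theta, alt)
      ll <- .loglik_mixture(pat, ts2, exp(theta[1]), mix, partition, pi)$ll
      v <- -sum(ll * pat$weights)
      if (!is.finite(v)) 1e10 else v
    }
  }
  eps <- 1e-4
  fit_one <- function(alt, extra_starts = list()) {
    if (alt) {
      start <- c(log(2), log(0.3), log(2), log(0.3), log(2), 0, 0, 0)
      lower <- c(log(1e-3), log(1e-6), log(1) + eps, log(1e-6),
                 log(1) + eps, rep(-8, 3))
      upper <- c(log(1e3), log(1), log(1e3), log(1), log(1e3), rep(8, 3))
    } else {
      start <- c(log(2), log(0.3), log(2), log(0.3), 0)
      lower <- c(log(1e-3), log(1e-6), log(1) + eps, log(1e-6), -8)
      upper <- c(log(1e3), log(1), log(1e3), log(1), 8)
    }
    k <- length(start)
    npar <- k
    if (estimate_branch_lengths) {
      start <- c(start, log(pmax(base_lens, 1e-6)))
      lower <- c(lower, rep(log(1e-8), ne))
      upper <- c(upper, rep(log(50), ne))
      k <- k + ne
    }
    o <- .optimise_restarts(make_nll(alt, npar), start, lower, upper,
                            restarts, seed, extra_starts = extra_starts)
    mix <- mix_from_theta(o$par, alt)
    rownames(mix) <- if (alt) c("i", "ii", "iii", "iv") else c("i", "iii")
    est <- list(kappa = exp(o$par[1]), mixture = mix, freqs = pi)
    if (estimate_branch_lengths) {
      est$branch_lengths <- exp(o$par[-seq_len(npar)])
    }
    .model_fit(if (alt) "site-alternative" else "site-null", -o$value, k,
               est, o$diagnostics, partition$P, list(theta = o$par))
  }
  null <- fit_one(FALSE)
  # warm-start the alternative at the null optimum (tiny gamma1 classes) so
  # the nested log-likelihood ordering survives flat mixture surfaces
  thn <- null$theta
  warm <- c(thn[1:4], log(2), -6, thn[5], -6)
  if (estimate_branch_lengths) warm <- c(warm, thn[-(1:5)])
  alt <- fit_one(TRUE, extra_starts = list(warm))

  # empirical-Bayes posteriors under the alternative fit
  mix <- alt$estimates$mixture
  res <- .loglik_mixture(pat, ts, alt$estimates$kappa, mix, partition, pi)
  lp <- log(mix$prop) + res$class_ll
  m <- apply(lp, 2L, max)
  post_pat <- exp(sweep(lp, 2L, m))
  post_pat <- sweep(post_pat, 2L, colSums(post_pat), "/")
  post <- t(post_pat[, pat$site_map, drop = FALSE])
  posterior <- data.frame(site = seq_len(nrow(post)),
                          p_i = post[, 1], p_ii = post[, 2],
                          p_iii = post[, 3], p_iv = post[, 4])
  posterior$p_gamma1 <- posterior$p_ii + posterior$p_iv
  list(null = null, alternative = alt, posterior = posterior)
}

#' Compare nested codon-model fits by AIC and likelihood ratio test
#'
#' @param null,alt `model_fit` objects, `alt` nesting `null`.
#' @return List of class `model_comparison`: `lrt` (2 * delta logL), `df`,
#'   `p_value` (chi-square upper tail), `delta_AIC` (null - alternative,
#'   positive favouring the alternative), and the two AICs. For the site
#'   mixture the chi-square reference is the conventional approximation;
#'   boundary effects on the mixture proportions make it approximate.
#' @export
compare_models <- function(null, alt) {
  stopifnot(inherits(null, "model_fit"), inherits(alt, "model_fit"))
  lrt <- 2 * (alt$loglik - null$loglik)
  if (lrt < -1e-4) {
    warning("alternative log-likelihood below null (", signif(lrt / 2, 4),
            "); optimization likely not converged")
  }
  lrt <- max(lrt, 0)
  df <- alt$k - null$k
  if (df < 1) stop("models not nested: alternative has no extra parameters")
  structure(list(lrt = lrt, df = df,
                 p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
                 delta_AIC = null$AIC - alt$AIC,
                 AIC_null = null$AIC, AIC_alt = alt$AIC),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT: 2*dlogL = %.4f, df = %d, p = %.4g\n",
              x$lrt, x$df, x$p_value))
  cat(sprintf("AIC: null %.3f vs alternative %.3f (delta %.3f)\n",
              x$AIC_null, x$AIC_alt, x$delta_AIC))
  invisible(x)
}

#' Sweep radical/conservative partitions and pick the AIC-best one
#'
#' Refits the chosen model variant at each percent cutoff in `P_grid` and
#' selects the partition minimising the alternative model's AIC. Failures at
#' single grid points are recorded and the sweep continues.
#'
#' @param aln,tree,freqs As in [fit_branch_model()].
#' @param scale An [aa_scale()] used to build each partition.
#' @param model_kind `"branch"` or `"site"`.
#' @param P_grid Percent cutoffs (default 10, 20, ..., 90).
#' @param ... Passed on to the fitting function.
#' @return List of class `partition_sweep`: `table` (one row per P with
#'   log-likelihoods, AICs, estimates or an error message), `best_P`, and
#'   `fits` (the per-P fit objects).
#' @export
sweep_partitions <- function(aln, tree, scale,
                             model_kind = c("branch", "site"),
                             P_grid = seq(10, 90, by = 10),
                             freqs = codon_frequencies(aln), ...) {
  model_kind <- match.arg(model_kind)
  if (!length(P_grid)) stop("P_grid is empty")
  rows <- list()
  fits <- list()
  for (P in P_grid) {
    res <- tryCatch({
      part <- build_partition(scale, P)
      f <- if (model_kind == "branch") {
        fit_branch_model(aln, tree, part, freqs = freqs, ...)
      } else {
        fit_site_model(aln, tree, part, freqs = freqs, ...)
      }
      f
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[as.character(P)]] <- data.frame(
        P = P, loglik_null = NA, loglik_alt = NA, AIC_null = NA,
        AIC_alt = NA, error = conditionMessage(res))
      next
    }
    fits[[as.character(P)]] <- res
    rows[[as.character(P)]] <- data.frame(
      P = P, loglik_null = res$null$loglik, loglik_alt = res$alternative$loglik,
      AIC_null = res$null$AIC, AIC_alt = res$alternative$AIC,
      error = NA_character_)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$AIC_alt)
  if (!any(ok)) stop("every partition fit failed")
  best_P <- tab$P[ok][which.min(tab$AIC_alt[ok])]
  structure(list(table = tab, best_P = best_P, fits = fits,
                 model_kind = model_kind),
            class = "partition_sweep")
}

#' @export
print.partition_sweep <- function(x, ...) {
  cat(sprintf("Partition sweep (%s model): best P = %d%% by AIC\n",
              x$model_kind, x$best_P))
  print(x$table, digits = 8)
  invisible(x)
}
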