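#' Fit a folded Skellam mixture
#'
#' Fits a K-component mixture of folded Skellam distributions to absolute
#' (library-adjusted, rounded) allelic read differences.  Each component has
#' a weight \eqn{\pi_i} and an unordered rate pair
#' \eqn{(\lambda_{i,1}, \lambda_{i,2})}: the fold destroys the sign of the
#' difference, so the pair is identifiable only up to order and is stored
#' with the larger rate first.  Components with significantly unequal rates
#' are candidate allelic-imbalance (AEI) signal components; see
#' [lrt_equal_means()].
#'
#' Two backends are available.  `method = "em"` (default) is
#' expectation-maximization with the exact folded Skellam pmf: the E-step is
#' exact, and the M-step maximizes each component's responsibility-weighted
#' log-likelihood over \eqn{(\log\lambda_1, \log\lambda_2)} with Nelder-Mead,
#' warm-started at the current parameters and a moment-based candidate
#' (whichever scores higher), so the observed log-likelihood never decreases.
#' `method = "abc"` is a likelihood-free MCMC (approximate Bayesian
#' computation) sampler, see [fit_fskellam_abc()]; it exists as an
#' alternative backend and as a cross-check of the EM estimates.
#'
#' @param y non-negative integer absolute differences.
#' @param K number of components.
#' @param method `"em"` or `"abc"`.
#' @param init optional K-by-2 matrix of starting rates (EM backend).
#' @param tol EM convergence tolerance on log-likelihood improvement.
#' @param max_iter EM iteration cap.
#' @param seed optional seed (ABC backend and EM with random elements).
#' @param ... further arguments passed to [fit_fskellam_abc()].
#' @return an object of class `"fskmix"`: list with `K`, `weights`,
#'   `lambda1`, `lambda2` (per component, `lambda1 >= lambda2`), `loglik`,
#'   `bic` (with `3K - 1` free parameters), `n_obs`, `fit_method`,
#'   `converged`, `iterations`, `loglik_trace`.
#' @export
fit_fskellam_mixture <- function(y, K, method = c("em", "abc"), init = NULL,
                                 init_weights = NULL, tol = 1e-6,
                                 max_iter = 300L, seed = NULL, ...) {
  method <- match.arg(method)
  y <- check_counts(y)
  if (K < 1) stop("K must be >= 1")
  if (K > length(unique(y)))
    stop("K (", K, ") exceeds the number of distinct values (",
         length(unique(y)), ")")
  if (method == "abc")
    return(fit_fskellam_abc(y, K, seed = seed, ...))
  if (!is.null(seed)) set.seed(seed)
  fskellam_em(y, K, init = init, init_weights = init_weights, tol = tol,
              max_iter = max_iter)
}

# moment-based (sum, gap) -> rate pair; used for inits and M-step warm
# starts.  Two candidates span the weakly identified (sum, gap) ridge: a
# gapped pair (gap ~ mean, sensible when the component sits away from zero)
# and the equal-rates null pair (lambda = E y^2 / 2).
rates_from_moments <- function(m1, m2) {
  d <- max(m1, 0)                       # gap ~ mean |y| when gap is large
  s <- max(m2 - d^2, d, 0.25)           # sum from E y^2 = s + d^2
  c((s + d) / 2, max((s - d) / 2, 1e-6))
}

rates_equal_moments <- function(m2) {
  lam <- max(m2 / 2, 1e-4)
  c(lam, lam)
}

# 1-d k-means bins for initialization: returns a list of value subsets,
# ordered by cluster mean (k-means separates bulk and tail populations far
# better than quantile cuts when the data mix scales)
init_bins <- function(y, K) {
  if (K == 1L) return(list(y))
  km <- stats::kmeans(y, centers = K, nstart = 5, iter.max = 50)
  o <- order(km$centers)
  lapply(o, function(k) y[km$cluster == k])
}

fskellam_em <- function(y, K, init = NULL, init_weights = NULL, tol = 1e-6,
                        max_iter = 300L) {
  tab <- table(y)
  uy <- as.numeric(names(tab))
  w <- as.numeric(tab)
  n <- sum(w)
  if (is.null(init)) {
    # cluster starts: split the data into K bins, moment-match each
    bins <- init_bins(y, K)
    rates <- t(vapply(bins, function(yk) {
      if (length(yk) == 0L) yk <- y
      g <- rates_from_moments(mean(yk), mean(yk^2))
      e <- rates_equal_moments(mean(yk^2))
      if (fskellam_loglik(yk, e[1], e[2]) >=
            fskellam_loglik(yk, g[1], g[2])) e else g
    }, numeric(2)))
  } else {
    if (!is.matrix(init) || nrow(init) != K || ncol(init) != 2)
      stop("init must be a K x 2 matrix of rates")
    rates <- pmax(init, 1e-6)
  }
  pi_k <- if (is.null(init_weights)) rep(1 / K, K)
          else init_weights / sum(init_weights)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  iy <- as.integer(uy)
  ymax <- max(iy)
  comp_lp <- function(k) fsk_logpmf_all(ymax, rates[k, 1], rates[k, 2])[iy + 1L]
  lpmat <- matrix(vapply(seq_len(K), comp_lp, numeric(length(uy))),
                  nrow = length(uy))
  repeat {
    iter <- iter + 1L
    lp <- sweep(matrix(lpmat, nrow = length(uy)), 2, log(pi_k), `+`)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    r <- exp(lp - lse)
    nk <- colSums(w * r)
    pi_k <- pmax(nk / n, 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next                  # empty component: freeze
      wk <- w * r[, k]
      obj <- function(par) fsk_wnll(iy, wk, par)
      cur <- log(pmax(rates[k, ], 1e-8))
      m1 <- sum(wk * uy) / nk[k]
      m2 <- sum(wk * uy^2) / nk[k]
      cands <- list(cur,
                    log(pmax(rates_from_moments(m1, m2), 1e-8)),
                    log(pmax(rates_equal_moments(m2), 1e-8)))
      start <- cands[[which.min(vapply(cands, obj, 0))]]
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-10))
      best <- if (opt$value <= obj(cur)) exp(opt$par) else rates[k, ]
      rates[k, ] <- best
      lpmat[, k] <- comp_lp(k)
    }
  }
  # polish: near the equal-rates point the likelihood is flat along the
  # (sum, gap) ridge — the gap enters only at fourth order — so a single
  # Nelder-Mead run stalls short of the maximum.  Restart from a fan of
  # gap values at matched second moment and keep the best (the LRT needs
  # the true unconstrained maximum).
  lp <- sweep(lpmat, 2, log(pi_k), `+`)
  mm <- apply(lp, 1, max)
  r <- exp(lp - (mm + log(rowSums(exp(lp - mm)))))
  for (k in seq_len(K)) {
    wk <- w * r[, k]
    if (sum(wk) < 1e-8) next
    obj <- function(par) fsk_wnll(iy, wk, par)
    cur <- log(pmax(rates[k, ], 1e-8))
    s0 <- sum(exp(cur)) + diff(range(exp(cur)))^2   # preserve E y^2
    starts <- list(cur)
    for (d in c(0.5, 1, 2, 4, 8)) {
      s <- s0 - d^2
      if (s > d) starts <- c(starts, list(log(c((s + d) / 2, (s - d) / 2))))
    }
    best_par <- cur
    best_val <- obj(cur)
    for (st in starts) {
      opt <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-12))
      if (opt$value < best_val) { best_val <- opt$value; best_par <- opt$par }
    }
    rates[k, ] <- exp(best_par)
    lpmat[, k] <- comp_lp(k)
  }
  lp <- sweep(lpmat, 2, log(pi_k), `+`)
  mm <- apply(lp, 1, max)
  ll2 <- sum(w * (mm + log(rowSums(exp(lp - mm)))))
  if (ll2 >= ll) {
    ll <- ll2
    trace <- c(trace, ll2)
  }
  # canonical order: ascending total rate; within a pair, larger rate first
  o <- order(rates[, 1] + rates[, 2])
  rates <- rates[o, , drop = FALSE]
  pi_k <- pi_k[o]
  l1 <- pmax(rates[, 1], rates[, 2])
  l2 <- pmin(rates[, 1], rates[, 2])
  structure(list(K = as.integer(K), weights = pi_k, lambda1 = l1,
                 lambda2 = l2,
                 loglik = ll, bic = bic_value(ll, 3 * K - 1, n), n_obs = n,
                 fit_method = "em_exact", converged = converged,
                 iterations = iter, loglik_trace = trace),
            class = "fskmix")
}

#' Select the number of folded Skellam components by BIC
#'
#' Fits the mixture for every K in `k_range` (quantile-bin start plus
#' `restarts - 1` randomly perturbed starts, best log-likelihood kept) and
#' returns the fit minimizing BIC (`3K - 1` parameters); ties go to the
#' smaller K.
#'
#' @param y non-negative integer absolute differences.
#' @param k_range candidate component counts.
#' @param restarts EM starts per K.
#' @param seed optional integer seed.
#' @param ... passed to [fit_fskellam_mixture()].
#' @return the selected `"fskmix"` fit with a `bic_table` attribute.
#' @export
select_fskellam_k <- function(y, k_range = 1:8, restarts = 5L, seed = NULL,
                              ...) {
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  y <- check_counts(y)
  hi <- max(max(y), 2)
  fits <- list()
  for (K in sort(unique(k_range))) {
    best <- fit_fskellam_mixture(y, K, method = "em", ...)
    if (restarts > 1L && K > 1L) {
      for (r in seq_len(restarts - 1L)) {
        init <- matrix(exp(stats::runif(2 * K, log(0.5), log(2 * hi))),
                       ncol = 2)
        f <- fit_fskellam_mixture(y, K, method = "em", init = init, ...)
        if (f$loglik > best$loglik) best <- f
      }
    }
    fits[[as.character(K)]] <- best
  }
  tab <- data.frame(K = as.integer(names(fits)),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  sel <- fits[[which.min(tab$bic)]]
  attr(sel, "bic_table") <- tab
  sel
}

#' Posterior component probabilities for absolute differences
#'
#' @param object a `"fskmix"` fit.
#' @param newdata non-negative integer absolute differences.
#' @param type `"posterior"` for the n-by-K mixture-probability matrix (rows
#'   sum to 1) or `"class"` for argmax labels (ties to the lowest index).
#' @param ... unused.
#' @return matrix or integer vector.
#' @export
predict.fskmix <- function(object, newdata,
                           type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  y <- check_counts(newdata)
  lp <- vapply(seq_len(object$K),
               function(k) log(object$weights[k]) +
                 dfskellam(y, object$lambda1[k], object$lambda2[k], log = TRUE),
               numeric(length(y)))
  lp <- matrix(lp, nrow = length(y))
  m <- apply(lp, 1, max)
  post <- exp(lp - (m + log(rowSums(exp(lp - m)))))
  if (type == "class") return(apply(post, 1, which.max))
  post
}

#' Per-component likelihood-ratio tests for equal Poisson rates
#'
#' For each mixture component, the observations hard-assigned to it (argmax
#' posterior) are tested for allelic imbalance.  Under the null of no
#' imbalance the two rates are equal and estimated by the method of moments
#' (`mean(y^2)/2` on the assigned subset); the unconstrained log-likelihood
#' is evaluated at the component's globally fitted rate pair.  The statistic
#' `max(0, 2 * (L1 - L0))` is referred to chi-square(1).  Components with
#' fewer than `min_test_n` assigned observations are not tested
#' (`tested = FALSE`, statistic and p-value `NA`).
#'
#' Because L1 comes from the global mixture fit rather than a refit on the
#' assigned subset, the chi-square(1) reference is approximate; the clamp at
#' zero absorbs the (small) cases where the moment-based null scores higher.
#'
#' @param model a `"fskmix"` fit.
#' @param y the absolute differences the model was fitted to.
#' @param min_test_n minimum assigned observations for a test (default 10).
#' @param alpha significance level used for the Bonferroni column.
#' @return data frame with one row per component: `component`, `weight`,
#'   `lambda1`, `lambda2`, `n_assigned`, `lambda_null`, `L0`, `L1`, `stat`,
#'   `pvalue`, `pvalue_bonf`, `tested`.
#' @export
lrt_equal_means <- function(model, y, min_test_n = 10L, alpha = 0.05) {
  stopifnot(inherits(model, "fskmix"))
  y <- check_counts(y)
  lab <- predict(model, y, type = "class")
  res <- lapply(seq_len(model$K), function(k) {
    yk <- y[lab == k]
    nk <- length(yk)
    if (nk < min_test_n) {
      return(data.frame(component = k, weight = model$weights[k],
                        lambda1 = model$lambda1[k], lambda2 = model$lambda2[k],
                        n_assigned = nk, lambda_null = NA_real_,
                        L0 = NA_real_, L1 = NA_real_, stat = NA_real_,
                        pvalue = NA_real_, tested = FALSE))
    }
    lam0 <- mom_lambda_null(yk)
    L0 <- fskellam_loglik(yk, lam0, lam0)
    L1 <- fskellam_loglik(yk, model$lambda1[k], model$lambda2[k])
    t <- fskellam_lrt(L0, L1)
    data.frame(component = k, weight = model$weights[k],
               lambda1 = model$lambda1[k], lambda2 = model$lambda2[k],
               n_assigned = nk, lambda_null = lam0, L0 = L0, L1 = L1,
               stat = t$stat, pvalue = t$p.value, tested = TRUE)
  })
  out <- do.call(rbind, res)
  nt <- sum(out$tested)
  out$pvalue_bonf <- pmin(out$pvalue * max(nt, 1), 1)
  out
}

#' Designate AEI signal components
#'
#' Signal detection is contrastive: allelic imbalance shows up as components
#' lying further from zero than the bulk of comparable no-imbalance SNPs, so
#' the component closest to zero — smallest rate gap
#' \eqn{|\lambda_1 - \lambda_2|} — always serves as the no-signal reference
#' and is never designated (with a single component there is consequently no
#' signal).  Among the remaining components, a component is a signal
#' component if its LRT rejects equal rates at level `alpha`, or if it was
#' untested (too few assigned observations) but lies further from zero than
#' the smallest gap among the LRT-significant components.  With no
#' significant component the inherited rule is vacuous and the set is empty.
#'
#' @param model a `"fskmix"` fit.
#' @param tests output of [lrt_equal_means()].
#' @param alpha significance level (default 0.05).
#' @return integer vector of signal component indices (possibly empty).
#' @export
designate_signal_components <- function(model, tests, alpha = 0.05) {
  stopifnot(inherits(model, "fskmix"))
  gap <- abs(model$lambda1 - model$lambda2)
  reference <- which.min(gap)
  sig <- tests$tested & !is.na(tests$pvalue) & tests$pvalue < alpha &
    tests$component != reference
  if (!any(sig)) return(integer(0))
  min_gap <- min(gap[tests$component[sig]])
  inherit <- !tests$tested & gap[tests$component] > min_gap
  sort(tests$component[sig | inherit])
}

#' Classify SNPs by aggregated signal probability
#'
#' Computes, for each observation, the posterior over mixture components and
#' the aggregated signal probability (sum of posteriors over signal
#' components).  Under the `"max_prob"` rule a SNP is designated `AEI` when
#' its argmax component is a signal component; under the `"threshold"` rule
#' when the aggregated probability reaches `threshold` (e.g. 0.80 or 0.99).
#' SNPs not designated `AEI` whose aggregated signal probability still
#' exceeds `alpha` are reported `uncertain`; the rest are `no_AEI`.  A
#' confidence tier records whether the aggregated probability clears 0.80 or
#' 0.99.
#'
#' @param model a `"fskmix"` fit.
#' @param y absolute differences to classify.
#' @param signal integer vector of signal component indices.
#' @param rule `"max_prob"` or `"threshold"`.
#' @param threshold aggregated-probability cutoff for the threshold rule.
#' @param alpha floor above which a non-AEI SNP is called `uncertain`.
#' @return data frame with `component` (argmax), `signal_prob`,
#'   `designation` (`AEI`/`uncertain`/`no_AEI`) and `tier` (`p99`, `p80` or
#'   `max_prob`); the posterior matrix is attached as attribute
#'   `"posterior"`.
#' @export
classify_snps <- function(model, y, signal, rule = c("max_prob", "threshold"),
                          threshold = 0.8, alpha = 0.05) {
  rule <- match.arg(rule)
  post <- predict(model, y, type = "posterior")
  argmax <- apply(post, 1, which.max)
  sp <- if (length(signal) == 0L) rep(0, length(y))
        else rowSums(post[, signal, drop = FALSE])
  aei <- if (rule == "max_prob") argmax %in% signal else sp >= threshold
  desig <- ifelse(aei, "AEI", ifelse(sp > alpha, "uncertain", "no_AEI"))
  tier <- ifelse(sp > 0.99, "p99", ifelse(sp >= 0.80, "p80", "max_prob"))
  out <- data.frame(component = argmax, signal_prob = sp,
                    designation = desig, tier = tier,
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  out
}

#' @export
print.fskmix <- function(x, ...) {
  cat("Folded Skellam mixture (", x$fit_method, "), K = ", x$K, "\n", sep = "")
  cat(sprintf("  loglik %.2f  BIC %.2f  n %d\n", x$loglik, x$bic, x$n_obs))
  print(data.frame(component = seq_len(x$K),
                   weight = round(x$weights, 4),
                   lambda1 = round(x$lambda1, 2),
                   lambda2 = round(x$lambda2, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fskmix <- function(object, ...) {
  cbind(weight = object$weights, lambda1 = object$lambda1,
        lambda2 = object$lambda2)
}

#' @export
logLik.fskmix <- function(object, ...) {
  structure(object$loglik, df = 3 * object$K - 1, nobs = object$n_obs,
            class = "logLik")
}

#' Simulate from a fitted folded Skellam mixture
#'
#' Draws component labels from the mixture weights, then absolute Skellam
#' differences from the component rates (useful for goodness-of-fit
#' histograms of the fitted model against the observed differences).
#'
#' @param object a `"fskmix"` fit.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with columns `y` and `component`.
#' @export
simulate.fskmix <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  data.frame(y = abs(stats::rpois(nsim, object$lambda1[comp]) -
                       stats::rpois(nsim, object$lambda2[comp])),
             component = comp)
}

#' Histogram of absolute differences coloured by mixture component
#'
#' @param x a `"fskmix"` fit.
#' @param y the absolute differences the model was fitted to.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the per-component count matrix.
#' @export
plot.fskmix <- function(x, y, ...) {
  y <- check_counts(y)
  lab <- predict(x, y, type = "class")
  br <- 0:(max(y) + 1)
  counts <- t(vapply(seq_len(x$K),
                     function(k) tabulate(y[lab == k] + 1L, nbins = length(br) - 1),
                     numeric(length(br) - 1)))
  graphics::barplot(counts, names.arg = br[-length(br)],
                    col = grDevices::hcl.colors(x$K, "Dark 3"),
                    border = NA, space = 0,
                    xlab = "|adjusted read difference|", ylab = "SNPs",
                    legend.text = paste0("Mix", seq_len(x$K)), ...)
  invisible(counts)
}
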