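#' Fit a finite Poisson mixture by EM
#'
#' Fits a K-component univariate Poisson mixture to non-negative integer
#' data (here: rounded per-gene averages of library-adjusted read sums) with
#' the expectation-maximization algorithm.  Used to group SNPs into
#' "comparable" coverage classes: SNPs whose gene units fall in the same
#' component have total read sums of similar magnitude, so their allelic
#' count differences can be modelled jointly.
#'
#' The log-likelihood is non-decreasing over iterations; components are
#' reported in ascending order of their means.  The BIC uses `2K - 1` free
#' parameters (K means plus K-1 independent weights).
#'
#' @param x non-negative integers (values are tabulated internally, so large
#'   samples with few distinct values are cheap).
#' @param K number of components (must not exceed the number of distinct
#'   values).
#' @param init optional numeric vector of K starting means; default places
#'   them at K evenly spaced quantiles of `x`.
#' @param tol convergence tolerance on the log-likelihood improvement.
#' @param max_iter iteration cap.
#' @return an object of class `"poismix"`: list with `K`, `weights`, `means`,
#'   `loglik`, `bic`, `n_obs`, `converged`, `iterations`, `loglik_trace`.
#' @seealso [select_poisson_k()] for BIC-based choice of K,
#'   [predict.poismix()] for posterior classification.
#' @export
fit_poisson_mixture <- function(x, K, init = NULL, tol = 1e-8,
                                max_iter = 1000L) {
  x <- check_counts(x)
  if (K < 1) stop("K must be >= 1")
  tab <- table(x)
  ux <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (K > length(ux))
    stop("K (", K, ") exceeds the number of distinct values (", length(ux), ")")
  lambda <- if (is.null(init)) {
    pmax(stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE),
         1e-6)
  } else {
    if (length(init) != K) stop("init must have length K")
    pmax(init, 1e-6)
  }
  pi_k <- rep(1 / K, K)
  n <- sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lp <- vapply(seq_len(K),
                 function(k) log(pi_k[k]) + stats::dpois(ux, lambda[k], log = TRUE),
                 numeric(length(ux)))
    lp <- matrix(lp, nrow = length(ux))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    r <- exp(lp - lse)                       # responsibilities (rows sum to 1)
    nk <- colSums(w * r)
    pi_k <- nk / n
    lambda <- pmax(colSums(w * r * ux) / pmax(nk, 1e-300), 1e-6)
  }
  o <- order(lambda)
  out <- structure(list(K = as.integer(K), weights = pi_k[o],
                        means = lambda[o],
                        loglik = ll, bic = bic_value(ll, 2 * K - 1, n),
                        n_obs = n, converged = converged, iterations = iter,
                        loglik_trace = trace),
                   class = "poismix")
  out
}

#' Bayesian information criterion
#'
#' `-2 * loglik + n_params * log(n_obs)`.  For a K-component Poisson mixture
#' `n_params = 2K - 1`; for a K-component folded Skellam mixture
#' `n_params = 3K - 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_obs number of observations.
#' @return the BIC value (smaller is better).
#' @examples
#' bic_value(-216846, 13, 62326)  # ~433836
#' @export
bic_value <- function(loglik, n_params, n_obs) {
  if (n_obs < 1) stop("n_obs must be >= 1")
  -2 * loglik + n_params * log(n_obs)
}

#' Select the number of Poisson mixture components by BIC
#'
#' Fits the mixture for each K in `k_range` (quantile start plus
#' `restarts - 1` random restarts with means drawn log-uniformly over the
#' data range; the best log-likelihood per K is kept) and returns the fit
#' with the smallest BIC.  Ties go to the smaller K.
#'
#' @param x non-negative integers.
#' @param k_range candidate component counts.
#' @param restarts EM starts per K.
#' @param seed optional integer seed for the random restarts.
#' @param ... passed to [fit_poisson_mixture()].
#' @return the selected `"poismix"` fit, with a `bic_table` attribute
#'   (data frame of K, loglik, bic).
#' @export
select_poisson_k <- function(x, k_range = 1:10, restarts = 10L, seed = NULL,
                             ...) {
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  x <- check_counts(x)
  lo <- log(max(min(x), 0.5)); hi <- log(max(max(x), 1))
  fits <- list()
  for (K in sort(unique(k_range))) {
    best <- fit_poisson_mixture(x, K, ...)
    if (restarts > 1L && K > 1L) {
      for (r in seq_len(restarts - 1L)) {
        init <- exp(stats::runif(K, lo, hi))
        f <- fit_poisson_mixture(x, K, init = init, ...)
        if (f$loglik > best$loglik) best <- f
      }
    }
    fits[[as.character(K)]] <- best
  }
  tab <- data.frame(K = as.integer(names(fits)),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  sel <- fits[[which.min(tab$bic)]]          # which.min: ties -> first = smaller K
  attr(sel, "bic_table") <- tab
  sel
}

#' Posterior classification under a Poisson mixture
#'
#' @param object a `"poismix"` fit.
#' @param newdata numeric values to classify (rounded half-up to integers,
#'   matching the convention used when fitting gene-unit averages).
#' @param type `"class"` for hard labels (argmax posterior, ties to the
#'   lowest-mean component) or `"posterior"` for the n-by-K responsibility
#'   matrix (rows sum to 1).
#' @param ... unused.
#' @return integer component labels or a posterior matrix.
#' @export
predict.poismix <- function(object, newdata, type = c("class", "posterior"),
                            ...) {
  type <- match.arg(type)
  v <- round_half_up(newdata)
  lp <- vapply(seq_len(object$K),
               function(k) log(object$weights[k]) +
                 stats::dpois(v, object$means[k], log = TRUE),
               numeric(length(v)))
  lp <- matrix(lp, nrow = length(v))
  m <- apply(lp, 1, max)
  post <- exp(lp - (m + log(rowSums(exp(lp - m)))))
  if (type == "posterior") return(post)
  apply(post, 1, which.max)
}

#' Classify gene units into coverage components
#'
#' Attaches the hard component label and the posterior matrix of a fitted
#' Poisson mixture to a table of gene units (see [compute_unit_averages()]).
#'
#' @param model a `"poismix"` fit.
#' @param units data frame with a `mean_total` column.
#' @return `units` with an added integer `component` column; the posterior
#'   matrix is attached as attribute `"posterior"`.
#' @export
classify_units <- function(model, units) {
  stopifnot(inherits(model, "poismix"), "mean_total" %in% names(units))
  post <- predict(model, units$mean_total, type = "posterior")
  units$component <- apply(post, 1, which.max)
  attr(units, "posterior") <- post
  units
}

#' @export
print.poismix <- function(x, ...) {
  cat("Poisson mixture (EM), K =", x$K, "\n")
  cat(sprintf("  loglik %.2f  BIC %.2f  n %d  %s in %d iterations\n",
              x$loglik, x$bic, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(component = seq_len(x$K),
                   weight = round(x$weights, 4),
                   mean = round(x$means, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.poismix <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means)
}

#' @export
logLik.poismix <- function(object, ...) {
  structure(object$loglik, df = 2 * object$K - 1, nobs = object$n_obs,
            class = "logLik")
}

#' Simulate from a fitted Poisson mixture
#'
#' @param object a `"poismix"` fit.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param ... unused.
#' @return integer vector of draws.
#' @export
simulate.poismix <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  stats::rpois(nsim, object$means[comp])
}

check_counts <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty data")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("data must be non-negative integers")
  x
}

# round half away from zero (for non-negative input: half up)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
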