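# Independent brute-force oracle: P(Y1 - Y2 = k) by truncated convolution of
# two Poisson pmfs.  Used to validate the Bessel-function implementation.
skellam_pmf_conv <- function(k, lambda1, lambda2, trunc = 500) {
  j <- 0:trunc
  vapply(k, function(kk) sum(stats::dpois(kk + j, lambda1) *
                               stats::dpois(j, lambda2)), numeric(1))
}

folded_pmf_conv <- function(y, lambda1, lambda2, trunc = 500) {
  p <- skellam_pmf_conv(y, lambda1, lambda2, trunc)
  n <- skellam_pmf_conv(-y, lambda1, lambda2, trunc)
  ifelse(y == 0, p, p + n)
}

# minimal counts table used across preprocessing tests
tiny_counts <- function() {
  data.frame(
    subject = c("S1", "S1", "S1", "S2", "S2", "S2"),
    tissue = c("T1", "T1", "T2", "T1", "T1", "T1"),
    gene = c("gA", "gA", "gA", "gB", "gB", "gC"),
    snp = paste0("rs", 1:6),
    region = c("3utr", "exonic", "3utr", "intronic", "intergenic", "5utr"),
    ref_count = c(6L, 10L, 8L, 12L, 50L, 3L),
    var_count = c(9L, 10L, 4L, 3L, 50L, 100L),
    stringsAsFactors = FALSE)
}

# build a classed folded-Skellam mixture object from known parameters
# (for testing designation/classification logic against published-style
# configurations without refitting)
fskmix_object <- function(weights, lambda1, lambda2, n_obs = 1000L) {
  structure(list(K = length(weights), weights = weights / sum(weights),
                 lambda1 = lambda1, lambda2 = lambda2,
                 loglik = NA_real_, bic = NA_real_, n_obs = n_obs,
                 fit_method = "em_exact", converged = TRUE,
                 iterations = 0L, loglik_trace = numeric(0)),
            class = "fskmix")
}
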