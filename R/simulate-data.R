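#' Synthetic allele-count generator configuration
#'
#' Builds the configuration of the synthetic RNA-seq allele-count generator.
#' Counts follow the additive latent model \eqn{P = Y_1 + Z},
#' \eqn{M = Y_2 + Z} with independent \eqn{Y_1, Y_2} (Poisson) and a shared
#' non-negative component \eqn{Z}; the difference \eqn{P - M = Y_1 - Y_2} is
#' Skellam whatever the law of \eqn{Z}, while \eqn{Z} induces the strong
#' positive correlation between allele reads seen in real RNA-seq.
#'
#' Defaults emulate a multi-tissue human brain study: 10 subjects with 10
#' tissues each; gene SNP counts `1 + Geometric(0.315)`, so 78 percent of
#' genes carry at most 4 SNPs; three coverage classes with mean total reads
#' (8, 20, 43) and weights (0.77, 0.19, 0.04), putting ~95 percent of read
#' pairs below 33 reads; shared-component intensity 0.92 (fraction of the
#' lower allele mean carried by `Z`), which reproduces an allele-read
#' correlation of about 0.92 under the null; 6 percent of genes with allelic
#' imbalance at fold change `rho = 2.5`; log-normal library-size multipliers
#' (sdlog 0.25); unbiased Bernoulli(0.5) assignment of the reference allele
#' to a parental copy.
#'
#' @param n_subjects,tissues_per_subject study dimensions.
#' @param n_genes number of genes.
#' @param snps_per_gene function(n) returning n positive integers; default
#'   `1 + rgeom(n, 0.315)`.
#' @param coverage_weights,coverage_totals coverage-class mixture: sampling
#'   weights and mean total reads (R + V) per class.
#' @param aei_fraction fraction of genes with allelic imbalance.
#' @param rho fold change of the imbalanced parental copy (`> 0`).
#' @param z_intensity fraction of the lower allele mean carried by the shared
#'   component `Z`, in `[0, 1)`; 0 removes the shared component.
#' @param z_family law of `Z`: `"poisson"`, `"overdispersed"`
#'   (gamma-mixed Poisson, shape `z_shape`) or `"none"`.
#' @param z_shape gamma shape for the over-dispersed `Z`.
#' @param expr_prob probability a gene is expressed (observed) in a tissue.
#' @param library_sdlog sdlog of the per-sample log-normal depth multiplier.
#' @param ref_bias probability that the reference allele is the paternal
#'   copy (0.5 = unbiased; other values stress-test reference bias).
#' @param region_probs named sampling probabilities of genic region labels.
#' @return a list of class `"aei_sim_config"`.
#' @export
sim_config <- function(n_subjects = 10L,
                       tissues_per_subject = 10L,
                       n_genes = 60L,
                       snps_per_gene = function(n) 1L + stats::rgeom(n, 0.315),
                       coverage_weights = c(0.77, 0.19, 0.04),
                       coverage_totals = c(8, 20, 43),
                       aei_fraction = 0.06,
                       rho = 2.5,
                       z_intensity = 0.92,
                       z_family = c("poisson", "overdispersed", "none"),
                       z_shape = 5,
                       expr_prob = 0.7,
                       library_sdlog = 0.25,
                       ref_bias = 0.5,
                       region_probs = c(utr3 = 0.60, utr5 = 0.03,
                                        exon = 0.24, intron = 0.10,
                                        upstream = 0.01, downstream = 0.01,
                                        intergenic = 0.01)) {
  z_family <- match.arg(z_family)
  stopifnot(rho > 0, aei_fraction >= 0, aei_fraction <= 1,
            z_intensity >= 0, z_intensity < 1,
            length(coverage_weights) == length(coverage_totals),
            all(coverage_totals > 0), ref_bias >= 0, ref_bias <= 1,
            abs(sum(region_probs[names(region_probs) %in% region_levels]) -
                  sum(region_probs)) < 1e-12)
  structure(as.list(environment()), class = "aei_sim_config")
}

#' Simulate a synthetic allele-count dataset
#'
#' Draws an allele count table in the pipeline input schema together with a
#' per-SNP truth table.  For every expressed (subject, tissue, gene, SNP)
#' combination the paternal/maternal reads are \eqn{P = Y_1 + Z},
#' \eqn{M = Y_2 + Z}.  A gene's total coverage class fixes
#' \eqn{E(P) + E(M)}; for imbalanced genes \eqn{E(P) = \rho E(M)}
#' consistently across all the gene's SNPs and tissues.  The shared
#' component's rate is `z_intensity` times the lower allele mean, so the
#' fold change applies to total allelic expression while the difference
#' \eqn{P - M} remains Skellam\eqn{(\lambda_{Y_1}, \lambda_{Y_2})}.  Reads
#' are mapped to (reference, variant) orientation per (subject, SNP) and
#' scaled by the sample's library multiplier (rounded half away from zero).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return list with `counts` (columns `subject`, `tissue`, `gene`, `snp`,
#'   `region`, `ref_count`, `var_count`) and `truth` (those keys plus `rho`,
#'   `lambda_p`, `lambda_m`, `z_rate`, `aei_label`, and the pre-scaling reads
#'   `P`, `M`).
#' @export
simulate_aei_counts <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "aei_sim_config"))
  set.seed(seed)
  cf <- config
  subjects <- sprintf("S%02d", seq_len(cf$n_subjects))
  tissues <- sprintf("T%02d", seq_len(cf$tissues_per_subject))
  genes <- sprintf("g%03d", seq_len(cf$n_genes))
  n_snps_gene <- cf$snps_per_gene(cf$n_genes)
  cls <- sample.int(length(cf$coverage_totals), cf$n_genes, replace = TRUE,
                    prob = cf$coverage_weights)
  aei_gene <- stats::runif(cf$n_genes) < cf$aei_fraction
  snp_gene <- rep.int(seq_len(cf$n_genes), n_snps_gene)
  n_snp <- length(snp_gene)
  snp_id <- sprintf("rs%05d", seq_len(n_snp))
  snp_region <- sample(names(cf$region_probs), n_snp, replace = TRUE,
                       prob = cf$region_probs)

  # expand over subjects x tissues x expressed genes
  grid <- expand.grid(snp = seq_len(n_snp), tissue = tissues,
                      subject = subjects, stringsAsFactors = FALSE)
  gidx <- snp_gene[grid$snp]
  expr_key <- paste(grid$subject, grid$tissue, gidx)
  uk <- unique(expr_key)
  expressed <- stats::setNames(stats::runif(length(uk)) < cf$expr_prob, uk)
  grid <- grid[expressed[expr_key], , drop = FALSE]
  gidx <- snp_gene[grid$snp]
  n <- nrow(grid)

  rho_g <- ifelse(aei_gene, cf$rho, 1)[gidx]
  total <- cf$coverage_totals[cls[gidx]]
  ep <- total * rho_g / (1 + rho_g)      # paternal mean
  em <- total / (1 + rho_g)              # maternal mean
  lam_z <- cf$z_intensity * pmin(ep, em)
  if (cf$z_family == "none") lam_z <- rep(0, n)
  lam1 <- ep - lam_z
  lam2 <- em - lam_z
  z <- switch(cf$z_family,
              none = integer(n),
              poisson = stats::rpois(n, lam_z),
              overdispersed = stats::rpois(
                n, stats::rgamma(n, shape = cf$z_shape,
                                 rate = cf$z_shape / pmax(lam_z, 1e-12))))
  p <- stats::rpois(n, lam1) + z
  m <- stats::rpois(n, lam2) + z

  # reference allele orientation fixed per (subject, SNP)
  ok <- paste(grid$subject, grid$snp)
  uo <- unique(ok)
  ref_is_p <- stats::setNames(stats::runif(length(uo)) < cf$ref_bias, uo)[ok]
  r <- ifelse(ref_is_p, p, m)
  v <- ifelse(ref_is_p, m, p)

  mult <- stats::setNames(
    exp(stats::rnorm(cf$n_subjects * cf$tissues_per_subject, 0,
                     cf$library_sdlog)),
    as.vector(outer(tissues, subjects, function(t, s) paste(s, t))))
  mu <- mult[paste(grid$subject, grid$tissue)]

  counts <- data.frame(subject = grid$subject, tissue = grid$tissue,
                       gene = genes[gidx], snp = snp_id[grid$snp],
                       region = snp_region[grid$snp],
                       ref_count = as.integer(round_half_up(mu * r)),
                       var_count = as.integer(round_half_up(mu * v)),
                       stringsAsFactors = FALSE)
  truth <- data.frame(counts[c("subject", "tissue", "gene", "snp")],
                      rho = rho_g, lambda_p = ep, lambda_m = em,
                      z_rate = lam_z, aei_label = aei_gene[gidx],
                      P = p, M = m, stringsAsFactors = FALSE)
  o <- order(counts$subject, counts$tissue, counts$gene, counts$snp)
  list(counts = counts[o, , drop = FALSE], truth = truth[o, , drop = FALSE])
}

#' Confusion summary of AEI calls against simulation truth
#'
#' Joins a call table with the generator's truth table by (subject, tissue,
#' gene, snp) and summarizes detection performance.  SNPs present in the
#' truth but absent from the calls (filtered out, trimmed, or in skipped
#' strata) count as negative calls, so sensitivity reflects the whole
#' pipeline.  Metrics are reported overall and per fold-change stratum.
#'
#' @param calls data frame with the key columns and a `designation` column
#'   (`"AEI"` counted as a positive call).
#' @param truth the generator's truth table.
#' @return list with `overall` (data frame: tp, fp, fn, tn, sensitivity,
#'   specificity, fdr) and `by_rho` (same per fold change).
#' @export
truth_eval <- function(calls, truth) {
  key <- function(d) paste(d$subject, d$tissue, d$gene, d$snp, sep = "\r")
  kt <- key(truth)
  kc <- key(calls)
  if (any(!kc %in% kt))
    stop("calls contain SNP keys absent from the truth table")
  called_aei <- stats::setNames(calls$designation == "AEI", kc)
  pred <- ifelse(kt %in% kc, called_aei[kt], FALSE)
  conf <- function(truth_pos, pred_pos) {
    tp <- sum(truth_pos & pred_pos); fp <- sum(!truth_pos & pred_pos)
    fn <- sum(truth_pos & !pred_pos); tn <- sum(!truth_pos & !pred_pos)
    data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
  }
  by_rho <- do.call(rbind, lapply(split(seq_along(kt), truth$rho),
                                  function(i) conf(truth$aei_label[i],
                                                   pred[i])))
  by_rho <- cbind(rho = as.numeric(rownames(by_rho)), by_rho)
  rownames(by_rho) <- NULL
  list(overall = conf(truth$aei_label, pred), by_rho = by_rho)
}
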