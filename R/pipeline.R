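#' Pipeline configuration
#'
#' Collects the tunable constants of the AEI detection pipeline.  Defaults
#' follow the reference analysis: lower-allele threshold 3, intergenic SNPs
#' excluded, top 0.1 percent of gene units trimmed, Poisson mixture K chosen
#' over 1..10 and folded Skellam K over 1..8 by BIC, LRT level 0.05,
#' minimum 10 assigned SNPs per component test, strata under 50 SNPs left
#' unclassified.
#'
#' @param min_low_allele minimum raw reads for the lower allele.
#' @param exclude_regions regions dropped before analysis.
#' @param trim_fraction fraction of highest-coverage units removed.
#' @param poisson_k_range candidate K for the coverage mixture.
#' @param skellam_k_range candidate K for the folded Skellam mixtures.
#' @param target_components coverage components to analyze (`NULL` = all).
#' @param target_regions regions to analyze (`NULL` = all four modelled).
#' @param alpha LRT significance level (also the `uncertain` floor).
#' @param min_test_n minimum assigned SNPs for a component LRT.
#' @param min_stratum_n minimum SNPs for fitting a stratum mixture.
#' @param rule SNP classification rule, `"max_prob"` or `"threshold"`.
#' @param threshold aggregated signal probability cutoff (threshold rule).
#' @param backend folded Skellam fitting backend, `"em"` or `"abc"`.
#' @param restarts EM restarts per candidate K.
#' @param seed integer seed governing every random draw in a run.
#' @param library_totals optional per-sample totals (see
#'   [adjust_library_size()]).
#' @return list of class `"aei_config"`.
#' @export
aei_config <- function(min_low_allele = 3L,
                       exclude_regions = "intergenic",
                       trim_fraction = 0.001,
                       poisson_k_range = 1:10,
                       skellam_k_range = 1:8,
                       target_components = NULL,
                       target_regions = NULL,
                       alpha = 0.05,
                       min_test_n = 10L,
                       min_stratum_n = 50L,
                       rule = c("max_prob", "threshold"),
                       threshold = 0.8,
                       backend = c("em", "abc"),
                       restarts = 5L,
                       seed = 1L,
                       library_totals = NULL) {
  rule <- match.arg(rule)
  backend <- match.arg(backend)
  stopifnot(length(poisson_k_range) > 0, length(skellam_k_range) > 0,
            trim_fraction >= 0, trim_fraction < 1,
            alpha > 0, alpha < 1, threshold > 0, threshold <= 1)
  structure(as.list(environment()), class = "aei_config")
}

#' Run the AEI detection pipeline
#'
#' Executes the four analysis stages on a raw allele count table: (1) filter
#' SNPs and adjust for library size; (2) average adjusted read sums per gene
#' unit, trim the extreme top, fit the Poisson coverage mixture (K by BIC)
#' and classify units into comparable coverage classes; (3) within each
#' (coverage class x genic region) stratum, fit a folded Skellam mixture
#' (K by BIC) to the absolute adjusted read differences; (4) test every
#' component for unequal Poisson rates, designate signal components, and
#' classify SNPs.  Strata smaller than `min_stratum_n` are skipped and their
#' SNPs reported `unclassified`, as are upstream/downstream SNPs.
#'
#' @param counts a counts data frame (schema of [read_snp_counts()]) or a
#'   path to a TSV file.
#' @param config an [aei_config()] object.
#' @return object of class `"aei_run"`: list with `adjusted`, `units`
#'   (labelled, post-trim), `trimmed`, `poisson_model`, `strata_models`
#'   (per-stratum list of `fskmix`, `tests`, `signal`), `calls` (one row per
#'   input SNP retained after filtering), `manifest`.
#' @export
aei_run <- function(counts, config = aei_config()) {
  stopifnot(inherits(config, "aei_config"))
  if (is.character(counts)) counts <- read_snp_counts(counts)
  counts <- validate_snp_counts(counts)
  set.seed(config$seed)
  n_input <- nrow(counts)

  filtered <- filter_snps(counts, config$min_low_allele,
                          config$exclude_regions)
  if (nrow(filtered) == 0L) stop("stage filter: no SNPs left")
  adjusted <- adjust_library_size(filtered, config$library_totals)

  units <- compute_unit_averages(adjusted)
  tr <- trim_top_units(units, config$trim_fraction)
  ukey <- function(d) paste(d$subject, d$tissue, d$gene, sep = "\r")
  keep_snp <- ukey(adjusted) %in% ukey(tr$kept)
  body <- adjusted[keep_snp, , drop = FALSE]

  vals <- round_half_up(tr$kept$mean_total)
  krange <- config$poisson_k_range[config$poisson_k_range <=
                                     length(unique(vals))]
  if (length(krange) == 0L) krange <- 1L
  pm <- select_poisson_k(vals, k_range = krange, restarts = config$restarts)
  labelled <- classify_units(pm, tr$kept)

  st <- stratify_by_region(body, labelled)
  strata <- st$strata
  if (!is.null(config$target_components)) {
    keep <- vapply(strata, function(d) d$component[1] %in%
                     config$target_components, logical(1))
    strata <- strata[keep]
  }
  if (!is.null(config$target_regions)) {
    keep <- vapply(strata, function(d) d$region[1] %in%
                     config$target_regions, logical(1))
    strata <- strata[keep]
  }

  models <- list()
  call_rows <- list()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    if (nrow(d) < config$min_stratum_n) {
      warning("stratum ", nm, " has ", nrow(d), " SNPs (< ",
              config$min_stratum_n, "); left unclassified", call. = FALSE)
      call_rows[[nm]] <- unclassified_calls(d)
      next
    }
    y <- d$abs_diff
    skr <- config$skellam_k_range[config$skellam_k_range <=
                                    length(unique(y))]
    if (length(skr) == 0L) skr <- 1L
    fit <- if (config$backend == "em") {
      select_fskellam_k(y, k_range = skr, restarts = config$restarts)
    } else {
      fit_fskellam_abc(y, K = max(skr))
    }
    tests <- lrt_equal_means(fit, y, min_test_n = config$min_test_n,
                             alpha = config$alpha)
    signal <- designate_signal_components(fit, tests, alpha = config$alpha)
    cls <- classify_snps(fit, y, signal, rule = config$rule,
                         threshold = config$threshold, alpha = config$alpha)
    models[[nm]] <- list(model = fit, tests = tests, signal = signal)
    out <- cbind(d, cls)
    out$stratum <- nm
    out$ratio <- pmax(out$ref_count, out$var_count) /
      pmin(out$ref_count, out$var_count)
    out$diff_sign <- sign(out$diff_adj)
    post <- attr(cls, "posterior")
    colnames(post) <- paste0("p_mix", seq_len(ncol(post)))
    call_rows[[nm]] <- cbind(out, as.data.frame(post))
  }
  dropped_strata <- st$excluded
  if (nrow(dropped_strata) > 0L)
    call_rows[["excluded_regions"]] <- unclassified_calls(dropped_strata)

  calls <- rbind_fill(call_rows)
  if (nrow(calls) > 0L)
    calls <- calls[order(calls$subject, calls$tissue, calls$gene,
                         calls$snp), , drop = FALSE]
  rownames(calls) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("skellamAEI")),
    seed = config$seed,
    config = config[setdiff(names(config), "library_totals")],
    stage_counts = list(
      input = n_input, filtered_out = n_input - nrow(filtered),
      trimmed_units = nrow(tr$removed),
      trimmed_unit_snps = sum(!keep_snp),
      stratified = sum(vapply(strata, nrow, 0L)),
      excluded_regions = nrow(dropped_strata)),
    poisson = list(K = pm$K, bic = pm$bic, loglik = pm$loglik),
    strata = lapply(models, function(m)
      list(K = m$model$K, bic = m$model$bic, signal = m$signal)))

  structure(list(adjusted = adjusted, units = labelled, trimmed = tr$removed,
                 poisson_model = pm, strata_models = models, calls = calls,
                 manifest = manifest, config = config),
            class = "aei_run")
}

unclassified_calls <- function(d) {
  d$component_call <- NA_integer_
  d$signal_prob <- NA_real_
  d$designation <- "unclassified"
  d$tier <- NA_character_
  d$stratum <- NA_character_
  d$ratio <- pmax(d$ref_count, d$var_count) / pmin(d$ref_count, d$var_count)
  d$diff_sign <- sign(d$diff_adj)
  d
}

# rbind data frames with unequal columns (missing filled with NA)
rbind_fill <- function(lst) {
  lst <- lst[vapply(lst, function(d) !is.null(d) && nrow(d) > 0, logical(1))]
  if (length(lst) == 0L) return(data.frame())
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  }))
}

#' Extract the per-SNP call table from a pipeline run
#'
#' @param run an `"aei_run"` object.
#' @return data frame of calls.
#' @export
aei_calls <- function(run) {
  stopifnot(inherits(run, "aei_run"))
  run$calls
}

#' @export
print.aei_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("AEI pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat(sprintf("  input %d SNPs; filtered out %d; trimmed-unit SNPs %d\n",
              sc$input, sc$filtered_out, sc$trimmed_unit_snps))
  cat(sprintf("  coverage mixture: K = %d (BIC %.1f)\n",
              x$poisson_model$K, x$poisson_model$bic))
  cat(sprintf("  strata fitted: %d; SNPs classified: %d\n",
              length(x$strata_models),
              sum(x$calls$designation != "unclassified")))
  print(table(designation = x$calls$designation))
  invisible(x)
}

#' @export
summary.aei_run <- function(object, ...) {
  tab <- table(object$calls$designation)
  strata <- lapply(object$strata_models, function(m) {
    data.frame(K = m$model$K, signal_components =
                 paste(m$signal, collapse = ","),
               bic = m$model$bic)
  })
  out <- list(designations = tab,
              poisson = coef(object$poisson_model),
              strata = do.call(rbind, strata),
              n_aei_99 = sum(object$calls$designation == "AEI" &
                               object$calls$tier == "p99", na.rm = TRUE))
  class(out) <- "summary.aei_run"
  out
}

#' @export
print.summary.aei_run <- function(x, ...) {
  cat("Designations:\n"); print(x$designations)
  cat("\nCoverage mixture components:\n"); print(round(x$poisson, 3))
  if (!is.null(x$strata)) {
    cat("\nPer-stratum folded Skellam fits:\n"); print(x$strata)
  }
  cat("\nAEI calls at the 99% tier:", x$n_aei_99, "\n")
  invisible(x)
}

#' Cross-region consistency of AEI designations
#'
#' For every (subject, SNP) observed in at least two tissues, compares the
#' number of tissues where the SNP is designated AEI with the number of
#' tissues where it is expressed; the designation is consistent when AEI is
#' called in at least half of the expressed tissues.
#'
#' @param calls pipeline call table (see [aei_calls()]).
#' @return data frame with `subject`, `snp`, `n_regions_expressed`,
#'   `n_regions_aei`, `consistent`.
#' @export
consistency_report <- function(calls) {
  key <- paste(calls$subject, calls$snp, sep = "\r")
  spl <- split(seq_len(nrow(calls)), key)
  rec <- lapply(spl, function(i) {
    ne <- length(unique(calls$tissue[i]))
    if (ne < 2L) return(NULL)
    na <- length(unique(calls$tissue[i][calls$designation[i] == "AEI"]))
    data.frame(subject = calls$subject[i][1], snp = calls$snp[i][1],
               n_regions_expressed = ne, n_regions_aei = na,
               consistent = na >= ceiling(ne / 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  if (is.null(out))
    return(data.frame(subject = character(), snp = character(),
                      n_regions_expressed = integer(),
                      n_regions_aei = integer(), consistent = logical()))
  rownames(out) <- NULL
  out[order(out$subject, out$snp), , drop = FALSE]
}

#' Percentiles of absolute read ratios by designation group
#'
#' Tabulates min, deciles and max of the absolute raw read ratio
#' `max(R, V) / min(R, V)` separately for each designation group.  Ratios use
#' raw counts; library adjustment preserves them exactly.  Percentiles use
#' linear interpolation between order statistics.
#'
#' @param calls pipeline call table with `ref_count`, `var_count` and a
#'   grouping column.
#' @param group name of the grouping column (default `"designation"`).
#' @return data frame, one row per group: group, n, min, 10%..90%, max.
#' @export
ratio_percentile_table <- function(calls, group = "designation") {
  ratio <- pmax(calls$ref_count, calls$var_count) /
    pmin(calls$ref_count, calls$var_count)
  g <- calls[[group]]
  rows <- lapply(split(ratio, g), function(r) {
    q <- stats::quantile(r, probs = c(0, seq(0.1, 0.9, 0.1), 1),
                         names = FALSE, type = 7)
    c(n = length(r), stats::setNames(q, c("min", paste0("p", 1:9 * 10),
                                          "max")))
  })
  out <- data.frame(group = names(rows), do.call(rbind, rows),
                    check.names = FALSE, row.names = NULL)
  out
}

#' Write the outputs of a pipeline run
#'
#' Writes `adjusted.tsv`, `poisson_model.tsv`, per-stratum model TSVs under
#' `skellam_models/`, `calls.tsv`, `consistency.tsv` and `manifest.json`.
#' Numeric columns of `calls.tsv` are written with full precision and fixed
#' notation, so identical runs produce byte-identical files.
#'
#' @param run an `"aei_run"` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_aei_run <- function(run, dir) {
  stopifnot(inherits(run, "aei_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    format(d, digits = 15, trim = TRUE, scientific = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$adjusted, "adjusted.tsv")
  pm <- run$poisson_model
  wt(data.frame(component = seq_len(pm$K), weight = pm$weights,
                mean = pm$means, loglik = pm$loglik, bic = pm$bic),
     "poisson_model.tsv")
  dir.create(file.path(dir, "skellam_models"), showWarnings = FALSE)
  for (nm in names(run$strata_models)) {
    m <- run$strata_models[[nm]]
    tab <- m$tests
    tab$signal <- tab$component %in% m$signal
    utils::write.table(format(tab, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       file.path(dir, "skellam_models", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(run$calls, "calls.tsv")
  wt(consistency_report(run$calls), "consistency.tsv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
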