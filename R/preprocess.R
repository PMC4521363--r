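#' Read a per-SNP allele count table
#'
#' Reads a tab-delimited UTF-8 file with header columns `subject`, `tissue`,
#' `gene`, `snp`, `region`, `ref_count`, `var_count`.  Region tokens are
#' case-insensitive and normalized: `3utr`/`utr3`, `5utr`/`utr5`,
#' `exonic`/`exon`, `intronic`/`intron`, `intergenic`, `upstream`,
#' `downstream`.
#'
#' @param file path to the TSV file.
#' @return data frame of SNP observations with normalized `region` labels.
#' @export
read_snp_counts <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  validate_snp_counts(x)
}

#' @rdname read_snp_counts
#' @param x a data frame already in the counts schema.
#' @export
validate_snp_counts <- function(x) {
  need <- c("subject", "tissue", "gene", "snp", "region",
            "ref_count", "var_count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(x$ref_count < 0) || any(x$var_count < 0) ||
      any(x$ref_count != round(x$ref_count)) ||
      any(x$var_count != round(x$var_count)))
    stop("ref_count and var_count must be non-negative integers")
  x$region <- normalize_region(x$region)
  x
}

region_levels <- c("utr3", "utr5", "exon", "intron",
                   "upstream", "downstream", "intergenic")

normalize_region <- function(r) {
  r <- tolower(trimws(as.character(r)))
  map <- c("3utr" = "utr3", "utr3" = "utr3", "3'utr" = "utr3",
           "5utr" = "utr5", "utr5" = "utr5", "5'utr" = "utr5",
           "exonic" = "exon", "exon" = "exon",
           "intronic" = "intron", "intron" = "intron",
           "intergenic" = "intergenic", "upstream" = "upstream",
           "downstream" = "downstream")
  out <- unname(map[r])
  if (anyNA(out))
    stop("unrecognized region label(s): ",
         paste(unique(r[is.na(out)]), collapse = ", "))
  out
}

#' Filter SNPs on minimum allele coverage and region
#'
#' Retains SNPs with at least `min_low_allele` raw reads for the
#' lower-expressed allele (`min(R, V) >= 3` by default) and drops SNPs in the
#' excluded regions (intergenic by default).  Applied to raw counts, before
#' library-size adjustment.
#'
#' @param counts SNP count data frame (see [read_snp_counts()]).
#' @param min_low_allele minimum reads for the lower allele.
#' @param exclude_regions character vector of region labels to drop.
#' @return the filtered data frame (warns if empty).
#' @export
filter_snps <- function(counts, min_low_allele = 3L,
                        exclude_regions = "intergenic") {
  counts <- validate_snp_counts(counts)
  keep <- pmin(counts$ref_count, counts$var_count) >= min_low_allele &
    !(counts$region %in% exclude_regions)
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no SNPs pass the filter")
  rownames(out) <- NULL
  out
}

#' Library-size adjustment of allele counts
#'
#' Multiplies each read pair by the ratio of the median per-sample total read
#' count to the sample's own total, so samples sequenced deeper are scaled
#' down and vice versa.  The adjustment preserves the within-pair ratio
#' exactly.  By default the sample total is the sum of `ref_count +
#' var_count` over the sample's retained SNPs; true library sizes may be
#' supplied instead via `library_totals`.
#'
#' @param counts SNP count data frame.
#' @param library_totals optional data frame with columns `subject`,
#'   `tissue`, `total` overriding the per-sample totals.
#' @return `counts` with added columns `ref_adj`, `var_adj`, `scale`,
#'   `sum_adj`, `diff_adj` (signed, real) and `abs_diff` (absolute adjusted
#'   difference rounded half away from zero, the folded-Skellam observable).
#' @export
adjust_library_size <- function(counts, library_totals = NULL) {
  counts <- validate_snp_counts(counts)
  key <- paste(counts$subject, counts$tissue, sep = "\r")
  if (is.null(library_totals)) {
    tot <- tapply(counts$ref_count + counts$var_count, key, sum)
  } else {
    if (!all(c("subject", "tissue", "total") %in% names(library_totals)))
      stop("library_totals needs columns subject, tissue, total")
    tot <- stats::setNames(library_totals$total,
                           paste(library_totals$subject,
                                 library_totals$tissue, sep = "\r"))
  }
  own <- tot[key]
  bad <- is.na(own) | own <= 0
  if (any(bad))
    stop("missing or non-positive library total for sample(s): ",
         paste(unique(gsub("\r", "/", key[bad])), collapse = ", "))
  scale <- stats::median(tot) / as.numeric(own)
  counts$ref_adj <- scale * counts$ref_count
  counts$var_adj <- scale * counts$var_count
  counts$scale <- scale
  counts$sum_adj <- counts$ref_adj + counts$var_adj
  counts$diff_adj <- counts$ref_adj - counts$var_adj
  counts$abs_diff <- round_half_up(abs(counts$diff_adj))
  counts
}

#' Per-gene-unit coverage averages
#'
#' A unit is one gene in one tissue of one subject ("tissue-specific gene");
#' the same gene in two tissues forms two units.  For each unit the adjusted
#' read sums of its SNPs are averaged; these averages are the input of the
#' Poisson coverage mixture.
#'
#' @param adjusted output of [adjust_library_size()].
#' @return data frame with `subject`, `tissue`, `gene`, `mean_total`,
#'   `n_snps`.
#' @export
compute_unit_averages <- function(adjusted) {
  if (nrow(adjusted) == 0L) stop("empty table")
  if (!"sum_adj" %in% names(adjusted))
    stop("run adjust_library_size() first")
  key <- interaction(adjusted$subject, adjusted$tissue, adjusted$gene,
                     drop = TRUE, sep = "\r")
  agg <- data.frame(key = levels(key),
                    mean_total = as.numeric(tapply(adjusted$sum_adj, key, mean)),
                    n_snps = as.integer(tapply(adjusted$sum_adj, key, length)),
                    stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- data.frame(subject = parts[, 1], tissue = parts[, 2],
                    gene = parts[, 3], mean_total = agg$mean_total,
                    n_snps = agg$n_snps, stringsAsFactors = FALSE)
  out[order(out$subject, out$tissue, out$gene), , drop = FALSE]
}

#' Trim the highest-coverage gene units
#'
#' Removes the `ceiling(fraction * N)` units with the largest average scaled
#' counts (0.1 percent by default) before fitting the coverage mixture; the
#' extreme tail otherwise dominates the largest Poisson component.  Ties are
#' broken deterministically by descending `mean_total`, then subject, tissue,
#' gene.
#'
#' @param units output of [compute_unit_averages()].
#' @param fraction fraction of units to remove, in `[0, 1)`.
#' @return list with elements `kept` and `removed`.
#' @export
trim_top_units <- function(units, fraction = 0.001) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(units)
  n_remove <- if (fraction == 0) 0L else as.integer(ceiling(fraction * n))
  o <- order(-units$mean_total, units$subject, units$tissue, units$gene)
  idx <- o[seq_len(n_remove)]
  list(kept = units[setdiff(seq_len(n), idx), , drop = FALSE],
       removed = units[idx, , drop = FALSE])
}

#' Stratify SNPs by coverage component and genic region
#'
#' Partitions adjusted SNP rows into (Poisson component) x (region) strata
#' for the four modelled regions (3'UTR, 5'UTR, exon, intron); fluctuations
#' of read differences are only comparable within one coverage class and one
#' region.  Upstream/downstream SNPs are returned separately, unstratified.
#'
#' @param adjusted output of [adjust_library_size()].
#' @param unit_labels output of [classify_units()]: unit table with a
#'   `component` column.  Every unit appearing in `adjusted` must be
#'   labelled.
#' @return list with `strata` (named list of data frames,
#'   `"comp<k>_<region>"`) and `excluded` (upstream/downstream rows, with
#'   their component label).
#' @export
stratify_by_region <- function(adjusted, unit_labels) {
  key <- paste(adjusted$subject, adjusted$tissue, adjusted$gene, sep = "\r")
  lkey <- paste(unit_labels$subject, unit_labels$tissue, unit_labels$gene,
                sep = "\r")
  comp <- unit_labels$component[match(key, lkey)]
  if (anyNA(comp))
    stop("unlabeled gene unit(s): ",
         paste(utils::head(unique(gsub("\r", "/", key[is.na(comp)])), 5),
               collapse = ", "))
  adjusted$component <- comp
  modelled <- c("utr3", "utr5", "exon", "intron")
  in_model <- adjusted$region %in% modelled
  excluded <- adjusted[!in_model, , drop = FALSE]
  body <- adjusted[in_model, , drop = FALSE]
  f <- interaction(paste0("comp", body$component), body$region,
                   drop = TRUE, sep = "_")
  strata <- split(body, f)
  list(strata = strata[order(names(strata))], excluded = excluded)
}
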