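#' Define a gene region with flanking sequence
#'
#' @param chrom Chromosome label (with or without a `"chr"` prefix).
#' @param start,end 1-based base positions, `start <= end`.
#' @param flank Bases added on both sides (default 0).
#' @return A `gene_region` object.
#' @examples
#' # the GCK coding region on GRCh37 with a 100-kb flank
#' gene_region("7", 44182812, 44229038, flank = 1e5)
#' @export
gene_region <- function(chrom, start, end, flank = 0) {
  stopifnot(start <= end, flank >= 0)
  structure(list(chrom = sub("^chr", "", as.character(chrom)),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank)),
            class = "gene_region")
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("chr%s:%.0f-%.0f (flank %.0f bp -> window chr%s:%.0f-%.0f)\n",
              x$chrom, x$start, x$end, x$flank,
              x$chrom, x$start - x$flank, x$end + x$flank))
  invisible(x)
}

keep_rows <- function(table, keep) {
  at <- attributes(table)
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_name", "trait_unit", "ancestry", "sample_size", "build")) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Restrict a summary-statistics table to (or away from) a gene region
#'
#' `mode = "within"` keeps variants with `start - flank <= pos <= end + flank`
#' on the region's chromosome; `mode = "exclude"` keeps the complement. Used
#' to build cis instruments for a drug-target design and genome-wide
#' instruments that exclude the target region.
#'
#' @param table A `sumstats` object.
#' @param region A [gene_region()].
#' @param mode `"within"` or `"exclude"`.
#' @return Filtered `sumstats` object (possibly empty of rows).
#' @export
filter_by_region <- function(table, region, mode = c("within", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(region, "gene_region"))
  inside <- table$chrom == region$chrom &
    table$pos >= region$start - region$flank &
    table$pos <= region$end + region$flank
  keep <- if (mode == "within") inside else !inside
  if (!any(keep)) message("filter_by_region: no variants retained")
  keep_rows(table, keep)
}

#' Filter by genome-wide significance threshold
#'
#' Retains variants with `pvalue <= threshold` (inclusive boundary).
#'
#' @param table A `sumstats` object.
#' @param threshold P-value threshold in (0, 1); conventionally `5e-8`.
#' @export
filter_by_pvalue <- function(table, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  keep_rows(table, table$pvalue <= threshold)
}

#' Construct an LD matrix of squared correlations
#'
#' @param r2 Square numeric matrix of pairwise r-squared values in \[0, 1\].
#' @param variant_ids rsid labels; taken from `rownames(r2)` when missing.
#' @return An `ld_matrix` object (matrix with rsid dimnames).
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("variant_ids required", call. = FALSE)
  stopifnot(nrow(r2) == ncol(r2), length(variant_ids) == nrow(r2))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric", call. = FALSE)
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("r2 values outside [0, 1]", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  r2 <- pmin(pmax(r2, 0), 1)
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Compute an LD matrix from a genotype dosage matrix
#'
#' r-squared between two variants is the squared Pearson correlation of
#' their dosage vectors across reference samples (the statistic PLINK-style
#' clumping thresholds on).
#'
#' @param genotypes Numeric matrix, variants in rows and samples in columns,
#'   entries in \[0, 2\]; rownames are rsids.
#' @return An `ld_matrix` object.
#' @export
compute_ld_from_genotypes <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- apply(genotypes, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance variant(s): ",
         paste(rownames(genotypes)[v == 0], collapse = ", "), call. = FALSE)
  }
  r2 <- stats::cor(t(genotypes))^2
  diag(r2) <- 1
  ld_matrix(r2, rownames(genotypes))
}

#' Read / write an LD matrix as square TSV
#'
#' The format is a square table with rsids as both header row and first
#' column.
#' @param path File path.
#' @rdname ld_matrix_io
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  ld_matrix(as.matrix(tab), rownames(tab))
}

#' @param ld An `ld_matrix` object.
#' @rdname ld_matrix_io
#' @export
write_ld_matrix <- function(ld, path) {
  tab <- data.frame(rsid = rownames(ld), unclass(ld), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the unprocessed variant with the
#' smallest p-value as index, retain it, and remove all unprocessed variants
#' on the same chromosome within `window_bases` of it whose r-squared with
#' the index exceeds `r2_threshold`. Ties on p-value are broken by smaller
#' genomic position, then lexicographic rsid, so the result is independent
#' of input row order. Variants absent from the LD source are dropped from
#' candidacy with a warning rather than assumed independent.
#'
#' @param table A `sumstats` object.
#' @param ld An `ld_matrix` covering the table's rsids.
#' @param r2_threshold Retained pairs within the window must have
#'   `r2 <= r2_threshold`.
#' @param window_bases Window half-width in bases around the index variant,
#'   inclusive; the conventional drug-target setting is 10 Mb.
#' @return `sumstats` object of retained index variants, in retention order.
#' @export
clump <- function(table, ld, r2_threshold = 0.3, window_bases = 1e7) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_bases >= 0)
  in_ld <- table$rsid %in% rownames(ld)
  if (!all(in_ld)) {
    warning("dropped ", sum(!in_ld),
            " variant(s) absent from the LD source before clumping",
            call. = FALSE)
    table <- keep_rows(table, in_ld)
  }
  if (nrow(table) == 0L) return(table)
  ord <- order(table$pvalue, table$pos, table$rsid)
  df <- as.data.frame(table)[ord, , drop = FALSE]
  r2 <- unclass(ld)[df$rsid, df$rsid, drop = FALSE]
  active <- rep(TRUE, nrow(df))
  retained <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!active[i]) next
    retained <- c(retained, i)
    prune <- active & df$chrom == df$chrom[i] &
      abs(df$pos - df$pos[i]) <= window_bases &
      r2[i, ] > r2_threshold
    active[prune] <- FALSE
    active[i] <- FALSE
  }
  keep <- match(df$rsid[retained], table$rsid)
  keep_rows(table, keep)
}

#' Per-variant instrument-strength F statistic
#'
#' The single-variant approximation `F = (beta / se)^2`, the square of the
#' GWAS z-score. An alternative explained-variance form
#' `F = (n - 2) * r2 / (1 - r2)` with `r2 = 2 * eaf * (1 - eaf) * beta^2 /
#' (2 * eaf * (1 - eaf) * beta^2 + 2 * eaf * (1 - eaf) * n * se^2)` is
#' available when `eaf` and `n` are known; the two agree closely for traits
#' analyzed on a variance-standardized scale.
#'
#' @param beta,se Per-allele effect and standard error (vectors allowed).
#' @param method `"ratio"` (default) or `"r2"`.
#' @param eaf,n Effect-allele frequency and sample size, required for
#'   `method = "r2"`.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se, method = c("ratio", "r2"), eaf = NULL, n = NULL) {
  method <- match.arg(method)
  stopifnot(all(se > 0))
  if (method == "ratio") return((beta / se)^2)
  if (is.null(eaf) || is.null(n)) stop("method 'r2' needs eaf and n", call. = FALSE)
  v <- 2 * eaf * (1 - eaf)
  r2 <- v * beta^2 / (v * beta^2 + v * n * se^2)
  (n - 2) * r2 / (1 - r2)
}

#' Select independent instruments from a summary-statistics table
#'
#' Runs the selection cascade: region filter (cis, or genome-wide with the
#' region excluded), p-value filter, greedy LD clumping, then per-variant
#' and mean F statistics.
#'
#' @param table Exposure `sumstats`.
#' @param region A [gene_region()]; kept for `mode = "cis"`, excluded for
#'   `mode = "genome-wide"`. May be `NULL` for `mode = "genome-wide"`.
#' @param mode `"cis"` or `"genome-wide"`.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param ld An `ld_matrix` over the candidate variants.
#' @param r2_threshold Clumping r-squared threshold; if `NULL`, defaults to
#'   0.3 for cis and 0.001 for genome-wide designs.
#' @param window_bases Clumping window (default 10 Mb).
#' @return An `instrument_set`: list with `instruments` (sumstats),
#'   `per_variant_F`, `mean_F`, `selection_mode`, `params`, and per-stage
#'   candidate `counts`.
#' @export
select_instruments <- function(table, region, mode = c("cis", "genome-wide"),
                               p_threshold = 5e-8, ld, r2_threshold = NULL,
                               window_bases = 1e7) {
  mode <- match.arg(mode)
  if (is.null(r2_threshold)) r2_threshold <- if (mode == "cis") 0.3 else 0.001
  if (mode == "cis") {
    stopifnot(!is.null(region))
    cand <- filter_by_region(table, region, "within")
  } else if (!is.null(region)) {
    cand <- filter_by_region(table, region, "exclude")
  } else {
    cand <- table
  }
  sig <- filter_by_pvalue(cand, p_threshold)
  if (nrow(sig) == 0L) stop("no instruments: no variants pass p <= ", p_threshold,
                            call. = FALSE)
  inst <- clump(sig, ld, r2_threshold = r2_threshold, window_bases = window_bases)
  if (nrow(inst) == 0L) stop("no instruments retained after clumping", call. = FALSE)
  f <- f_statistic(inst$beta, inst$se)
  structure(list(instruments = inst, per_variant_F = f, mean_F = mean(f),
                 selection_mode = mode,
                 params = list(p_threshold = p_threshold,
                               clump_window_bases = window_bases,
                               r2_threshold = r2_threshold,
                               region = if (mode == "cis") region else NULL,
                               excluded_region = if (mode != "cis") region else NULL),
                 counts = c(candidates = nrow(cand), significant = nrow(sig),
                            clumped = nrow(inst))),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("%s instrument set: %d variants, mean F = %.1f\n",
              x$selection_mode, nrow(x$instruments), x$mean_F))
  cat(sprintf("  p <= %g, clump window %g bp, r2 threshold %g\n",
              x$params$p_threshold, x$params$clump_window_bases,
              x$params$r2_threshold))
  invisible(x)
}
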