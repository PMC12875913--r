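# Canonical internal column order for a summary-statistics table.
SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# Shipped column dialects. Each maps canonical names to source header names.
# "finngen-r5" follows the FinnGen release-5 export convention, where the
# ALT allele is the effect allele.
SUMSTATS_DIALECTS <- list(
  "generic" = c(rsid = "rsid", chrom = "chrom", pos = "pos",
                ea = "effect_allele", oa = "other_allele", eaf = "eaf",
                beta = "beta", se = "se", p = "pvalue", n = "n"),
  "magic" = c(rsid = "variant", chrom = "chromosome", pos = "base_pair_location",
              ea = "effect_allele", oa = "other_allele",
              eaf = "effect_allele_frequency", beta = "beta",
              se = "standard_error", p = "p_value", n = "sample_size"),
  "finngen-r5" = c(rsid = "rsids", chrom = "#chrom", pos = "pos",
                   ea = "alt", oa = "ref", eaf = "af_alt",
                   beta = "beta", se = "sebeta", p = "pval", n = NA)
)

#' Construct a validated summary-statistics table
#'
#' Builds the package's internal representation of per-variant GWAS
#' associations: a data frame with columns `rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#' carrying the trait metadata as attributes. Rows violating the record
#' invariants (non-SNP alleles, `se <= 0`, `pvalue` outside (0, 1], `eaf`
#' outside \[0, 1\], `pos < 1`) are dropped with a warning; duplicate rsids
#' are resolved by keeping the record with the smallest p-value; p-values of
#' exactly zero are floored to the smallest positive double.
#'
#' @param df Data frame holding (at least) the canonical columns. `eaf` and
#'   `n` may be absent and are filled with `NA`.
#' @param trait_name,trait_unit,ancestry Trait metadata strings.
#' @param sample_size Study-level sample size (optional).
#' @param build Genome build label carried as metadata (default `"GRCh37"`).
#' @return A `sumstats` object (data frame).
#' @export
sumstats <- function(df, trait_name = NA_character_, trait_unit = NA_character_,
                     ancestry = NA_character_, sample_size = NA_integer_,
                     build = "GRCh37") {
  for (col in c("eaf", "n")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, c("eaf", "n")), names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[SUMSTATS_COLS]
  df$rsid <- as.character(df$rsid)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$pos <- as.numeric(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  n_zero_p <- sum(!is.na(df$pvalue) & df$pvalue == 0)
  if (n_zero_p > 0) {
    warning(n_zero_p, " p-value(s) of exactly 0 floored to smallest positive double",
            call. = FALSE)
    df$pvalue[!is.na(df$pvalue) & df$pvalue == 0] <- .Machine$double.xmin
  }

  snp <- c("A", "C", "G", "T")
  ok <- !is.na(df$rsid) & nzchar(df$rsid) &
    df$effect_allele %in% snp & df$other_allele %in% snp &
    df$effect_allele != df$other_allele &
    !is.na(df$beta) & !is.na(df$se) & df$se > 0 &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    !is.na(df$pos) & df$pos >= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning("dropped ", n_bad, " record(s) violating association invariants",
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }

  # duplicate rsids: keep smallest p-value (ties: first occurrence)
  if (anyDuplicated(df$rsid)) {
    ord <- order(df$pvalue)
    keep <- ord[!duplicated(df$rsid[ord])]
    n_dup <- nrow(df) - length(keep)
    warning("dropped ", n_dup, " duplicate rsid record(s), keeping smallest p-value",
            call. = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid summary-statistics records", call. = FALSE)

  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name, trait_unit = trait_unit,
            ancestry = ancestry, sample_size = sample_size, build = build,
            n_dropped = n_bad,
            class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table (optionally gzipped), renames the
#' columns of the requested dialect to the internal canonical schema, and
#' validates the records via [sumstats()].
#'
#' @param path File path.
#' @param dialect One of `"generic"`, `"magic"`, `"finngen-r5"`, or the
#'   string `"custom"` together with `col_map`.
#' @param col_map Named character vector overriding the dialect, with names
#'   among `rsid, chrom, pos, ea, oa, eaf, beta, se, p, n` and values giving
#'   the source column headers. `eaf` and `n` are optional.
#' @param sep Field separator; guessed from the header line when `NULL`.
#' @inheritParams sumstats
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, dialect = "generic", col_map = NULL,
                          trait_name = NA_character_, trait_unit = NA_character_,
                          ancestry = NA_character_, sample_size = NA_integer_,
                          build = "GRCh37", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(col_map)) {
    if (!dialect %in% names(SUMSTATS_DIALECTS)) {
      stop("unknown dialect '", dialect, "'; supply col_map", call. = FALSE)
    }
    col_map <- SUMSTATS_DIALECTS[[dialect]]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  header <- readLines(con, n = 1L)
  close(con)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")

  canon <- c(rsid = "rsid", chrom = "chrom", pos = "pos", ea = "effect_allele",
             oa = "other_allele", eaf = "eaf", beta = "beta", se = "se",
             p = "pvalue", n = "n")
  mandatory <- c("rsid", "chrom", "pos", "ea", "oa", "beta", "se", "p")
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (key in names(canon)) {
    src <- if (key %in% names(col_map)) col_map[[key]] else NA
    if (is.na(src) || !src %in% names(raw)) {
      if (key %in% mandatory) {
        stop("dialect does not resolve mandatory column '", key,
             "' (expected source column '", src, "')", call. = FALSE)
      }
      next
    }
    df[[canon[[key]]]] <- raw[[src]]
  }
  sumstats(df, trait_name = trait_name, trait_unit = trait_unit,
           ancestry = ancestry, sample_size = sample_size, build = build)
}

#' Write a summary-statistics table as generic-dialect TSV
#'
#' @param table A `sumstats` object.
#' @param path Output path.
#' @export
write_sumstats <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants, build %s\n",
              attr(x, "trait_name"), attr(x, "trait_unit"), nrow(x),
              attr(x, "build")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

result_section <- function(x) {
  if (inherits(x, "mr_result")) "mr_results"
  else if (inherits(x, "heterogeneity_result")) "heterogeneity"
  else if (inherits(x, "egger_result")) "egger"
  else if (inherits(x, "presso_result")) "presso"
  else "other"
}

result_record <- function(x) {
  if (inherits(x, "presso_result")) {
    return(data.frame(
      rss_obs = x$rss_obs, p_global = x$p_global,
      n_outliers = length(x$outliers),
      outliers = paste(x$outliers, collapse = ","),
      p_distortion = if (is.null(x$p_distortion)) NA_real_ else x$p_distortion,
      n_sim = x$n_sim, seed = x$seed))
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  as.data.frame(x[vapply(x, function(e)
    !is.null(e) && length(e) == 1L && is.atomic(e), logical(1))])
}

#' Write MR results and sensitivity records
#'
#' Serializes a collection of result records (MR estimates, heterogeneity,
#' Egger, MR-PRESSO) to TSV (flat table with a `section` column) or JSON
#' (typed sections). Reading the written file with [read_results()]
#' reproduces the numeric fields exactly.
#'
#' @param results A single result object or a list of them.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.list(results) || !is.null(attr(results, "class"))) results <- list(results)
  if (length(results) == 0L) stop("results must be non-empty", call. = FALSE)
  sections <- split(results, vapply(results, result_section, character(1)))
  rbind_fill <- function(dfs) {
    all_cols <- unique(unlist(lapply(dfs, names)))
    dfs <- lapply(dfs, function(d) {
      d[setdiff(all_cols, names(d))] <- NA
      d[all_cols]
    })
    do.call(rbind, c(dfs, list(make.row.names = FALSE)))
  }
  tables <- lapply(sections, function(recs) rbind_fill(lapply(recs, result_record)))
  if (format == "json") {
    jsonlite::write_json(tables, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "columns", na = "null")
  } else {
    flat <- lapply(names(tables), function(nm) {
      tab <- tables[[nm]]
      cbind(section = nm, tab)
    })
    all_cols <- unique(unlist(lapply(flat, names)))
    flat <- lapply(flat, function(tab) {
      tab[setdiff(all_cols, names(tab))] <- NA
      tab[all_cols]
    })
    out <- do.call(rbind, flat)
    num <- vapply(out, is.numeric, logical(1))
    for (col in names(out)[num]) {
      out[[col]] <- sprintf("%.17g", out[[col]])
      out[[col]][out[[col]] %in% c("NA", "nan")] <- "NA"
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a results file written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; guessed from the extension when `NULL`.
#' @return Named list of data frames, one per result section.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "tsv"
  }
  if (format == "json") {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(out, as.data.frame)
  } else {
    flat <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, na.strings = "NA")
    for (col in setdiff(names(flat), c("section", "method", "rsid", "outcome",
                                       "outliers"))) {
      suppressWarnings(num <- as.numeric(flat[[col]]))
      if (!anyNA(num[!is.na(flat[[col]])])) flat[[col]] <- num
    }
    split_df <- split(flat[setdiff(names(flat), "section")], flat$section)
    lapply(split_df, function(tab) {
      tab <- tab[, colSums(!is.na(tab)) > 0 | !vapply(tab, is.logical, logical(1)),
                 drop = FALSE]
      rownames(tab) <- NULL
      tab
    })
  }
}
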