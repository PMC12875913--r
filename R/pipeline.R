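#' Analysis configuration for a full MR run
#'
#' Bundles every tunable of the pipeline. Clumping r-squared defaults are
#' mode-appropriate when not given: 0.3 for the cis (drug-target) design,
#' 0.001 for the genome-wide design.
#'
#' @param exposure List: `path`, `dialect` (and optionally `col_map`,
#'   `trait_name`, `trait_unit`).
#' @param outcomes List of lists: `name`, `path`, `dialect`, `binary`
#'   (logical), optional `col_map`.
#' @param region A [gene_region()] (kept in cis mode, excluded in
#'   genome-wide mode; optional in genome-wide mode).
#' @param mode `"cis"` or `"genome-wide"`.
#' @param p_threshold Instrument significance threshold (default `5e-8`).
#' @param clump_window_bases Clump window (default 1e7, i.e. 10 Mb).
#' @param r2_threshold Clump r-squared threshold; mode default when `NULL`.
#' @param ld List: `path`, `kind` (`"r2"` for a square r-squared TSV or
#'   `"genotypes"` for a dosage TSV), or an `ld_matrix` object directly.
#' @param palindromic_eaf_limit Harmonization ambiguity limit (default 0.42).
#' @param n_sim,seed MR-PRESSO simulation count and seed.
#' @param alpha Significance level (default 0.05; no across-outcome
#'   multiple-testing adjustment is applied).
#' @param output_dir Optional directory for per-stage TSV/JSON outputs.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcomes, region = NULL,
                            mode = c("cis", "genome-wide"),
                            p_threshold = 5e-8, clump_window_bases = 1e7,
                            r2_threshold = NULL, ld = NULL,
                            palindromic_eaf_limit = 0.42,
                            n_sim = 1000L, seed = 1L, alpha = 0.05,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(r2_threshold)) r2_threshold <- if (mode == "cis") 0.3 else 0.001
  structure(list(exposure = exposure, outcomes = outcomes, region = region,
                 mode = mode, p_threshold = p_threshold,
                 clump_window_bases = clump_window_bases,
                 r2_threshold = r2_threshold, ld = ld,
                 palindromic_eaf_limit = palindromic_eaf_limit,
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 alpha = alpha, output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; `region` is a mapping
#' with `chrom`/`start`/`end`/`flank`. An example configuration with the
#' GCK drug-target defaults ships in
#' `system.file("extdata", "config-gck-example.yaml", package = "targetmr")`.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  region <- NULL
  if (!is.null(y$region)) {
    region <- gene_region(y$region$chrom, y$region$start, y$region$end,
                          y$region$flank %||% 0)
  }
  args <- list(exposure = y$exposure, outcomes = y$outcomes, region = region,
               mode = y$mode %||% "cis", ld = y$ld)
  for (key in c("p_threshold", "clump_window_bases", "r2_threshold",
                "palindromic_eaf_limit", "n_sim", "seed", "alpha",
                "output_dir")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(analysis_config, args)
}

load_ld_source <- function(ld) {
  if (inherits(ld, "ld_matrix")) return(ld)
  if (is.null(ld)) stop("an LD source is required for clumping", call. = FALSE)
  kind <- ld$kind %||% "r2"
  if (kind == "r2") return(read_ld_matrix(ld$path))
  if (kind == "genotypes") {
    geno <- utils::read.table(ld$path, header = TRUE, sep = "\t",
                              row.names = 1L, check.names = FALSE)
    return(compute_ld_from_genotypes(as.matrix(geno)))
  }
  stop("unknown LD source kind: ", kind, call. = FALSE)
}

load_table <- function(spec_entry, what) {
  if (inherits(spec_entry, "sumstats")) return(spec_entry)
  if (!is.null(spec_entry$table)) return(spec_entry$table)
  read_sumstats(spec_entry$path, dialect = spec_entry$dialect %||% "generic",
                col_map = spec_entry$col_map,
                trait_name = spec_entry$trait_name %||% spec_entry$name %||% what,
                trait_unit = spec_entry$trait_unit %||% NA_character_)
}

#' Run the full MR analysis for one design
#'
#' Executes the pipeline: region filter, p-value filter, LD clumping,
#' orientation of the exposure to the trait-lowering allele, then per
#' outcome: harmonization, random-effects IVW, MR-Egger, Cochran's Q,
#' MR-PRESSO, and odds-ratio transformation for binary outcomes. The report
#' carries the instrument list with per-variant and mean F statistics, all
#' estimates and diagnostics, the dropped-variant ledger per outcome,
#' per-stage counts, a config echo, and the seed, so a run is reproducible
#' from its own report.
#'
#' @param cfg An [analysis_config()]. `exposure`, each outcome, and `ld`
#'   may be in-memory objects (`sumstats` / `ld_matrix`) instead of paths.
#' @return An `mr_report` list.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  exposure <- stage("read-exposure", load_table(cfg$exposure, "exposure"))
  ld <- stage("load-ld", load_ld_source(cfg$ld))
  inst <- stage("select-instruments",
                select_instruments(exposure, cfg$region, mode = cfg$mode,
                                   p_threshold = cfg$p_threshold, ld = ld,
                                   r2_threshold = cfg$r2_threshold,
                                   window_bases = cfg$clump_window_bases))
  oriented <- stage("orient", orient_to_lowering(inst$instruments))

  outcomes <- list()
  for (oc in cfg$outcomes) {
    name <- oc$name %||% "outcome"
    binary <- isTRUE(oc$binary)
    otype <- if (binary) "binary" else "continuous"
    outcome_tab <- stage(paste0("read-outcome-", name), load_table(oc, name))
    pairs <- stage(paste0("harmonize-", name),
                   harmonize(oriented, outcome_tab,
                             palindromic_eaf_limit = cfg$palindromic_eaf_limit,
                             outcome_type = otype))
    est <- stage(paste0("ivw-", name), ivw(pairs, effects = "random"))
    if (binary) est <- to_or_scale(est)
    egg <- if (nrow(pairs) >= 3L) stage(paste0("egger-", name), egger(pairs)) else NULL
    q <- if (nrow(pairs) >= 2L) stage(paste0("cochran-q-", name), cochran_q(pairs)) else NULL
    presso <- if (nrow(pairs) >= 4L) {
      stage(paste0("presso-", name),
            mr_presso(pairs, n_sim = cfg$n_sim, seed = cfg$seed,
                      alpha = cfg$alpha))
    } else NULL
    egger_row <- if (!is.null(egg)) {
      row <- egger_slope_result(egg, outcome_type = otype)
      if (binary) to_or_scale(row) else row
    } else NULL
    outcomes[[name]] <- list(
      name = name, binary = binary, n_snps = nrow(pairs),
      ivw = est, egger = egg, egger_slope = egger_row,
      heterogeneity = q, presso = presso,
      pleiotropy = if (!is.null(egg)) egger_intercept_test(egg, cfg$alpha) else NULL,
      pairs = pairs, dropped = attr(pairs, "dropped"))
  }

  report <- structure(list(
    mode = cfg$mode,
    instruments = inst,
    oriented_exposure = oriented,
    outcomes = outcomes,
    config = cfg, seed = cfg$seed,
    counts = inst$counts), class = "mr_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(cfg$output_dir,
                                   paste0("report-", cfg$mode, ".json")))
    for (name in names(outcomes)) {
      recs <- c(list(outcomes[[name]]$ivw),
                if (!is.null(outcomes[[name]]$egger_slope))
                  list(outcomes[[name]]$egger_slope),
                if (!is.null(outcomes[[name]]$heterogeneity))
                  list(outcomes[[name]]$heterogeneity),
                if (!is.null(outcomes[[name]]$presso))
                  list(outcomes[[name]]$presso))
      write_results(recs, file.path(cfg$output_dir,
                                    paste0("results-", cfg$mode, "-", name, ".tsv")),
                    format = "tsv")
    }
  }
  report
}

report_outcome_row <- function(oc) {
  est <- oc$ivw
  data.frame(
    outcome = oc$name, binary = oc$binary, n_snps = oc$n_snps,
    beta = est$beta, se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
    pvalue = est$pvalue,
    or = if (!is.null(est$or)) est$or else NA_real_,
    or_ci_low = if (!is.null(est$or_ci_low)) est$or_ci_low else NA_real_,
    or_ci_high = if (!is.null(est$or_ci_high)) est$or_ci_high else NA_real_,
    q_pvalue = if (!is.null(oc$heterogeneity)) oc$heterogeneity$pvalue else NA_real_,
    egger_intercept_p = if (!is.null(oc$egger)) oc$egger$p_intercept else NA_real_,
    presso_global_p = if (!is.null(oc$presso)) oc$presso$p_global else NA_real_,
    n_presso_outliers = if (!is.null(oc$presso)) length(oc$presso$outliers) else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Summarize an MR report as one row per outcome
#'
#' @param report An `mr_report`.
#' @return Data frame with the IVW estimate, OR scale where applicable, and
#'   the sensitivity p-values per outcome.
#' @export
summarize_report <- function(report) {
  out <- do.call(rbind, c(lapply(report$outcomes, report_outcome_row),
                          list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report (%s design): %d instruments, mean F = %.1f\n",
              x$mode, nrow(x$instruments$instruments), x$instruments$mean_F))
  print(summarize_report(x))
  invisible(x)
}

#' Write an MR report as JSON
#'
#' Serializes the summary table, instrument list, per-outcome diagnostics,
#' per-stage counts, and a config echo. Numeric fields keep full precision,
#' so identical runs give byte-identical files.
#'
#' @param report An `mr_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  cfg <- report$config
  echo <- list(mode = cfg$mode, p_threshold = cfg$p_threshold,
               clump_window_bases = cfg$clump_window_bases,
               r2_threshold = cfg$r2_threshold,
               palindromic_eaf_limit = cfg$palindromic_eaf_limit,
               n_sim = cfg$n_sim, seed = cfg$seed, alpha = cfg$alpha,
               region = if (!is.null(cfg$region)) unclass(cfg$region))
  body <- list(
    mode = report$mode,
    counts = as.list(report$counts),
    mean_F = report$instruments$mean_F,
    instruments = data.frame(rsid = report$instruments$instruments$rsid,
                             F = report$instruments$per_variant_F),
    summary = summarize_report(report),
    dropped = lapply(report$outcomes, function(oc) oc$dropped),
    config = echo, seed = report$seed)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", null = "null")
  invisible(path)
}

#' Compare the cis (drug-target) and genome-wide designs
#'
#' Places the two designs' estimates side by side per outcome and flags
#' outcomes where the cis design is significant at `alpha` while the
#' genome-wide design is not — the pattern read as an effect of target
#' modulation not solely attributable to lowering the exposure (a flag,
#' not a causal claim).
#'
#' @param report_cis,report_gw `mr_report` objects over the same outcomes.
#' @param alpha Significance level (default from the cis report's config).
#' @return Data frame with one row per outcome and a `cis_specific` flag.
#' @export
compare_designs <- function(report_cis, report_gw, alpha = NULL) {
  if (is.null(alpha)) alpha <- report_cis$config$alpha %||% 0.05
  miss <- c(setdiff(names(report_cis$outcomes), names(report_gw$outcomes)),
            setdiff(names(report_gw$outcomes), names(report_cis$outcomes)))
  if (length(miss)) {
    stop("outcome sets differ between designs: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  s_cis <- summarize_report(report_cis)
  s_gw <- summarize_report(report_gw)
  s_gw <- s_gw[match(s_cis$outcome, s_gw$outcome), , drop = FALSE]
  data.frame(
    outcome = s_cis$outcome, binary = s_cis$binary,
    cis_beta = s_cis$beta, cis_ci_low = s_cis$ci_low,
    cis_ci_high = s_cis$ci_high, cis_pvalue = s_cis$pvalue,
    cis_or = s_cis$or,
    gw_beta = s_gw$beta, gw_ci_low = s_gw$ci_low,
    gw_ci_high = s_gw$ci_high, gw_pvalue = s_gw$pvalue,
    gw_or = s_gw$or,
    cis_specific = s_cis$pvalue < alpha & s_gw$pvalue >= alpha,
    stringsAsFactors = FALSE)
}
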