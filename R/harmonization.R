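ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

#' Orient an exposure table to the trait-lowering allele
#'
#' Re-codes every record so the effect allele is the one that lowers the
#' exposure (for an HbA1c exposure, the HbA1c-decreasing allele, mimicking
#' pharmacological activation of the target): records with `beta > 0` have
#' their alleles swapped, `beta` negated, and `eaf` replaced by `1 - eaf`.
#' Records with `beta < 0` are unchanged; `beta == 0` is left as is with a
#' warning. Idempotent.
#'
#' @param exposure A `sumstats` object.
#' @return The re-oriented `sumstats` object.
#' @export
orient_to_lowering <- function(exposure) {
  flip <- exposure$beta > 0
  if (any(exposure$beta == 0)) {
    warning("record(s) with beta == 0 cannot be oriented to a lowering allele",
            call. = FALSE)
  }
  ea <- exposure$effect_allele
  exposure$effect_allele[flip] <- exposure$other_allele[flip]
  exposure$other_allele[flip] <- ea[flip]
  exposure$beta[flip] <- -exposure$beta[flip]
  exposure$eaf[flip] <- 1 - exposure$eaf[flip]
  exposure
}

#' Construct a harmonized exposure/outcome instrument set
#'
#' @param pairs Data frame with columns `rsid`, `gamma`, `se_gamma`,
#'   `Gamma`, `se_Gamma`, and optionally `palindromic`, `flipped`,
#'   `eaf_exposure`, `eaf_outcome`.
#' @param exposure_unit Working exposure unit label.
#' @param outcome_type `"continuous"` or `"binary"` (outcome effects on the
#'   log-odds scale).
#' @param dropped Data frame of `(rsid, reason)` for excluded variants.
#' @return A `harmonized_set` (data frame with metadata attributes).
#' @export
harmonized_set <- function(pairs, exposure_unit = "1% lower HbA1c",
                           outcome_type = c("continuous", "binary"),
                           dropped = data.frame(rsid = character(0),
                                                reason = character(0))) {
  outcome_type <- match.arg(outcome_type)
  for (col in c("palindromic", "flipped")) {
    if (is.null(pairs[[col]])) pairs[[col]] <- FALSE
  }
  for (col in c("eaf_exposure", "eaf_outcome")) {
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  }
  stopifnot(all(c("rsid", "gamma", "se_gamma", "Gamma", "se_Gamma") %in% names(pairs)),
            !anyDuplicated(pairs$rsid),
            all(pairs$se_gamma > 0), all(pairs$se_Gamma > 0),
            !any(pairs$rsid %in% dropped$rsid))
  pairs <- pairs[c("rsid", "gamma", "se_gamma", "Gamma", "se_Gamma",
                   "palindromic", "flipped", "eaf_exposure", "eaf_outcome")]
  rownames(pairs) <- NULL
  structure(pairs, exposure_unit = exposure_unit, outcome_type = outcome_type,
            dropped = dropped, class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized set: %d instruments (%s outcome, exposure unit: %s), %d dropped\n",
              nrow(x), attr(x, "outcome_type"), attr(x, "exposure_unit"),
              nrow(attr(x, "dropped"))))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Align outcome associations to the exposure's allele coding
#'
#' For each rsid shared between the oriented exposure and the outcome table,
#' aligns the outcome effect to the exposure's effect allele: identical
#' allele pairs are copied; swapped pairs have the outcome beta negated and
#' eaf complemented; reverse-strand (complement) codings are resolved by
#' complementing first. Palindromic variants (A/T or C/G), whose strand
#' cannot be read off the alleles, are aligned by allele frequency when both
#' eafs are available, unambiguous (outside
#' `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`) and concordant, and
#' dropped otherwise. Variants absent from the outcome, or with
#' irreconcilable allele sets, are dropped with a reason.
#'
#' The returned effects are expressed per unit *decrease* of the exposure:
#' after orientation the exposure beta is negative in raw trait units, and
#' the working `gamma` is its magnitude, so for an HbA1c exposure the Wald
#' ratio `Gamma / gamma` is the outcome effect per 1% lower HbA1c and a
#' protective association on a binary outcome appears as `Gamma < 0`
#' (odds ratio below 1).
#'
#' @param exposure Oriented exposure `sumstats` (see [orient_to_lowering()];
#'   any `beta > 0` is a contract error).
#' @param outcome Outcome `sumstats`.
#' @param palindromic_eaf_limit Frequency ambiguity limit in (0, 0.5);
#'   default 0.42.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return A [harmonized_set()].
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42,
                      outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(palindromic_eaf_limit > 0, palindromic_eaf_limit < 0.5)
  if (any(exposure$beta > 0)) {
    stop("exposure is not oriented to the lowering allele; run orient_to_lowering()",
         call. = FALSE)
  }
  exposure <- as.data.frame(exposure)
  outcome <- as.data.frame(outcome)

  shared <- sort(intersect(exposure$rsid, outcome$rsid))
  exp <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  out <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  n <- length(shared)
  gamma <- -exp$beta                      # per 1 unit *lower* exposure
  se_gamma <- exp$se
  Gamma <- rep(NA_real_, n)
  se_Gamma <- out$se
  eaf_out <- rep(NA_real_, n)
  flipped <- rep(FALSE, n)
  palin <- is_palindromic(exp$effect_allele, exp$other_allele)
  reason <- rep(NA_character_, n)

  same <- out$effect_allele == exp$effect_allele & out$other_allele == exp$other_allele
  swap <- out$effect_allele == exp$other_allele & out$other_allele == exp$effect_allele
  comp_ea <- unname(ALLELE_COMPLEMENT[out$effect_allele])
  comp_oa <- unname(ALLELE_COMPLEMENT[out$other_allele])
  comp_same <- comp_ea == exp$effect_allele & comp_oa == exp$other_allele
  comp_swap <- comp_ea == exp$other_allele & comp_oa == exp$effect_allele

  for (j in seq_len(n)) {
    if (palin[j]) {
      # strand unreadable from alleles: for a palindromic variant "same" and
      # "comp_swap" (and "swap"/"comp_same") are indistinguishable, so the
      # orientation must come from allele frequencies
      if (!(same[j] || swap[j])) {
        reason[j] <- "allele-mismatch"
        next
      }
      fe <- exp$eaf[j]
      fo <- out$eaf[j]
      lim <- c(palindromic_eaf_limit, 1 - palindromic_eaf_limit)
      if (is.na(fe) || is.na(fo) ||
          (fe >= lim[1] && fe <= lim[2]) || (fo >= lim[1] && fo <= lim[2])) {
        reason[j] <- "palindromic-ambiguous"
        next
      }
      concordant <- (fe < 0.5) == (fo < 0.5)
      if (concordant) {
        Gamma[j] <- out$beta[j]
        eaf_out[j] <- out$eaf[j]
      } else {
        Gamma[j] <- -out$beta[j]
        eaf_out[j] <- 1 - out$eaf[j]
        flipped[j] <- TRUE
      }
    } else if (same[j] || comp_same[j]) {
      Gamma[j] <- out$beta[j]
      eaf_out[j] <- out$eaf[j]
    } else if (swap[j] || comp_swap[j]) {
      Gamma[j] <- -out$beta[j]
      eaf_out[j] <- 1 - out$eaf[j]
      flipped[j] <- TRUE
    } else {
      reason[j] <- "allele-mismatch"
    }
  }

  ok <- is.na(reason)
  dropped <- data.frame(rsid = shared[!ok], reason = reason[!ok],
                        stringsAsFactors = FALSE)
  absent <- sort(setdiff(exposure$rsid, outcome$rsid))
  if (length(absent)) {
    dropped <- rbind(dropped,
                     data.frame(rsid = absent, reason = "absent-from-outcome",
                                stringsAsFactors = FALSE))
  }
  pairs <- data.frame(rsid = shared[ok], gamma = gamma[ok],
                      se_gamma = se_gamma[ok], Gamma = Gamma[ok],
                      se_Gamma = se_Gamma[ok], palindromic = palin[ok],
                      flipped = flipped[ok],
                      eaf_exposure = exp$eaf[ok], eaf_outcome = eaf_out[ok],
                      stringsAsFactors = FALSE)
  harmonized_set(pairs, outcome_type = outcome_type, dropped = dropped)
}

#' Export a harmonized set as TSV
#'
#' The bit-exact interchange surface between pipeline stages: rsid, working
#' exposure and outcome effects, their SEs, and the palindromic/flipped
#' flags.
#'
#' @param pairs A `harmonized_set`.
#' @param path Output path.
#' @export
write_harmonized <- function(pairs, path) {
  out <- as.data.frame(pairs)
  for (col in c("gamma", "se_gamma", "Gamma", "se_Gamma",
                "eaf_exposure", "eaf_outcome")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
    out[[col]][out[[col]] == "NA"] <- "NA"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
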