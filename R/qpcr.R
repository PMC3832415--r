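#' @title Delta-delta-Ct relative quantification
#' @name qpcr-module
#' @description
#' Classic ddCt arithmetic for qPCR validation assays, assuming
#' amplification efficiency 2 (one cycle = one doubling): reference-gene
#' normalised fold changes for knockdown verification, and direct
#' cycle-difference folds for IP-enrichment qPCR, where no stable
#' reference small RNA exists in immunoprecipitated material and equal
#' input volumes take its place. Replicate Ct values are averaged
#' (arithmetic mean of cycles) before any differencing; the replicate
#' standard deviation is carried along for reporting.
NULL

#' Delta-Ct: target minus reference
#'
#' Replicate Cts of either argument are averaged before differencing.
#'
#' @param ct_target Numeric, Ct value(s) of the target assay in one
#'   sample.
#' @param ct_reference Numeric, Ct value(s) of the reference assay in the
#'   same sample.
#' @return Scalar delta-Ct (cycles).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  mean(ct_target) - mean(ct_reference)
}

#' Delta-delta-Ct fold change between two samples
#'
#' `ddct = delta_treated - delta_control`, `fold = 2^(-ddct)`,
#' `percent_knockdown = 100 * (1 - fold)`. A fold of 0.2 corresponds to
#' 80% knockdown.
#'
#' @param delta_treated Delta-Ct of the treated sample.
#' @param delta_control Delta-Ct of the control sample.
#' @param target,treated,control Optional labels carried into the result.
#' @return Object of class `"ddct_result"`: list with `ddct`, `fold`,
#'   `percent_knockdown`, `delta_ct_treated`, `delta_ct_control`, labels.
#' @export
ddct_fold <- function(delta_treated, delta_control, target = NA_character_,
                      treated = NA_character_, control = NA_character_) {
  stopifnot(is.finite(delta_treated), is.finite(delta_control))
  ddct <- delta_treated - delta_control
  fold <- 2^(-ddct)
  structure(
    list(target = target, treated = treated, control = control,
         delta_ct_treated = delta_treated, delta_ct_control = delta_control,
         ddct = ddct, fold = fold,
         percent_knockdown = 100 * (1 - fold)),
    class = "ddct_result"
  )
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf(
    "ddCt %s%.3f -> fold %.4g (%.1f%% knockdown)\n",
    if (is.na(x$target)) "" else paste0("[", x$target, "] "),
    x$ddct, x$fold, x$percent_knockdown))
  invisible(x)
}

#' IP-enrichment fold from raw Ct difference
#'
#' For qPCR on immunoprecipitated RNA no reference assay is used (equal
#' volumes of RNA enter each reaction); the fold is the plain cycle
#' difference, `2^(ct_comparator - ct_ip)`. The comparator is explicit --
#' input or a control IP -- rather than assumed.
#'
#' @param ct_ip Ct value(s) in the IP sample (replicates averaged).
#' @param ct_comparator Ct value(s) in the comparator sample.
#' @return Scalar linear fold (> 1 means enriched in the IP).
#' @export
ip_qpcr_fold <- function(ct_ip, ct_comparator) {
  stopifnot(all(is.finite(ct_ip)), all(is.finite(ct_comparator)))
  2^(mean(ct_comparator) - mean(ct_ip))
}

#' Read a Ct table from TSV
#'
#' Expects header `sample_id assay_target replicate ct`.
#'
#' @param path Path to a tab-delimited Ct table.
#' @return A `data.frame` of class `"ct_table"`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_target", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  validate_ct_table(df)
}

#' Validate a Ct table
#'
#' @param df Data frame with columns `sample_id`, `assay_target`,
#'   `replicate`, `ct`.
#' @return The validated `"ct_table"`, invisibly usable downstream.
#' @export
validate_ct_table <- function(df) {
  if (any(!is.finite(df$ct))) stop("non-finite Ct value")
  if (any(df$ct <= 0 | df$ct >= 45)) {
    warning("Ct value(s) outside the usual 0-45 cycle range",
            call. = FALSE)
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Knockdown fold from a Ct table
#'
#' Convenience wrapper: averages replicate Cts per (sample, assay), forms
#' delta-Ct of `target` against `reference` within the treated and
#' control samples, and returns the ddCt fold. Replicate standard
#' deviations are attached for reporting.
#'
#' @param ct A `"ct_table"`.
#' @param target Assay target to quantify.
#' @param reference Reference assay (e.g. `"LMNA"`).
#' @param treated,control Sample ids of the treated and control samples.
#' @return A `"ddct_result"` with replicate s.d. in `attr(, "ct_sd")`.
#' @export
ddct_table <- function(ct, target, reference, treated, control) {
  stopifnot(inherits(ct, "ct_table"))
  grab <- function(sample, assay) {
    v <- ct$ct[ct$sample_id == sample & ct$assay_target == assay]
    if (length(v) == 0L) {
      stop("no Ct rows for sample '", sample, "', assay '", assay, "'")
    }
    v
  }
  tt <- grab(treated, target);   tr <- grab(treated, reference)
  ct_ <- grab(control, target);  cr <- grab(control, reference)
  res <- ddct_fold(delta_ct(tt, tr), delta_ct(ct_, cr),
                   target = target, treated = treated, control = control)
  attr(res, "ct_sd") <- c(treated_target = stats::sd(tt),
                          treated_reference = stats::sd(tr),
                          control_target = stats::sd(ct_),
                          control_reference = stats::sd(cr))
  res
}
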