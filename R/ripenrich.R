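#' @title IP:input enrichment screening
#' @name ripenrich-module
#' @description
#' The screening procedure at the heart of a RIP-chip catalogue: probesets
#' are called detected when they exceed the spike-in control level in both
#' the IP and input arrays, their IP:input enrichment is the linear fold
#' between the replicate-median IP abundance and the single input
#' abundance, and the bound set is the top quantile of that fold. Two cell
#' lines' selections are then partitioned into bound-in-both /
#' bound-in-A-only / bound-in-B-only strata. No significance model is
#' attached: with one input array per cell line a screening statistic is
#' the appropriate tool.
NULL

#' Spike-in detection thresholds for one cell line
#'
#' The spike-in control probesets hybridise at approximately the limit of
#' sensitivity, so their median level separates "reliably detectable" from
#' noise. The IP threshold is the median over all (spike-in probeset, IP
#' array) values of the cell line; the input threshold is the median of
#' the spike-in values on its single input array.
#'
#' @param expr Probesets x samples log2 expression matrix (from [rma()]).
#' @param annotation A `probe_annotation` with >= 3 spike-in probesets.
#' @param sheet A `sample_sheet`.
#' @param cell_line Cell line name.
#' @return Object of class `"detection_threshold"`: list with
#'   `cell_line`, `ip_threshold`, `input_threshold` (log2 units).
#' @export
detection_threshold <- function(expr, annotation, sheet, cell_line) {
  spikes <- intersect(spikein_probesets(annotation), rownames(expr))
  if (length(spikes) < 3L) {
    stop("detection threshold needs >= 3 spike-in probesets in the ",
         "expression matrix, found ", length(spikes))
  }
  des <- rip_design(sheet, cell_line)
  missing <- setdiff(c(des$ip, des$input), colnames(expr))
  if (length(missing)) {
    stop("sample(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(cell_line = cell_line,
         ip_threshold = stats::median(as.vector(expr[spikes, des$ip])),
         input_threshold = stats::median(expr[spikes, des$input])),
    class = "detection_threshold"
  )
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf("%s detection thresholds (log2): IP %.3f, input %.3f\n",
              x$cell_line, x$ip_threshold, x$input_threshold))
  invisible(x)
}

#' Per-probeset IP:input enrichment records for one cell line
#'
#' For every non-spike-in probeset: the median log2 abundance across the
#' cell line's IP replicate arrays, the log2 abundance on its input array,
#' the linear enrichment fold `2^(ip_median_log2 - input_log2)`, and the
#' detection call. Detection requires the probeset to exceed the spike-in
#' threshold in the IP arrays and (by default) also in the input array:
#' a fold is only interpretable when both of its terms are above the limit
#' of sensitivity. `detect_in = "ip"` relaxes this to the IP side only.
#' The `selected` flag is initialised FALSE; see [select_bound()].
#'
#' @param expr Probesets x samples log2 expression matrix.
#' @param annotation A `probe_annotation`.
#' @param sheet A `sample_sheet`.
#' @param cell_line Cell line name.
#' @param threshold A `"detection_threshold"`; computed from `expr` if
#'   omitted.
#' @param detect_in `"both"` (default) or `"ip"`.
#' @return A `data.frame` of class `"enrichment_records"` with columns
#'   `probeset_id`, `cell_line`, `ip_median_log2`, `input_log2`, `fold`,
#'   `detected`, `selected`.
#' @export
enrichment <- function(expr, annotation, sheet, cell_line,
                       threshold = NULL,
                       detect_in = c("both", "ip")) {
  detect_in <- match.arg(detect_in)
  if (is.null(threshold)) {
    threshold <- detection_threshold(expr, annotation, sheet, cell_line)
  }
  stopifnot(inherits(threshold, "detection_threshold"))
  des <- rip_design(sheet, cell_line)
  keep <- setdiff(rownames(expr), spikein_probesets(annotation))
  ip <- expr[keep, des$ip, drop = FALSE]
  ip_median <- apply(ip, 1, stats::median)
  input <- expr[keep, des$input]
  detected <- ip_median > threshold$ip_threshold
  if (detect_in == "both") {
    detected <- detected & input > threshold$input_threshold
  }
  rec <- data.frame(
    probeset_id = keep,
    cell_line = cell_line,
    ip_median_log2 = unname(ip_median),
    input_log2 = unname(input),
    fold = 2^(unname(ip_median) - unname(input)),
    detected = unname(detected),
    selected = FALSE,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("enrichment_records", "data.frame")
  attr(rec, "threshold") <- threshold
  attr(rec, "detect_in") <- detect_in
  rec
}

#' Select the most-enriched probesets
#'
#' Marks as bound the detected probesets whose enrichment fold is strictly
#' greater than the empirical `quantile_q` quantile (linear interpolation
#' between order statistics) of the folds of all records with finite fold
#' -- the quantile is taken over everything measured, not only the
#' detected subset, so the cutoff describes the population of assayed
#' sncRNAs. With the default q = 0.995 the selection is the top 0.5% of
#' measured probesets; ties at the threshold are excluded (strict
#' inequality).
#'
#' @param records An `"enrichment_records"` data frame.
#' @param quantile_q Quantile in \[0, 1); default 0.995. At q = 0 the
#'   threshold is the minimum fold, so every detected record except the
#'   minimum is selected.
#' @return `records` with `selected` set; the fold threshold in
#'   `attr(, "fold_threshold")`.
#' @export
select_bound <- function(records, quantile_q = 0.995) {
  stopifnot(inherits(records, "enrichment_records"))
  if (nrow(records) == 0L) stop("empty record list")
  if (!(quantile_q >= 0 && quantile_q < 1)) {
    stop("quantile_q must be in [0, 1)")
  }
  folds <- records$fold[is.finite(records$fold)]
  if (length(folds) == 0L) stop("no finite folds")
  t <- stats::quantile(folds, quantile_q, names = FALSE, type = 7)
  records$selected <- records$detected & is.finite(records$fold) &
    records$fold > t
  attr(records, "fold_threshold") <- t
  attr(records, "quantile_q") <- quantile_q
  records
}

#' Classify the overlap of two cell lines' bound sets
#'
#' Partitions every probeset selected in either cell line into
#' `both` (A intersect B), `A_only`, and `B_only` strata, and carries both
#' cell lines' folds for every classified probeset -- the non-selected
#' cell line's fold is informative (a probeset bound in one line may sit
#' just under threshold in the other).
#'
#' @param records_a,records_b `"enrichment_records"` for the two cell
#'   lines, after [select_bound()], over the same annotation universe.
#' @return A `data.frame` of class `"overlap_table"` with columns
#'   `probeset_id`, `stratum` (both / A_only / B_only), `fold_a`,
#'   `fold_b`, `cell_line_a`, `cell_line_b`.
#' @export
classify_overlap <- function(records_a, records_b) {
  stopifnot(inherits(records_a, "enrichment_records"),
            inherits(records_b, "enrichment_records"))
  sel_a <- records_a$probeset_id[records_a$selected]
  sel_b <- records_b$probeset_id[records_b$selected]
  ids <- c(intersect(sel_a, sel_b),
           setdiff(sel_a, sel_b),
           setdiff(sel_b, sel_a))
  stratum <- c(rep("both", length(intersect(sel_a, sel_b))),
               rep("A_only", length(setdiff(sel_a, sel_b))),
               rep("B_only", length(setdiff(sel_b, sel_a))))
  tab <- data.frame(
    probeset_id = ids,
    stratum = stratum,
    fold_a = records_a$fold[match(ids, records_a$probeset_id)],
    fold_b = records_b$fold[match(ids, records_b$probeset_id)],
    cell_line_a = rep(records_a$cell_line[1], length(ids)),
    cell_line_b = rep(records_b$cell_line[1], length(ids)),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("overlap_table", "data.frame")
  tab
}

#' Format an overlap table as an annotated report
#'
#' Orders rows within each stratum by descending fold in the stratum's
#' defining cell line (cell line A for `both` and `A_only`, B for
#' `B_only`; ties keep input order) and joins the sncRNA class and any
#' reannotation note. Probesets absent from the annotation are reported
#' with class `"unknown"` and a warning rather than dropped.
#'
#' @param table An `"overlap_table"`.
#' @param annotation A `probe_annotation`.
#' @return A `data.frame` with columns `stratum`, `probeset_id`,
#'   `fold_a`, `fold_b`, `selected_a`, `selected_b`, `rna_class`,
#'   `reannotation`.
#' @export
enrichment_report <- function(table, annotation) {
  stopifnot(inherits(table, "overlap_table"))
  cols <- c("stratum", "probeset_id", "fold_a", "fold_b", "rna_class",
            "reannotation")
  if (nrow(table) == 0L) {
    out <- data.frame(stratum = character(), probeset_id = character(),
                      fold_a = numeric(), fold_b = numeric(),
                      selected_a = logical(), selected_b = logical(),
                      rna_class = character(), reannotation = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  ps <- annotation[!duplicated(annotation$probeset_id),
                   c("probeset_id", "rna_class", "reannotation")]
  i <- match(table$probeset_id, ps$probeset_id)
  rna_class <- ps$rna_class[i]
  if (anyNA(i)) {
    warning("probeset(s) missing from annotation, reported as 'unknown': ",
            paste(table$probeset_id[is.na(i)], collapse = ", "),
            call. = FALSE)
    rna_class[is.na(i)] <- "unknown"
  }
  key_fold <- ifelse(table$stratum == "B_only", table$fold_b, table$fold_a)
  stratum_f <- factor(table$stratum, levels = c("both", "A_only", "B_only"))
  ord <- order(stratum_f, -key_fold)  # base order(): stable on ties
  out <- data.frame(
    stratum = table$stratum,
    probeset_id = table$probeset_id,
    fold_a = table$fold_a,
    fold_b = table$fold_b,
    selected_a = table$stratum %in% c("both", "A_only"),
    selected_b = table$stratum %in% c("both", "B_only"),
    rna_class = rna_class,
    reannotation = ps$reannotation[i],
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cell_line_a") <- table$cell_line_a[1]
  attr(out, "cell_line_b") <- table$cell_line_b[1]
  out
}
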