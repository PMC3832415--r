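#' @title Domain containers and TSV readers for RIP-chip array data
#' @name arraydata
#' @description
#' Plain-text (UTF-8, tab-delimited, "." decimal, unquoted) readers and
#' writers for the three inputs every analysis stage consumes: a probe
#' annotation table, a sample sheet, and a probe-level intensity matrix;
#' plus the normalised expression matrix written downstream. Missing values
#' are never permitted in intensity files: an array reports a fluorescence
#' value for every cell, so absence is treated as a file defect, not NA.
NULL

#' Recognised small-RNA classes for probeset annotation
#'
#' The classes cover the content of a miRNA-era small-RNA array: mature
#' miRNAs, precursor hairpins, C/D- and H/ACA-box snoRNAs, scaRNAs, a
#' catch-all for other sncRNAs (tRNA fragments, vault/Y RNAs, rRNA
#' cross-mapping probes, ...), and bacterial spike-in hybridisation
#' controls whose median level defines the detection threshold.
#'
#' @format Character vector of valid `rna_class` tokens.
#' @export
RNA_CLASSES <- c(
  "mature_miRNA", "precursor_hairpin", "snoRNA_CD", "snoRNA_HACA",
  "scaRNA", "other_sncRNA", "spikein_control"
)

#' Recognised sample fractions and treatments
#'
#' `IgG` is accepted in sample sheets for completeness (control IPs are
#' part of the wet-lab design) but no analysis stage consumes IgG arrays:
#' IgG-bound RNA is typically too scarce to quantify.
#'
#' @format Character vectors of valid tokens.
#' @export
FRACTIONS <- c("input", "IP", "IgG")

#' @rdname FRACTIONS
#' @export
TREATMENTS <- c("untransfected", "siCtrl", "siYB1")

#' Construct a probe annotation table
#'
#' Maps each probe to its probeset and each probeset to a small-RNA class.
#' Probes map to exactly one probeset (one row per probe); median-polish
#' summarisation assumes this partition.
#'
#' @param probe_id Character, unique probe identifiers.
#' @param probeset_id Character, probeset each probe belongs to.
#' @param rna_class Character, one of [RNA_CLASSES] per probe; must be
#'   constant within a probeset.
#' @param family Optional character, sncRNA family (e.g. "let-7").
#' @param reannotation Optional character, free-text reannotation note
#'   (e.g. "tRNA-Gly, removed from miRBase").
#' @return A `data.frame` of class `"probe_annotation"`.
#' @export
probe_annotation <- function(probe_id, probeset_id, rna_class,
                             family = NA_character_,
                             reannotation = NA_character_) {
  ann <- data.frame(
    probe_id = as.character(probe_id),
    probeset_id = as.character(probeset_id),
    rna_class = as.character(rna_class),
    family = as.character(family),
    reannotation = as.character(reannotation),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  validate_probe_annotation(ann)
  ann
}

#' Validate a probe annotation table
#'
#' Checks probe uniqueness, known class tokens, class consistency within
#' probesets, and counts spike-in probesets. Fewer than 3 spike-in
#' probesets is only a warning here: it becomes an error if and when a
#' detection threshold is requested.
#'
#' @param ann A `probe_annotation`.
#' @return `ann`, invisibly.
#' @export
validate_probe_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (nrow(ann) == 0L) stop("empty probe annotation")
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup)) {
    stop("duplicate probe_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(ann$rna_class), RNA_CLASSES)
  if (length(bad)) {
    stop("unknown rna_class token(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(RNA_CLASSES, collapse = ", "), ")")
  }
  ncls <- tapply(ann$rna_class, ann$probeset_id, function(x) length(unique(x)))
  if (any(ncls > 1L)) {
    stop("probeset(s) with inconsistent rna_class: ",
         paste(names(ncls)[ncls > 1L], collapse = ", "))
  }
  if (length(spikein_probesets(ann)) < 3L) {
    warning("fewer than 3 spike-in probesets: detection thresholds ",
            "will not be computable", call. = FALSE)
  }
  invisible(ann)
}

#' Spike-in control probesets of an annotation
#'
#' @param ann A `probe_annotation`.
#' @return Character vector of probeset ids flagged `spikein_control`.
#' @export
spikein_probesets <- function(ann) {
  unique(ann$probeset_id[ann$rna_class == "spikein_control"])
}

#' Read a probe annotation table from TSV
#'
#' Expects a header line `probe_id probeset_id rna_class family
#' reannotation` (tab-separated); `family` and `reannotation` may be
#' empty.
#'
#' @param path Path to a tab-delimited annotation file.
#' @return A `probe_annotation`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "probeset_id", "rna_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$family)) df$family <- NA_character_
  if (is.null(df$reannotation)) df$reannotation <- NA_character_
  df$family[!nzchar(df$family)] <- NA_character_
  df$reannotation[!nzchar(df$reannotation)] <- NA_character_
  probe_annotation(df$probe_id, df$probeset_id, df$rna_class,
                   df$family, df$reannotation)
}

#' Write a probe annotation table to TSV
#'
#' @param ann A `probe_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  out <- as.data.frame(ann)
  out$family[is.na(out$family)] <- ""
  out$reannotation[is.na(out$reannotation)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a sample sheet
#'
#' One row per array. Samples are grouped by `(cell_line, fraction,
#' treatment)`; `replicate` is informative only.
#'
#' @param sample_id Character, unique sample identifiers.
#' @param cell_line Character.
#' @param fraction One of [FRACTIONS] per sample.
#' @param treatment One of [TREATMENTS] per sample.
#' @param replicate Positive integer replicate index.
#' @return A `data.frame` of class `"sample_sheet"`.
#' @export
sample_sheet <- function(sample_id, cell_line, fraction, treatment,
                         replicate) {
  sh <- data.frame(
    sample_id = as.character(sample_id),
    cell_line = as.character(cell_line),
    fraction = as.character(fraction),
    treatment = as.character(treatment),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  class(sh) <- c("sample_sheet", "data.frame")
  validate_sample_sheet(sh)
  sh
}

#' Validate a sample sheet
#'
#' @param sheet A `sample_sheet`.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet))
  if (nrow(sheet) == 0L) stop("no samples")
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  badf <- setdiff(unique(sheet$fraction), FRACTIONS)
  if (length(badf)) stop("unknown fraction token(s): ",
                         paste(badf, collapse = ", "))
  badt <- setdiff(unique(sheet$treatment), TREATMENTS)
  if (length(badt)) stop("unknown treatment token(s): ",
                         paste(badt, collapse = ", "))
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  invisible(sheet)
}

#' Read a sample sheet from TSV
#'
#' Expects header `sample_id cell_line fraction treatment replicate`.
#' A cell line with multiple input arrays is accepted here; the RIP
#' enrichment stage, which needs a unique input, rejects it at use.
#'
#' @param path Path to a tab-delimited sample sheet.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop("no samples in ", path, call. = FALSE)
  )
  if (nrow(df) == 0L) stop("no samples in ", path)
  need <- c("sample_id", "cell_line", "fraction", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  sample_sheet(df$sample_id, df$cell_line, df$fraction, df$treatment,
               df$replicate)
}

#' Write a sample sheet to TSV
#'
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Samples of the RIP design for one cell line
#'
#' Resolves the IP replicate arrays and the single input array of a cell
#' line. Errors if the input array is missing or duplicated, or if no IP
#' arrays exist.
#'
#' @param sheet A `sample_sheet`.
#' @param cell_line Cell line name.
#' @return List with character vectors `ip` (>= 1 sample ids) and `input`
#'   (exactly 1).
#' @export
rip_design <- function(sheet, cell_line) {
  sub <- sheet[sheet$cell_line == cell_line, , drop = FALSE]
  if (nrow(sub) == 0L) stop("cell line not in sample sheet: ", cell_line)
  ip <- sub$sample_id[sub$fraction == "IP"]
  input <- sub$sample_id[sub$fraction == "input"]
  if (length(ip) < 1L) stop("no IP arrays for cell line ", cell_line)
  if (length(input) == 0L) stop("no input array for cell line ", cell_line)
  if (length(input) > 1L) {
    stop("multiple input arrays for cell line ", cell_line,
         " (", paste(input, collapse = ", "), "); exactly one is required")
  }
  list(ip = ip, input = input)
}

#' Read a probe-level intensity matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample, in file
#' order. Every value must be numeric and strictly positive: the
#' convolution background model conditions on positive observations, so a
#' zero or negative cell is a data defect reported with its coordinates.
#'
#' @param path Path to a tab-delimited intensity file.
#' @param annotation Optional `probe_annotation`; if given, every probe in
#'   the file must be annotated.
#' @param sheet Optional `sample_sheet`; if given, every column must be a
#'   known sample.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_intensity_matrix <- function(path, annotation = NULL, sheet = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") {
    stop("intensity file must have 'probe_id' as first column")
  }
  probes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  validate_intensity_matrix(m, annotation = annotation, sheet = sheet)
  m
}

#' Validate an intensity matrix against annotation and sample sheet
#'
#' @param m Numeric probes x samples matrix with dimnames.
#' @param annotation Optional `probe_annotation`.
#' @param sheet Optional `sample_sheet`.
#' @return `m`, invisibly.
#' @export
validate_intensity_matrix <- function(m, annotation = NULL, sheet = NULL) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("intensity matrix must be a matrix with probe and sample dimnames")
  }
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive or non-numeric intensity at probe '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]],
         "' (", nrow(bad), " offending cell(s); ",
         "the background model requires positive observations)")
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(rownames(m), annotation$probe_id)
    if (length(unknown)) {
      stop("probe(s) absent from annotation: ",
           paste(utils::head(unknown, 5), collapse = ", "),
           if (length(unknown) > 5) " ...")
    }
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(m), sheet$sample_id)
    if (length(unknown)) {
      stop("sample(s) absent from sample sheet: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(m)
}

#' Write an intensity matrix to TSV at full precision
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces every double bit-exactly.
#'
#' @param m Numeric probes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(m, path) {
  .write_numeric_tsv(m, path, id_col = "probe_id", fmt = "%.17g")
}

#' Write a normalised expression matrix to TSV
#'
#' Probeset-level log2 abundances, 6 decimal places, first column
#' `probeset_id`.
#'
#' @param m Numeric probesets x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  .write_numeric_tsv(m, path, id_col = "probeset_id", fmt = "%.6f")
}

#' Read a normalised expression matrix from TSV
#'
#' @param path Path to a file written by [write_expression_matrix()].
#' @return Numeric probesets x samples matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probeset_id") {
    stop("expression file must have 'probeset_id' as first column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(!is.finite(m))) stop("non-finite value in expression file")
  m
}

.write_numeric_tsv <- function(m, path, id_col, fmt) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(row) paste(sprintf(fmt, row), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}
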