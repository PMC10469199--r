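#' Closed vocabulary of alteration types
#'
#' The six genomic/transcriptomic alteration classes recognised by the
#' pipeline: mRNA up/downregulation (RNA-seq Z-score calls), copy-number
#' amplification and deep deletion, gene fusion, and putative driver
#' mutation (inframe, truncating and missense driver calls are collapsed
#' into this single class, since all downstream statistics treat driver
#' mutations as one category).
#'
#' @return Character vector of the six alteration type codes.
#' @export
alteration_types <- function() {
  c("mrna_up", "mrna_down", "cnv_amp", "cnv_deepdel", "fusion",
    "driver_mutation")
}

#' Closed vocabulary of circadian gene categories
#'
#' CCC = canonical clock component, CCG = clock-controlled gene/protein,
#' NMCRE = gene mediating the neural mechanisms of circadian rhythmicity
#' and its entrainment.
#'
#' @return Character vector of the three category codes.
#' @export
gene_categories <- function() {
  c("CCC", "CCG", "NMCRE")
}

## internal: read a tab-delimited table and check the header
read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

## internal: drop exact duplicate rows, reporting how many were removed
drop_duplicate_rows <- function(df, what = "rows") {
  dup <- duplicated(df)
  if (any(dup)) {
    message(sum(dup), " duplicate ", what, " dropped")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read per-patient alteration calls
#'
#' Parses a tab-delimited table with columns `patient_id`, `cancer_type`,
#' `gene`, `alteration_type`. Gene symbols are whitespace-stripped and
#' compared case-sensitively; no alias resolution is attempted. Exact
#' duplicate rows are dropped (with a message), so each
#' (patient, gene, alteration_type) triple occurs at most once per cohort.
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of alteration calls.
#' @export
read_alteration_calls <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "cancer_type", "gene",
                                 "alteration_type"))
  df$gene <- trimws(df$gene)
  df$patient_id <- trimws(df$patient_id)
  bad <- which(!(df$alteration_type %in% alteration_types()))
  if (length(bad) > 0) {
    stop("unknown alteration_type ", dQuote(df$alteration_type[bad[1]]),
         " in row ", bad[1], " of ", path, call. = FALSE)
  }
  drop_duplicate_rows(df, "alteration calls")
}

#' Read gene annotations
#'
#' Parses a tab-delimited table with columns `gene`, `category`
#' (CCC / CCG / NMCRE) and `is_cancer_driver` (TRUE/FALSE). Gene symbols
#' must be unique.
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of gene annotations.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("gene", "category", "is_cancer_driver"))
  if (nrow(df) == 0) {
    warning("annotation file ", path, " is empty")
    df$is_cancer_driver <- logical(0)
    return(df)
  }
  df$gene <- trimws(df$gene)
  bad <- which(!(df$category %in% gene_categories()))
  if (length(bad) > 0) {
    stop("unknown category ", dQuote(df$category[bad[1]]),
         " in row ", bad[1], " of ", path, call. = FALSE)
  }
  df$is_cancer_driver <- as.logical(df$is_cancer_driver)
  if (anyNA(df$is_cancer_driver)) {
    stop("is_cancer_driver must be TRUE or FALSE in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene symbol(s) in ", path, ": ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read cohort sizes
#'
#' Parses a tab-delimited table with columns `cancer_type` and
#' `n_patients` (positive integers, cohort codes unique).
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of cohorts.
#' @export
read_cohorts <- function(path) {
  df <- read_tsv_checked(path, c("cancer_type", "n_patients"))
  df$n_patients <- as.integer(df$n_patients)
  if (any(is.na(df$n_patients)) || any(df$n_patients < 1)) {
    stop("n_patients must be positive integers in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$cancer_type)) {
    stop("duplicated cohort code(s) in ", path, call. = FALSE)
  }
  df
}

#' Read a weighted protein-protein edge list
#'
#' Columns `protein_a`, `protein_b`, `confidence` with confidence in
#' \[0, 1\].
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of undirected weighted edges.
#' @export
read_ppi_edges <- function(path) {
  df <- read_tsv_checked(path, c("protein_a", "protein_b", "confidence"))
  df$confidence <- as.numeric(df$confidence)
  if (any(is.na(df$confidence)) ||
      any(df$confidence < 0 | df$confidence > 1)) {
    stop("confidence must lie in [0, 1] in ", path, call. = FALSE)
  }
  df
}

#' Read a directed causal edge list
#'
#' Columns `source`, `target`, `sign` with sign in \{-1, +1\}. Targets may
#' be proteins or hallmark phenotype sink nodes; phenotypes must never
#' appear as sources (validated downstream against the phenotype set in
#' use).
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of signed directed edges.
#' @export
read_causal_edges <- function(path) {
  df <- read_tsv_checked(path, c("source", "target", "sign"))
  df$sign <- as.integer(df$sign)
  if (any(!(df$sign %in% c(-1L, 1L)))) {
    stop("sign must be -1 or +1 in ", path, call. = FALSE)
  }
  df
}

#' Read per-patient survival records
#'
#' Columns `patient_id`, `time` (non-negative, months), `event`
#' (TRUE = death observed, FALSE = censored); any further columns (an
#' expression value or an altered flag) are carried through.
#'
#' @param path Path to the tab-delimited file.
#' @return A data.frame of survival records.
#' @export
read_survival_records <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "time", "event"))
  df$time <- as.numeric(df$time)
  if (any(is.na(df$time)) || any(df$time < 0)) {
    stop("time must be non-negative in ", path, call. = FALSE)
  }
  df$event <- as.logical(df$event)
  if (anyNA(df$event)) {
    stop("event must be TRUE or FALSE in ", path, call. = FALSE)
  }
  df
}

#' Write a table in the pipeline's canonical tab-delimited form
#'
#' Output is UTF-8 tab-delimited with a header, rows sorted by the columns
#' left to right (the leading columns act as the primary key), doubles
#' rendered with 6 significant digits and missing values written as "NA".
#' This makes outputs byte-reproducible and round-trippable.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  if (nrow(df) > 0) {
    ord <- do.call(order, unname(as.list(df)))
    df <- df[ord, , drop = FALSE]
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
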