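#' Pan-cancer cohort table (32 TCGA cohorts)
#'
#' The 32 TCGA PanCancer cohort codes with their patient counts (10,918
#' patients in total), shipped as a plain-text table. Useful for arithmetic
#' tallies at the real study scale and as a template for custom cohort
#' tables.
#'
#' @return data.frame with cancer_type, n_patients.
#' @export
reference_cohorts <- function() {
  read_cohorts(system.file("extdata", "tcga_pancancer_cohorts.tsv",
                           package = "chronoprio", mustWork = TRUE))
}

#' Reference-sized circadian gene annotation table (synthetic symbols)
#'
#' A 206-gene annotation table with the real category sizes: 17 canonical
#' clock components (the canonical CCC symbols: ARNTL, ARNTL2, CLOCK,
#' CRY1, CRY2, CSNK1D, CSNK1E, NPAS2, NR1D1, NR1D2, PER1, PER2, PER3,
#' RORA, RORB, RORC, TIMELESS), 59 clock-controlled genes and 130 NMCRE
#' genes. The CCG and NMCRE symbols are synthetic placeholders (`CCG001`
#' ..., `NMC001` ...): only the category structure is meaningful, which is
#' what the tally arithmetic consumes.
#'
#' @param driver_fraction Fraction of genes flagged as cancer drivers
#'   (default 0.25, applied deterministically to every 4th gene).
#' @return data.frame with gene, category, is_cancer_driver (206 rows).
#' @export
reference_gene_set <- function(driver_fraction = 0.25) {
  ccc <- c("ARNTL", "ARNTL2", "CLOCK", "CRY1", "CRY2", "CSNK1D", "CSNK1E",
           "NPAS2", "NR1D1", "NR1D2", "PER1", "PER2", "PER3", "RORA",
           "RORB", "RORC", "TIMELESS")
  genes <- c(ccc, sprintf("CCG%03d", seq_len(59)),
             sprintf("NMC%03d", seq_len(130)))
  n <- length(genes)
  step <- max(1L, round(1 / driver_fraction))
  data.frame(gene = genes,
             category = rep(c("CCC", "CCG", "NMCRE"),
                            times = c(17L, 59L, 130L)),
             is_cancer_driver = seq_len(n) %% step == 0L,
             stringsAsFactors = FALSE)
}
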