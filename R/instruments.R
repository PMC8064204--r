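#' Read a wide two-trait MR instrument table
#'
#' Reads the conventional wide instrument format in which each row carries
#' both the exposure and outcome association for one SNP: columns `SNP`,
#' `ea_E`, `oa_E`, `ea_O`, `oa_O`, `beta.E`, `beta.O`, `eaf.E`, `eaf.O`,
#' `se.O`, `pval.O`, `se.E`, `pval.E`, and optionally `exposure` / `outcome`
#' labels. The package ships such a table
#' (`system.file("extdata", "bw_t2d_instruments.tsv", package = "pleiocfdr")`)
#' holding a published set of genome-wide-significant birth-weight
#' instruments with their type 2 diabetes outcome effects (log-OR scale).
#'
#' @param path Path to the TSV file.
#' @return A list with summary-statistics tibbles `exposure` and `outcome`
#'   (columns as in [read_sumstats()], `chrom`/`pos` absent), ready for
#'   [harmonize()].
#' @export
read_instrument_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("SNP", "ea_E", "oa_E", "ea_O", "oa_O", "beta.E", "beta.O",
            "eaf.E", "eaf.O", "se.O", "pval.O", "se.E", "pval.E")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("instrument table missing column(s): ", paste(miss, collapse = ", ")))
  }
  exposure <- tibble::tibble(
    snp_id = tbl$SNP,
    effect_allele = tbl$ea_E, other_allele = tbl$oa_E,
    eaf = tbl$`eaf.E`, beta = tbl$`beta.E`, se = tbl$`se.E`, pval = tbl$`pval.E`
  )
  outcome <- tibble::tibble(
    snp_id = tbl$SNP,
    effect_allele = tbl$ea_O, other_allele = tbl$oa_O,
    eaf = tbl$`eaf.O`, beta = tbl$`beta.O`, se = tbl$`se.O`, pval = tbl$`pval.O`
  )
  attr(exposure, "trait_label") <- if ("exposure" %in% names(tbl)) tbl$exposure[1] else "exposure"
  attr(outcome, "trait_label") <- if ("outcome" %in% names(tbl)) tbl$outcome[1] else "outcome"
  list(exposure = exposure, outcome = outcome)
}
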