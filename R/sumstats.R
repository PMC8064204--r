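#' Column-name mapping for summary-statistics files
#'
#' Describes how the columns of a tab-separated GWAS summary-statistics file
#' map onto the canonical fields used throughout the package. The canonical
#' fields are `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval
#'   Column names in the file for each canonical field.
#' @param effect_is_or If `TRUE`, the `beta` column holds an odds ratio and is
#'   converted to a log odds ratio (`log(OR)`) on read.
#' @return A named list usable as the `dialect` argument of [read_sumstats()].
#' @export
sumstats_dialect <- function(snp_id = "SNP", chrom = "CHR", pos = "BP",
                             effect_allele = "EA", other_allele = "OA",
                             eaf = "EAF", beta = "BETA", se = "SE", pval = "P",
                             effect_is_or = FALSE) {
  list(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval,
    effect_is_or = isTRUE(effect_is_or)
  )
}

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-separated (optionally gzipped) summary-statistics file, renames
#' columns according to `dialect`, validates every record against the field
#' invariants, and returns a tibble sorted by `(chrom, pos)`. Records failing
#' an invariant (non-positive standard error, p-value outside `(0, 1]`, allele
#' frequency outside `[0, 1]`, identical or non-ACGT alleles, duplicated SNP
#' id) are dropped and counted; p-values of exactly 0 are clamped to the
#' smallest positive double rather than dropped. Multi-allelic records (allele
#' strings longer than one base) are rejected at read time.
#'
#' @param path Path to the file.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_label Optional label stored in the `trait_label` attribute.
#' @param n_samples Optional study sample size stored as metadata.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, sorted by `(chrom, pos)`,
#'   with attributes `trait_label`, `n_samples` and `n_dropped`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_label = NULL, n_samples = NA_integer_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  wanted <- dialect[setdiff(names(dialect), "effect_is_or")]
  missing <- unlist(wanted)[!unlist(wanted) %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    snp_id = raw[[dialect$snp_id]],
    chrom = raw[[dialect$chrom]],
    pos = suppressWarnings(as.integer(raw[[dialect$pos]])),
    effect_allele = toupper(raw[[dialect$effect_allele]]),
    other_allele = toupper(raw[[dialect$other_allele]]),
    eaf = suppressWarnings(as.numeric(raw[[dialect$eaf]])),
    beta = suppressWarnings(as.numeric(raw[[dialect$beta]])),
    se = suppressWarnings(as.numeric(raw[[dialect$se]])),
    pval = suppressWarnings(as.numeric(raw[[dialect$pval]]))
  )
  if (dialect$effect_is_or) tbl$beta <- log(tbl$beta)
  tbl$pval <- clamp_pvals(tbl$pval)
  ok <- !is.na(tbl$snp_id) & !is.na(tbl$pos) &
    tbl$effect_allele %in% VALID_BASES & tbl$other_allele %in% VALID_BASES &
    tbl$effect_allele != tbl$other_allele &
    !is.na(tbl$se) & tbl$se > 0 &
    !is.na(tbl$pval) & tbl$pval > 0 & tbl$pval <= 1 &
    !is.na(tbl$eaf) & tbl$eaf >= 0 & tbl$eaf <= 1 &
    !is.na(tbl$beta) & is.finite(tbl$beta)
  ok[ok] <- !duplicated(tbl$snp_id[ok])
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0("read_sumstats: dropped ", n_dropped,
                  " record(s) failing validation in ", basename(path)))
  }
  tbl <- tbl[ok, , drop = FALSE]
  if (nrow(tbl) == 0) abort(paste0("no valid records in ", path))
  tbl <- dplyr::arrange(tbl, chrom_rank(.data$chrom), .data$pos)
  attr(tbl, "trait_label") <- trait_label %||% basename(path)
  attr(tbl, "n_samples") <- n_samples
  attr(tbl, "n_dropped") <- n_dropped
  tbl
}

#' Write summary statistics to a tab-separated file
#'
#' Emits the canonical column order deterministically so that a write/read
#' round trip reproduces the table exactly.
#'
#' @param tbl A summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tbl, path) {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval")
  readr::write_tsv(tbl[, cols], path, progress = FALSE)
  invisible(path)
}

# Align t2's allele coding onto t1's. Returns a per-row action:
#   "same", "swap" (flip beta, complement eaf), "drop"
# Palindromic (A/T, C/G) pairs cannot be resolved by strand; they are dropped
# when eaf1 falls inside `band`, otherwise oriented by allele frequency.
align_alleles <- function(ea1, oa1, ea2, oa2, eaf1, eaf2,
                          band = c(0.42, 0.58)) {
  n <- length(ea1)
  action <- rep("drop", n)
  pal <- is_palindromic(ea1, oa1)

  same <- ea2 == ea1 & oa2 == oa1
  swap <- ea2 == oa1 & oa2 == ea1
  flip_same <- complement_allele(ea2) == ea1 & complement_allele(oa2) == oa1
  flip_swap <- complement_allele(ea2) == oa1 & complement_allele(oa2) == ea1

  action[!pal & same] <- "same"
  action[!pal & !same & swap] <- "swap"
  action[!pal & !same & !swap & flip_same] <- "same"
  action[!pal & !same & !swap & !flip_same & flip_swap] <- "swap"

  # palindromic: alleles cannot distinguish swap from strand flip; use eaf
  pal_ok <- pal & (same | swap | flip_same | flip_swap) &
    !(eaf1 >= band[1] & eaf1 <= band[2])
  agree <- (eaf1 - 0.5) * (eaf2 - 0.5) >= 0
  action[pal_ok & agree] <- "same"
  action[pal_ok & !agree] <- "swap"
  action
}

#' Merge two summary-statistics tables into a joint trait-pair panel
#'
#' Inner-joins two validated tables on `snp_id` and harmonizes the second
#' trait's effects onto the first trait's allele coding: swapped alleles flip
#' the sign of `beta` and complement `eaf`; strand-complement codings are
#' aligned likewise; palindromic SNPs (A/T or C/G) whose trait-1 effect-allele
#' frequency lies inside the ambiguity band are dropped, the remainder being
#' oriented by allele frequency. Rows whose allele sets cannot be reconciled
#' are dropped and counted. Signed z-scores `beta/se` are computed for both
#' traits.
#'
#' @param t1,t2 Summary-statistics tibbles from [read_sumstats()]. Trait 1 is
#'   the principal trait (`p1`, `z1`).
#' @param catalog Optional character vector of CpG-SNP ids; sets `cpg_flag`.
#' @param ambiguity_band Effect-allele-frequency window within which
#'   palindromic SNPs are considered unresolvable and dropped.
#' @return A tibble (`snp_id`, `chrom`, `pos`, `p1`, `p2`, `z1`, `z2`,
#'   `cpg_flag`) sorted by `(chrom, pos)`, with attribute `n_dropped`.
#' @export
merge_traits <- function(t1, t2, catalog = NULL, ambiguity_band = c(0.42, 0.58)) {
  j <- dplyr::inner_join(
    t1, t2,
    by = "snp_id", suffix = c("_1", "_2")
  )
  if (nrow(j) == 0) abort("no shared SNP ids between the two tables")
  action <- align_alleles(j$effect_allele_1, j$other_allele_1,
                          j$effect_allele_2, j$other_allele_2,
                          j$eaf_1, j$eaf_2, band = ambiguity_band)
  n_dropped <- sum(action == "drop")
  if (n_dropped > 0) {
    inform(paste0("merge_traits: dropped ", n_dropped,
                  " row(s) with irreconcilable or ambiguous alleles"))
  }
  keep <- action != "drop"
  j <- j[keep, , drop = FALSE]
  sgn <- ifelse(action[keep] == "swap", -1, 1)
  out <- tibble::tibble(
    snp_id = j$snp_id,
    chrom = j$chrom_1,
    pos = j$pos_1,
    p1 = j$pval_1,
    p2 = j$pval_2,
    z1 = j$beta_1 / j$se_1,
    z2 = sgn * j$beta_2 / j$se_2,
    cpg_flag = if (is.null(catalog)) FALSE else j$snp_id %in% catalog
  )
  out <- dplyr::arrange(out, chrom_rank(.data$chrom), .data$pos)
  attr(out, "trait_labels") <- c(attr(t1, "trait_label"), attr(t2, "trait_label"))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Restrict a merged panel to CpG-SNPs
#'
#' @param panel A merged trait-pair panel from [merge_traits()].
#' @param catalog Character vector of CpG-SNP ids.
#' @return The panel rows whose `snp_id` is in `catalog`, order preserved,
#'   with `cpg_flag` set to `TRUE`.
#' @export
filter_cpg <- function(panel, catalog) {
  out <- panel[panel$snp_id %in% catalog, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no panel SNPs found in the CpG catalog; check that catalog and panel use the same id scheme")
  }
  out$cpg_flag <- TRUE
  out
}
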