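#' Classify a SNP as a CpG-SNP from its flanking-base context
#'
#' A biallelic SNP is a CpG-SNP when its two alleles differ in whether a CG
#' dinucleotide overlaps the variant position, i.e. one allele creates (or
#' destroys) a potential DNA-methylation target. Because the CG dinucleotide
#' is strand-symmetric, checking the plus strand suffices: allele `X` at the
#' site forms a CpG either as `C`+`X` with `X == "G"` when the left flanking
#' base is `C`, or as `X`+`G` with `X == "C"` when the right flanking base is
#' `G`. The SNP is a CpG-SNP iff the set of CpG dinucleotides formed differs
#' between the two alleles.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param left_base,right_base Reference bases immediately 5' and 3' of the
#'   variant position.
#' @param allele_a,allele_b The two alleles; order is irrelevant.
#' @return Logical vector: `TRUE` where the alleles differ in CpG content.
#' @export
#' @examples
#' classify_cpg_snp("C", "T", "G", "A") # TRUE: G completes C-G, A does not
#' classify_cpg_snp("A", "T", "G", "C") # FALSE: neither allele forms CG
classify_cpg_snp <- function(left_base, right_base, allele_a, allele_b) {
  args <- vctrs_recycle(list(toupper(left_base), toupper(right_base),
                             toupper(allele_a), toupper(allele_b)))
  l <- args[[1]]; r <- args[[2]]; a <- args[[3]]; b <- args[[4]]
  bases <- c(l, r, a, b)
  if (any(!bases %in% VALID_BASES)) {
    abort(paste0("invalid nucleotide(s): ",
                 paste(unique(bases[!bases %in% VALID_BASES]), collapse = ", ")))
  }
  if (any(a == b)) abort("allele_a and allele_b must differ")
  left_site <- function(al) l == "C" & al == "G"
  right_site <- function(al) al == "C" & r == "G"
  (left_site(a) != left_site(b)) | (right_site(a) != right_site(b))
}

# minimal recycling helper (avoid a vctrs dependency for one call site)
vctrs_recycle <- function(xs) {
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else abort("arguments must have length 1 or a common length")
  })
}

#' Build a CpG-SNP catalog from flanking-base contexts
#'
#' @param contexts A tibble with columns `snp_id`, `left_base`, `right_base`,
#'   `allele_a`, `allele_b` (one row per SNP; see [read_snp_contexts()]).
#' @return Character vector of the `snp_id`s classified as CpG-SNPs.
#' @export
build_cpg_catalog <- function(contexts) {
  if (nrow(contexts) == 0) return(character(0))
  if (anyDuplicated(contexts$snp_id)) {
    abort("duplicate snp_id in contexts; ids must be unique")
  }
  is_cpg <- classify_cpg_snp(contexts$left_base, contexts$right_base,
                             contexts$allele_a, contexts$allele_b)
  contexts$snp_id[is_cpg]
}

#' Read SNP flanking-base contexts or a plain CpG-SNP id list
#'
#' `read_snp_contexts()` reads a tab-separated file with columns `snp_id`,
#' `left_base`, `right_base`, `allele_a`, `allele_b`. `read_cpg_catalog()`
#' reads a one-id-per-line list.
#'
#' @param path File path.
#' @return A tibble of contexts, or a character vector of ids.
#' @export
read_snp_contexts <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
  need <- c("snp_id", "left_base", "right_base", "allele_a", "allele_b")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("context file missing column(s): ", paste(miss, collapse = ", ")))
  }
  tbl
}

#' @rdname read_snp_contexts
#' @export
read_cpg_catalog <- function(path) {
  unique(readr::read_lines(path, progress = FALSE))
}
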