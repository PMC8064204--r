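#' Construct a genotype reference panel
#'
#' A genotype panel is a sample-by-SNP matrix of allele dosages in `{0, 1, 2}`
#' (missing values allowed) together with per-SNP coordinates, used for LD
#' computations. Columns are ordered by `(chrom, pos)`.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns; column
#'   names are SNP ids.
#' @param snp_info Tibble with columns `snp_id`, `chrom`, `pos` covering every
#'   column of `dosages`.
#' @return A `genotype_panel` object (the dosage matrix with an `snp_info`
#'   attribute, columns sorted by position).
#' @export
genotype_panel <- function(dosages, snp_info) {
  if (is.null(colnames(dosages))) abort("dosage matrix must have SNP ids as column names")
  if (anyDuplicated(colnames(dosages))) abort("duplicate SNP ids in dosage matrix")
  miss <- setdiff(colnames(dosages), snp_info$snp_id)
  if (length(miss) > 0) {
    abort(paste0("snp_info missing ", length(miss), " SNP id(s), e.g. ", miss[1]))
  }
  info <- snp_info[match(colnames(dosages), snp_info$snp_id), , drop = FALSE]
  ord <- order(chrom_rank(info$chrom), info$pos)
  dosages <- dosages[, ord, drop = FALSE]
  structure(dosages, snp_info = info[ord, , drop = FALSE], class = c("genotype_panel", "matrix", "array"))
}

#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.matrix(out) && !is.null(colnames(out))) {
    info <- attr(x, "snp_info")
    genotype_panel(out, info[info$snp_id %in% colnames(out), , drop = FALSE])
  } else {
    out
  }
}

panel_info <- function(panel) attr(panel, "snp_info")

#' Squared Pearson correlation between two dosage vectors
#'
#' Missing dosages are handled by pairwise-complete deletion. If fewer than
#' two complete pairs remain, or either vector has zero variance, the LD is
#' undefined; callers treat this as r-squared 0 (with a note), which this
#' function signals by returning `NA`.
#'
#' @param g_i,g_j Numeric dosage vectors of equal length.
#' @return Squared correlation in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_r2 <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) abort("dosage vectors must have equal length")
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- g_i[ok]; y <- g_j[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# r² matrix for a dosage submatrix; undefined entries become 0
r2_matrix <- function(g) {
  suppressWarnings(r <- cor(g, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Windowed LD pruning of a genotype panel
#'
#' PLINK-style `indep-pairwise` pruning: within a sliding window of
#' `window` SNPs, pairs with squared correlation above `r2_max` are broken by
#' removing one SNP of the pair until the window is clean; the window then
#' shifts `step` SNPs forward. Sweeps repeat until no window contains a
#' violating pair; because a step larger than 1 can leave a violating pair
#' that no stepped window straddles, a final unit-step sweep enforces the
#' procedure's termination condition — no retained pair within any
#' `window`-SNP span exceeds the ceiling — exactly.
#' Chromosomes are processed independently. The removal
#' tie-break is deterministic: the SNP with the larger principal-trait
#' p-value is removed when `pvals` is supplied, otherwise the SNP later in
#' position.
#'
#' @param panel A [genotype_panel()].
#' @param pvals Optional named numeric vector of principal-trait p-values
#'   (names are SNP ids), used for the removal tie-break.
#' @param window Window size in SNPs (must be > 1).
#' @param step Window shift in SNPs.
#' @param r2_max Squared-correlation ceiling above which a pair is violating.
#' @return A list of class `prune_result`: `kept` (ordered id vector) and
#'   `removed` (tibble `snp_id`, `partner`, `r2` recording, for each removed
#'   SNP, the retained partner that triggered the removal).
#' @export
indep_pairwise <- function(panel, pvals = NULL, window = 50, step = 5, r2_max = 0.2) {
  if (window <= 1) abort("`window` must be greater than 1")
  info <- panel_info(panel)
  ids <- info$snp_id
  removed <- list()
  kept_all <- character(0)
  for (ch in unique(info$chrom)) {
    k <- ids[info$chrom == ch]
    sweep_pass <- function(k, by) {
      changed <- FALSE
      s <- 1
      while (s <= length(k)) {
        repeat {
          win <- k[s:min(s + window - 1, length(k))]
          if (length(win) < 2) break
          r2 <- r2_matrix(panel[, win, drop = FALSE])
          viol <- which(upper.tri(r2) & r2 > r2_max, arr.ind = TRUE)
          if (nrow(viol) == 0) break
          viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
          a <- win[viol[1, 1]]; b <- win[viol[1, 2]]
          drop_id <- prune_tiebreak(a, b, pvals)
          keep_id <- setdiff(c(a, b), drop_id)
          removed[[length(removed) + 1]] <<-
            tibble::tibble(snp_id = drop_id, partner = keep_id,
                           r2 = r2[viol[1, 1], viol[1, 2]])
          k <- setdiff(k, drop_id)
          changed <- TRUE
        }
        if (s + window - 1 >= length(k)) break
        s <- s + by
      }
      list(k = k, changed = changed)
    }
    repeat {
      # stepped sweeps until stable, then a unit-step sweep to certify the
      # no-violating-pair termination condition
      repeat {
        res <- sweep_pass(k, step)
        k <- res$k
        if (!res$changed) break
      }
      res <- sweep_pass(k, 1L)
      k <- res$k
      if (!res$changed) break
    }
    kept_all <- c(kept_all, k)
  }
  structure(
    list(
      kept = kept_all,
      removed = if (length(removed) > 0) dplyr::bind_rows(removed)
                else tibble::tibble(snp_id = character(0), partner = character(0), r2 = numeric(0))
    ),
    class = "prune_result"
  )
}

# deterministic choice of which SNP of a violating pair to remove:
# larger principal p first, then later position (ids arrive position-sorted)
prune_tiebreak <- function(a, b, pvals) {
  if (!is.null(pvals) && !is.na(pvals[a]) && !is.na(pvals[b]) && pvals[a] != pvals[b]) {
    if (pvals[a] > pvals[b]) a else b
  } else {
    b
  }
}

#' @export
print.prune_result <- function(x, ...) {
  cat("LD pruning result: ", length(x$kept), " kept, ",
      nrow(x$removed), " removed\n", sep = "")
  invisible(x)
}

#' Greedy p-value clumping against a genotype panel
#'
#' Sorts SNPs by ascending p-value and accepts each SNP iff its squared
#' correlation with every previously accepted SNP on the same chromosome is
#' below `r2_max`. Ties in p are broken by SNP id for determinism. Undefined
#' LD (zero variance) counts as 0.
#'
#' @param stats Tibble with columns `snp_id` and `pval` (extra columns are
#'   ignored); every id must be present in `panel`.
#' @param panel A [genotype_panel()].
#' @param r2_max Squared-correlation ceiling for independence.
#' @return Character vector of kept ids, in acceptance (ascending-p) order.
#' @export
clump_by_pvalue <- function(stats, panel, r2_max = 0.001) {
  info <- panel_info(panel)
  stats <- stats[stats$snp_id %in% info$snp_id, , drop = FALSE]
  if (nrow(stats) == 0) return(character(0))
  ord <- order(stats$pval, stats$snp_id)
  cand <- stats$snp_id[ord]
  chrom <- setNames(info$chrom, info$snp_id)
  kept <- character(0)
  for (id in cand) {
    same_chr <- kept[chrom[kept] == chrom[id]]
    ok <- TRUE
    for (k in same_chr) {
      r2 <- pairwise_r2(panel[, id], panel[, k])
      if (is.na(r2)) r2 <- 0
      if (r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Read / write a genotype panel as plain TSV
#'
#' The dosage file is a tab-separated table with samples as rows: a first
#' column `sample_id` followed by one column per SNP. The SNP-info file has
#' columns `snp_id`, `chrom`, `pos`.
#'
#' @param dosage_path,info_path Paths to the two files.
#' @param panel A [genotype_panel()] to write.
#' @return `read_genotype_panel()` returns a [genotype_panel()];
#'   `write_genotype_panel()` returns the paths invisibly.
#' @export
read_genotype_panel <- function(dosage_path, info_path) {
  d <- readr::read_tsv(dosage_path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  info <- readr::read_tsv(info_path, col_types = "cci", progress = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  genotype_panel(m, info)
}

#' @rdname read_genotype_panel
#' @export
write_genotype_panel <- function(panel, dosage_path, info_path) {
  d <- tibble::as_tibble(unclass(panel))
  d <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(panel) %||%
                                         paste0("S", seq_len(nrow(panel)))), d)
  readr::write_tsv(d, dosage_path, progress = FALSE)
  readr::write_tsv(panel_info(panel), info_path, progress = FALSE)
  invisible(c(dosage_path, info_path))
}
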