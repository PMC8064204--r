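#' Genomic-control inflation factor
#'
#' The genomic-control lambda is the median association chi-square statistic
#' divided by the median of the 1-df chi-square distribution (0.4549). Each
#' p-value is converted to a two-sided z via the upper-tail normal quantile at
#' `p/2`, so lambda = median(z^2) / qchisq(0.5, 1).
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return The inflation factor (1 under a well-calibrated null).
#' @export
genomic_lambda <- function(pvals) {
  if (length(pvals) == 0) abort("`pvals` must be nonempty")
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1]")
  chi2 <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(chi2) / qchisq(0.5, df = 1)
}

stratum_label <- function(thr) paste0("p2 <= ", format(thr, trim = TRUE))

check_strata <- function(strata) {
  if (any(diff(strata) >= 0)) abort("stratum thresholds must be strictly decreasing")
  if (strata[1] != 1) abort("the first stratum must be the full set (threshold 1)")
  strata
}

#' Stratified conditional Q-Q curves
#'
#' For each conditional-trait stratum (SNPs with `p2` at or below a
#' threshold), sorts the principal-trait p-values `p1` ascending and pairs the
#' i-th order statistic with the empirical quantile `-log10(i / (n + 1))`.
#' Upward/leftward deflection of stricter strata relative to the full set
#' indicates cross-trait enrichment.
#'
#' @param panel A merged trait-pair panel ([merge_traits()]).
#' @param strata Strictly decreasing conditional-trait p-value thresholds,
#'   starting at 1 (the full set).
#' @param principal Which trait is principal: `"p1"` conditions on `p2`, and
#'   vice versa.
#' @return A tibble of class `cfdr_qq` with columns `stratum` (ordered
#'   factor), `threshold`, `n` (stratum size), `nominal` (`-log10 p`
#'   principal) and `empirical` (`-log10` quantile). Empty strata are omitted
#'   with a warning.
#' @export
conditional_qq <- function(panel, strata = c(1, 0.1, 0.01, 0.001),
                           principal = c("p1", "p2")) {
  if (nrow(panel) == 0) abort("`panel` must be nonempty")
  principal <- match.arg(principal)
  check_strata(strata)
  p1 <- panel[[principal]]
  p2 <- panel[[if (principal == "p1") "p2" else "p1"]]
  labs <- stratum_label(strata)
  out <- purrr::map2(strata, labs, function(thr, lab) {
    sel <- sort(p1[p2 <= thr])
    n <- length(sel)
    if (n == 0) {
      warn(paste0("stratum ", lab, " is empty; omitted"))
      return(NULL)
    }
    emp <- -log10(seq_len(n) / (n + 1))
    tibble::tibble(
      stratum = lab, threshold = thr, n = n,
      nominal = -log10(sel),
      empirical = emp
    )
  })
  out <- dplyr::bind_rows(out)
  out$stratum <- factor(out$stratum, levels = labs[labs %in% out$stratum])
  class(out) <- c("cfdr_qq", class(out))
  out
}

#' Inflation-corrected fold-enrichment curves
#'
#' For each stratum S and each nominal p-value on a log-spaced grid, the fold
#' enrichment is the fraction of S at or below that p divided by the fraction
#' of the full panel at or below it; the baseline (full-set) curve is 1
#' everywhere. When `gc_correct` is `TRUE` the principal-trait p-values are
#' first deflated by the genomic-control lambda (z^2 / lambda mapped back to
#' an upper-tail 1-df chi-square p).
#'
#' @inheritParams conditional_qq
#' @param gc_correct Apply genomic-control correction to the principal trait.
#' @param grid_n Number of nominal grid points, log-spaced between 1 and 1e-8.
#' @return A tibble of class `cfdr_enrichment` with columns `stratum`,
#'   `threshold`, `n`, `neglog10_p` (nominal grid) and `fold_enrichment`;
#'   grid points with an empty denominator are omitted. The lambda used is
#'   stored in attribute `lambda`.
#' @export
fold_enrichment <- function(panel, strata = c(1, 0.1, 0.01, 0.001),
                            principal = c("p1", "p2"), gc_correct = TRUE,
                            grid_n = 200) {
  if (nrow(panel) == 0) abort("`panel` must be nonempty")
  principal <- match.arg(principal)
  check_strata(strata)
  p1 <- panel[[principal]]
  p2 <- panel[[if (principal == "p1") "p2" else "p1"]]
  lambda <- genomic_lambda(p1)
  if (gc_correct) {
    chi2 <- qchisq(p1, df = 1, lower.tail = FALSE)
    p1 <- pchisq(chi2 / lambda, df = 1, lower.tail = FALSE)
  }
  grid <- 10^seq(0, -8, length.out = grid_n)
  n_all <- length(p1)
  base_frac <- vapply(grid, function(g) sum(p1 <= g) / n_all, numeric(1))
  labs <- stratum_label(strata)
  out <- purrr::map2(strata, labs, function(thr, lab) {
    in_s <- p2 <= thr
    n_s <- sum(in_s)
    if (n_s == 0) {
      warn(paste0("stratum ", lab, " is empty; omitted"))
      return(NULL)
    }
    s_frac <- vapply(grid, function(g) sum(p1[in_s] <= g) / n_s, numeric(1))
    keep <- base_frac > 0
    tibble::tibble(
      stratum = lab, threshold = thr, n = n_s,
      neglog10_p = -log10(grid[keep]),
      fold_enrichment = s_frac[keep] / base_frac[keep]
    )
  })
  out <- dplyr::bind_rows(out)
  out$stratum <- factor(out$stratum, levels = labs[labs %in% out$stratum])
  attr(out, "lambda") <- lambda
  class(out) <- c("cfdr_enrichment", class(out))
  out
}

#' Empirical conditional false discovery rate
#'
#' Pointwise empirical-Bayes estimate of the probability that a SNP is null
#' for the principal trait given that both its principal and conditional
#' p-values are at or below the observed values:
#' `cfdr_i = min(1, p1_i * N2_i / N12_i)`, where `N2_i` counts SNPs with
#' `p2 <= p2_i` and `N12_i` counts SNPs with both `p1 <= p1_i` and
#' `p2 <= p2_i` (ties inclusive; `N12 >= 1` since SNP i counts itself).
#' No monotonicity enforcement is applied; raw pointwise values are returned.
#'
#' @param p1 Principal-trait p-values.
#' @param p2 Conditional-trait p-values, aligned with `p1`.
#' @return Numeric vector of cFDR values in `(0, 1]`.
#' @export
empirical_cfdr <- function(p1, p2) {
  if (length(p1) != length(p2)) abort("`p1` and `p2` must have equal length")
  if (length(p1) == 0) abort("inputs must be nonempty")
  n2 <- rank_le(p2)
  n12 <- count_joint_le(p1, p2)
  pmin(1, p1 * n2 / n12)
}

# #{k : x_k <= x_i} = max-ties rank
rank_le <- function(x) rank(x, ties.method = "max")

#' Conjunction conditional FDR
#'
#' The element-wise maximum of the two cFDR orderings; small values support
#' association with both traits (pleiotropy).
#'
#' @param c12 cFDR of trait 1 conditional on trait 2.
#' @param c21 cFDR of trait 2 conditional on trait 1, aligned with `c12`.
#' @return Numeric vector `pmax(c12, c21)`.
#' @export
conjunction_cfdr <- function(c12, c21) {
  if (length(c12) != length(c21)) abort("`c12` and `c21` must have equal length")
  pmax(c12, c21)
}

#' Threshold cFDR values into significance calls
#'
#' A SNP is called significant when its value is at or below `alpha`
#' (inclusive boundary).
#'
#' @param values Numeric vector of cFDR or ccFDR values.
#' @param alpha Significance threshold, strictly inside (0, 1).
#' @return Logical vector of calls.
#' @export
call_significant <- function(values, alpha = 0.05) {
  check_prob(alpha)
  values <= alpha
}

#' Flag novel calls against a known-loci list
#'
#' A call is novel iff its id is absent from `known_ids` and, when a genotype
#' panel is supplied, its squared correlation with every known SNP on the same
#' chromosome is below `r2_link`.
#'
#' @param ids Character vector of called SNP ids.
#' @param known_ids Character vector of previously reported SNP ids (possibly
#'   empty).
#' @param panel Optional [genotype_panel()] covering the ids, for LD-based
#'   linking to known loci.
#' @param r2_link Squared-correlation threshold above which a call is
#'   considered tagged by a known SNP.
#' @return Logical vector: `TRUE` where the call is novel.
#' @export
exclude_known <- function(ids, known_ids, panel = NULL, r2_link = 0.2) {
  novel <- !(ids %in% known_ids)
  if (!is.null(panel)) {
    info <- panel_info(panel)
    chrom <- setNames(info$chrom, info$snp_id)
    known_in <- intersect(known_ids, info$snp_id)
    for (i in which(novel)) {
      id <- ids[i]
      if (!id %in% info$snp_id) next
      for (k in known_in[chrom[known_in] == chrom[id]]) {
        r2 <- pairwise_r2(panel[, id], panel[, k])
        if (!is.na(r2) && r2 >= r2_link) { novel[i] <- FALSE; break }
      }
    }
  }
  novel
}

#' Per-SNP conditional and conjunction FDR for a trait pair
#'
#' Computes both cFDR orderings, their conjunction, and significance flags at
#' the two conventional thresholds for every SNP of a merged panel.
#'
#' @param panel A merged trait-pair panel ([merge_traits()] /
#'   [filter_cpg()]), ideally LD-pruned.
#' @param alphas Two significance thresholds (default 0.05 and 0.01).
#' @param known_ids Optional known-loci list for novelty flagging.
#' @param geno Optional [genotype_panel()] for LD-based novelty linking.
#' @param r2_link LD threshold for novelty linking.
#' @return A tibble of class `cfdr_result`: `snp_id`, `chrom`, `pos`, `p1`,
#'   `p2`, `cfdr_12` (trait 1 given trait 2), `cfdr_21`, `ccfdr`, flags
#'   `sig05`, `sig01` (on `cfdr_12`), `pleio05`, `pleio01` (on `ccfdr`) and
#'   `novel`. Metadata attribute `monotonized = FALSE` records that raw
#'   pointwise values are reported.
#' @export
cfdr_analyse <- function(panel, alphas = c(0.05, 0.01), known_ids = character(0),
                         geno = NULL, r2_link = 0.2) {
  check_prob(alphas, "alphas")
  out <- dplyr::mutate(
    tibble::as_tibble(panel[, c("snp_id", "chrom", "pos", "p1", "p2")]),
    cfdr_12 = empirical_cfdr(panel$p1, panel$p2),
    cfdr_21 = empirical_cfdr(panel$p2, panel$p1),
    ccfdr = conjunction_cfdr(.data$cfdr_12, .data$cfdr_21),
    sig05 = call_significant(.data$cfdr_12, alphas[1]),
    sig01 = call_significant(.data$cfdr_12, alphas[2]),
    pleio05 = call_significant(.data$ccfdr, alphas[1]),
    pleio01 = call_significant(.data$ccfdr, alphas[2])
  )
  out$novel <- exclude_known(out$snp_id, known_ids, panel = geno, r2_link = r2_link)
  attr(out, "monotonized") <- FALSE
  attr(out, "alphas") <- alphas
  class(out) <- c("cfdr_result", class(out))
  out
}

#' Manhattan-plot data for cFDR results
#'
#' Lays SNPs out on a cumulative genome axis (chromosome offsets strictly
#' increasing) with `-log10` of the chosen FDR value on the y axis, plus the
#' significance flag at `alpha`. The reference-line height `-log10(alpha)`
#' (1.301 at alpha = 0.05) is stored in attribute `ref_line`.
#'
#' @param result A `cfdr_result` tibble from [cfdr_analyse()].
#' @param value Which column to plot: `"cfdr_12"`, `"cfdr_21"` or `"ccfdr"`.
#' @param alpha Significance threshold for the flag and reference line.
#' @return A tibble of class `cfdr_manhattan` with `snp_id`, `chrom`, `pos`,
#'   `pos_cum`, `neglog10`, `significant`.
#' @export
manhattan_data <- function(result, value = c("ccfdr", "cfdr_12", "cfdr_21"),
                           alpha = 0.05) {
  value <- match.arg(value)
  check_prob(alpha)
  d <- dplyr::arrange(tibble::as_tibble(result), chrom_rank(.data$chrom), .data$pos)
  offs <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$pos), rank = chrom_rank(.data$chrom)[1]) |>
    dplyr::arrange(.data$rank) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(as.numeric(.data$span)), default = 0))
  d <- dplyr::left_join(d, offs[, c("chrom", "offset")], by = "chrom")
  out <- tibble::tibble(
    snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
    pos_cum = d$pos + d$offset,
    neglog10 = -log10(d[[value]]),
    significant = d[[value]] <= alpha
  )
  attr(out, "ref_line") <- -log10(alpha)
  attr(out, "value") <- value
  class(out) <- c("cfdr_manhattan", class(out))
  out
}
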