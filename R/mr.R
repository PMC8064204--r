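#' Select genetic instruments from an exposure GWAS
#'
#' Instruments are SNPs reaching genome-wide significance (`pval <
#' p_threshold`, strict) in the exposure summary statistics, thinned to
#' approximate independence by greedy p-value clumping at `r2 < r2_max`
#' against the reference panel.
#'
#' @param exposure A summary-statistics tibble ([read_sumstats()]).
#' @param panel A [genotype_panel()] covering the candidate SNPs.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_max Independence ceiling for clumping (default 0.001).
#' @return Character vector of instrument SNP ids (possibly empty, with a
#'   warning).
#' @export
select_instruments <- function(exposure, panel, p_threshold = 5e-8, r2_max = 0.001) {
  hits <- exposure[exposure$pval < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    warn("no SNP reaches the significance threshold; returning an empty instrument set")
    return(character(0))
  }
  clump_by_pvalue(hits, panel, r2_max = r2_max)
}

#' Harmonize exposure and outcome effects onto a shared allele coding
#'
#' Joins exposure and outcome summary statistics on `snp_id` and re-signs the
#' outcome effect to the exposure's effect allele. Swapped allele codings flip
#' the outcome beta's sign and complement its allele frequency; strand
#' (complement) flips are resolved likewise. Palindromic SNPs (A/T or C/G) are
#' handled per `action`: `1` assumes both studies report the same strand,
#' `2` (default) resolves them by allele frequency but drops those whose
#' exposure effect-allele frequency falls inside the ambiguity band,
#' `3` drops all palindromic SNPs. Irreconcilable rows are dropped and
#' counted.
#'
#' @param exposure,outcome Summary-statistics tibbles restricted to the
#'   instrument SNPs (rows are matched on `snp_id`).
#' @param action Palindromic-SNP policy (1, 2 or 3; see above).
#' @param ambiguity_band Effect-allele-frequency window treated as
#'   unresolvable under action 2 (inclusive bounds).
#' @return An `mr_input` tibble: `snp_id`, `beta_exposure`, `se_exposure`,
#'   `pval_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `pval_outcome`, `eaf_outcome`, with attributes `exposure_label`,
#'   `outcome_label` and `n_dropped`.
#' @export
harmonize <- function(exposure, outcome, action = 2, ambiguity_band = c(0.42, 0.58)) {
  if (!action %in% 1:3) abort("`action` must be 1, 2 or 3")
  j <- dplyr::inner_join(exposure, outcome, by = "snp_id", suffix = c("_e", "_o"))
  if (nrow(j) == 0) abort("no shared SNP ids between exposure and outcome")
  pal <- is_palindromic(j$effect_allele_e, j$other_allele_e)
  act <- switch(action,
    # action 1: same strand assumed; palindromic swap is unambiguous
    align_same_strand(j),
    # action 2: eaf-resolved palindromes, ambiguous ones dropped
    align_alleles(j$effect_allele_e, j$other_allele_e,
                  j$effect_allele_o, j$other_allele_o,
                  j$eaf_e, j$eaf_o, band = ambiguity_band),
    # action 3: all palindromic dropped
    {
      a <- align_same_strand(j)
      a[pal] <- "drop"
      a
    }
  )
  n_dropped <- sum(act == "drop")
  if (n_dropped > 0) {
    inform(paste0("harmonize: dropped ", n_dropped,
                  " SNP(s) with ambiguous or irreconcilable alleles"))
  }
  keep <- act != "drop"
  sgn <- ifelse(act[keep] == "swap", -1, 1)
  jk <- j[keep, , drop = FALSE]
  out <- tibble::tibble(
    snp_id = jk$snp_id,
    beta_exposure = jk$beta_e, se_exposure = jk$se_e,
    pval_exposure = jk$pval_e, eaf_exposure = jk$eaf_e,
    beta_outcome = sgn * jk$beta_o, se_outcome = jk$se_o,
    pval_outcome = jk$pval_o,
    eaf_outcome = ifelse(sgn < 0, 1 - jk$eaf_o, jk$eaf_o)
  )
  attr(out, "exposure_label") <- attr(exposure, "trait_label")
  attr(out, "outcome_label") <- attr(outcome, "trait_label")
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mr_input", class(out))
  out
}

# strand-naive alignment: exact match or exact swap only
align_same_strand <- function(j) {
  act <- rep("drop", nrow(j))
  act[j$effect_allele_o == j$effect_allele_e & j$other_allele_o == j$other_allele_e] <- "same"
  act[j$effect_allele_o == j$other_allele_e & j$other_allele_o == j$effect_allele_e] <- "swap"
  act
}

#' Per-SNP Wald ratios
#'
#' The per-instrument causal estimate `beta_outcome / beta_exposure` with the
#' first-order standard error `se_outcome / |beta_exposure|`. SNPs with a zero
#' exposure beta are excluded with a note.
#'
#' @param input An `mr_input` tibble from [harmonize()].
#' @return A tibble `snp_id`, `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(input) {
  zero <- input$beta_exposure == 0
  if (any(zero)) {
    inform(paste0("wald_ratios: excluded ", sum(zero), " SNP(s) with beta_exposure = 0"))
  }
  x <- input[!zero, , drop = FALSE]
  tibble::tibble(
    snp_id = x$snp_id,
    ratio = x$beta_outcome / x$beta_exposure,
    ratio_se = x$se_outcome / abs(x$beta_exposure)
  )
}

mr_estimate_row <- function(method, n, b, se, pval) {
  tibble::tibble(
    method = method, nsnp = n, b = b, se = se, pval = pval,
    or = exp(b), or_lci95 = exp(b - 1.96 * se), or_uci95 = exp(b + 1.96 * se)
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of outcome betas on exposure betas without
#' intercept, weights `1/se_outcome^2`. The reported standard error follows
#' the multiplicative random-effects convention floored at the fixed-effect
#' SE: `se = se_FE * max(1, sigma_hat)`, where `sigma_hat` is the square root
#' of the weighted residual mean square on `n - 1` df. The p-value is normal.
#' A single instrument degenerates to its fixed-effect Wald ratio.
#'
#' @param input An `mr_input` tibble from [harmonize()].
#' @return A one-row estimate tibble (`method`, `nsnp`, `b`, `se`, `pval`,
#'   `or`, `or_lci95`, `or_uci95`).
#' @export
mr_ivw <- function(input) {
  n <- nrow(input)
  if (n == 0) abort("no instruments supplied")
  if (n == 1) {
    wr <- wald_ratios(input)
    return(mr_estimate_row("Inverse variance weighted", 1, wr$ratio, wr$ratio_se,
                           2 * pnorm(-abs(wr$ratio / wr$ratio_se))))
  }
  w <- 1 / input$se_outcome^2
  bx <- input$beta_exposure
  by <- input$beta_outcome
  b <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- 1 / sqrt(sum(w * bx^2))
  sigma <- sqrt(sum(w * (by - b * bx)^2) / (n - 1))
  se <- se_fe * max(1, sigma)
  mr_estimate_row("Inverse variance weighted", n, b, se, 2 * pnorm(-abs(b / se)))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, weights `1/se_outcome^2`, after orienting every SNP so its
#' exposure beta is non-negative (both betas negated where needed; required
#' for the intercept to be interpretable). Slope and intercept standard
#' errors are scaled by `max(1, sigma_hat)` as in [mr_ivw()]; p-values use the
#' t distribution on `n - 2` df. The intercept is the directional-pleiotropy
#' test.
#'
#' @param input An `mr_input` tibble with at least 3 instruments.
#' @return A list: `estimate` (one-row slope tibble) and `intercept`
#'   (tibble `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(input) {
  n <- nrow(input)
  if (n < 3) abort("MR-Egger needs at least 3 instruments for finite residual df")
  s <- ifelse(input$beta_exposure < 0, -1, 1)
  bx <- s * input$beta_exposure
  by <- s * input$beta_outcome
  w <- 1 / input$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  se_fixed <- sm$coefficients[, "Std. Error"] / sm$sigma
  se_rep <- se_fixed * scale
  est <- coef(fit)
  pvals <- 2 * pt(-abs(est / se_rep), df = n - 2)
  list(
    estimate = mr_estimate_row("MR Egger", n, est[["bx"]], se_rep[["bx"]], pvals[["bx"]]),
    intercept = tibble::tibble(
      intercept = est[["(Intercept)"]],
      se = se_rep[["(Intercept)"]],
      pval = pvals[["(Intercept)"]]
    )
  )
}

# interpolated weighted median of x with weights w
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  approx(s, x, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE for ratio-based estimators: resample each beta from
# its normal, recompute the point estimate
boot_se <- function(input, point_fun, n_boot, seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(input), input$beta_exposure, input$se_exposure)
    by <- rnorm(nrow(input), input$beta_outcome, input$se_outcome)
    point_fun(by / bx, input$se_outcome / abs(bx))
  }, numeric(1))
  sd(est)
}

#' Weighted-median causal estimate
#'
#' The interpolated weighted median of the per-SNP Wald ratios with weights
#' proportional to inverse squared first-order ratio standard errors;
#' consistent when at least half the weight comes from valid instruments. The
#' standard error is a parametric bootstrap (each beta resampled from its
#' normal) with a fixed seed; the p-value is normal.
#'
#' @param input An `mr_input` tibble with at least 3 instruments.
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed Seed for the bootstrap.
#' @return A one-row estimate tibble.
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = 20200527) {
  n <- nrow(input)
  if (n < 3) abort("weighted median needs at least 3 instruments")
  wr <- wald_ratios(input)
  b <- weighted_median_point(wr$ratio, 1 / wr$ratio_se^2)
  se <- boot_se(input, function(r, rse) weighted_median_point(r, 1 / rse^2),
                n_boot, seed)
  mr_estimate_row("Weighted median", n, b, se, 2 * pnorm(-abs(b / se)))
}

# kernel-density mode of ratios; bandwidth follows the mode-based-estimation
# rule h = phi * 0.9 * min(sd, mad) * n^(-1/5)
mode_point <- function(ratio, w, phi) {
  h <- phi * 0.9 * min(sd(ratio), mad(ratio)) / length(ratio)^(1 / 5)
  if (h <= 0 || !is.finite(h)) return(ratio[which.max(w)])
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, ratio, h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed empirical density of Wald ratios (normal
#' kernel, bandwidth `phi * 0.9 * min(SD, MAD) * n^(-1/5)`), with uniform
#' weights (simple mode) or inverse-variance weights on the ratio SEs
#' (weighted mode). Consistent when the largest group of instruments sharing
#' a ratio is valid. SE by parametric bootstrap; normal p-value. Mode
#' estimates are bandwidth-sensitive by nature.
#'
#' @param input An `mr_input` tibble with at least 3 instruments.
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform weights.
#' @param phi Bandwidth multiplier (default 1).
#' @inheritParams mr_weighted_median
#' @return A one-row estimate tibble.
#' @export
mr_mode <- function(input, weighted = TRUE, phi = 1, n_boot = 1000, seed = 20200527) {
  n <- nrow(input)
  if (n < 3) abort("mode estimation needs at least 3 instruments")
  wr <- wald_ratios(input)
  wfun <- if (weighted) function(rse) 1 / rse^2 else function(rse) rep(1, length(rse))
  b <- mode_point(wr$ratio, wfun(wr$ratio_se), phi)
  se <- boot_se(input, function(r, rse) mode_point(r, wfun(rse), phi), n_boot, seed)
  mr_estimate_row(if (weighted) "Weighted mode" else "Simple mode",
                  n, b, se, 2 * pnorm(-abs(b / se)))
}

#' Fit the full two-sample MR estimator suite
#'
#' Runs IVW, MR-Egger, weighted median, and simple and weighted mode on one
#' harmonized instrument set, collecting the estimates and the Egger
#' intercept (directional-pleiotropy) test in a single fit object.
#'
#' @param input An `mr_input` tibble from [harmonize()].
#' @param phi Mode bandwidth multiplier.
#' @inheritParams mr_weighted_median
#' @return An object of class `mr_fit`: list with `estimates` (five-row
#'   tibble), `egger_intercept`, `input`, and the bootstrap `seed`.
#' @export
mr_fit <- function(input, n_boot = 1000, seed = 20200527, phi = 1) {
  eg <- mr_egger(input)
  est <- dplyr::bind_rows(
    eg$estimate,
    mr_weighted_median(input, n_boot = n_boot, seed = seed),
    mr_ivw(input),
    mr_mode(input, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed),
    mr_mode(input, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed)
  )
  structure(
    list(estimates = est, egger_intercept = eg$intercept, input = input, seed = seed),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit (", nrow(x$input), " instruments; bootstrap seed ",
      x$seed, ")\n", sep = "")
  print(x$estimates)
  cat("Egger intercept: ", signif(x$egger_intercept$intercept, 3),
      " (p = ", signif(x$egger_intercept$pval, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname mr_fit
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::rename(x$estimates, estimate = "b", std.error = "se", p.value = "pval")
}

#' @rdname mr_fit
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    nsnp = nrow(x$input),
    egger_intercept = x$egger_intercept$intercept,
    egger_intercept_pval = x$egger_intercept$pval
  )
}

#' Bi-directional two-sample Mendelian randomization
#'
#' For each direction, selects instruments from the exposure summary
#' statistics ([select_instruments()]), extracts and harmonizes the outcome
#' effects ([harmonize()]), and fits the five-estimator suite ([mr_fit()]).
#' Directions with no instruments are reported as not estimable.
#'
#' @param t1,t2 Summary-statistics tibbles for the two traits.
#' @param panel A [genotype_panel()] for instrument clumping.
#' @param p_threshold,r2_max Instrument-selection parameters.
#' @param action Harmonization policy (see [harmonize()]).
#' @param n_boot,seed,phi Passed to [mr_fit()].
#' @return A tibble with columns `exposure`, `outcome`, `method`, `nsnp`,
#'   `b`, `se`, `pval`, `or`, `or_lci95`, `or_uci95` for both directions
#'   (method `"not estimable"` with `NA` values where a direction has no
#'   instruments), with the two `mr_fit` objects in attribute `fits`.
#' @export
run_bidirectional <- function(t1, t2, panel, p_threshold = 5e-8, r2_max = 0.001,
                              action = 2, n_boot = 1000, seed = 20200527, phi = 1) {
  lab1 <- attr(t1, "trait_label") %||% "trait1"
  lab2 <- attr(t2, "trait_label") %||% "trait2"
  one_direction <- function(exposure, outcome, elab, olab) {
    ivs <- select_instruments(exposure, panel, p_threshold, r2_max)
    if (length(ivs) < 3) {
      return(list(
        table = tibble::tibble(
          exposure = elab, outcome = olab, method = "not estimable",
          nsnp = length(ivs), b = NA_real_, se = NA_real_, pval = NA_real_,
          or = NA_real_, or_lci95 = NA_real_, or_uci95 = NA_real_
        ),
        fit = NULL
      ))
    }
    inp <- harmonize(exposure[exposure$snp_id %in% ivs, , drop = FALSE],
                     outcome[outcome$snp_id %in% ivs, , drop = FALSE],
                     action = action)
    fit <- mr_fit(inp, n_boot = n_boot, seed = seed, phi = phi)
    list(
      table = dplyr::bind_cols(tibble::tibble(exposure = elab, outcome = olab), fit$estimates),
      fit = fit
    )
  }
  fwd <- one_direction(t1, t2, lab1, lab2)
  rev <- one_direction(t2, t1, lab2, lab1)
  out <- dplyr::bind_rows(fwd$table, rev$table)
  attr(out, "fits") <- list(forward = fwd$fit, reverse = rev$fit)
  out
}
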