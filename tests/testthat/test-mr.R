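mk_input <- function(bx, by, se_o = rep(0.05, length(bx)), se_e = rep(0.005, length(bx))) {
  tibble::tibble(
    snp_id = sprintf("s%02d", seq_along(bx)),
    beta_exposure = bx, se_exposure = se_e,
    pval_exposure = 2 * pnorm(-abs(bx / se_e)), eaf_exposure = 0.3,
    beta_outcome = by, se_outcome = se_o,
    pval_outcome = 2 * pnorm(-abs(by / se_o)), eaf_outcome = 0.3
  )
}

test_that("Wald ratios follow the first-order formulas", {
  inp <- mk_input(c(0.5, 0.2, 0.1), c(0.1, 0, -0.05), se_o = c(0.05, 0.04, 0.02))
  wr <- wald_ratios(inp)
  expect_equal(wr$ratio, c(0.2, 0, -0.5), tolerance = 1e-12)
  expect_equal(wr$ratio_se, c(0.1, 0.2, 0.2), tolerance = 1e-12)
  set.seed(12)
  inp <- mk_input(rnorm(5, 0.1, 0.02), rnorm(5, 0, 0.05), se_o = runif(5, 0.02, 0.08))
  wr <- wald_ratios(inp)
  expect_equal(wr$ratio, inp$beta_outcome / inp$beta_exposure)
  expect_equal(wr$ratio_se, inp$se_outcome / abs(inp$beta_exposure))
  # zero exposure effect excluded with a note
  inp$beta_exposure[2] <- 0
  expect_message(wr0 <- wald_ratios(inp), "excluded")
  expect_equal(nrow(wr0), 4)
})

test_that("IVW reduces to the Wald ratio for one instrument and to WLS in general", {
  one <- mk_input(0.5, 0.1, se_o = 0.05)
  est <- mr_ivw(one)
  expect_equal(est$b, 0.2, tolerance = 1e-12)
  expect_equal(est$se, 0.1, tolerance = 1e-12)
  # 3-instrument toy set against explicitly solved normal equations
  inp <- mk_input(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.04), se_o = c(0.02, 0.03, 0.05))
  est <- mr_ivw(inp)
  w <- 1 / inp$se_outcome^2
  b_hand <- sum(w * inp$beta_exposure * inp$beta_outcome) / sum(w * inp$beta_exposure^2)
  s2 <- sum(w * (inp$beta_outcome - b_hand * inp$beta_exposure)^2) / 2
  se_hand <- sqrt(1 / sum(w * inp$beta_exposure^2)) * max(1, sqrt(s2))
  expect_equal(est$b, b_hand, tolerance = 1e-12)
  expect_equal(est$se, se_hand, tolerance = 1e-12)
  expect_error(mr_ivw(mk_input(numeric(0), numeric(0))), "no instruments")
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  set.seed(8)
  inp <- mk_input(rnorm(20, 0.1, 0.03), rnorm(20, 0.02, 0.04), se_o = runif(20, 0.02, 0.1))
  wr <- wald_ratios(inp)
  w <- (inp$beta_exposure / inp$se_outcome)^2
  expect_equal(mr_ivw(inp)$b, weighted.mean(wr$ratio, w), tolerance = 1e-12)
})

test_that("Egger slope and intercept match a hand-computed weighted regression", {
  set.seed(9)
  inp <- mk_input(c(0.1, -0.15, 0.2, 0.25, -0.3),
                  c(0.03, -0.02, 0.05, 0.04, -0.09),
                  se_o = c(0.02, 0.03, 0.04, 0.05, 0.03))
  eg <- mr_egger(inp)
  # orient, then solve the 2x2 weighted normal equations directly
  s <- sign(inp$beta_exposure)
  x <- s * inp$beta_exposure; y <- s * inp$beta_outcome
  w <- 1 / inp$se_outcome^2
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / 3
  cov_fixed <- solve(t(X) %*% (w * X))
  se_rep <- sqrt(diag(cov_fixed)) * max(1, sqrt(sigma2))
  expect_equal(eg$estimate$b, unname(beta[2]), tolerance = 1e-10)
  expect_equal(eg$estimate$se, unname(se_rep[2]), tolerance = 1e-10)
  expect_equal(eg$intercept$intercept, unname(beta[1]), tolerance = 1e-10)
  expect_equal(eg$intercept$se, unname(se_rep[1]), tolerance = 1e-10)
  expect_equal(eg$estimate$pval, unname(2 * pt(-abs(beta[2] / se_rep[2]), df = 3)),
               tolerance = 1e-10)
  expect_error(mr_egger(mk_input(c(0.1, 0.2), c(0.05, 0.15))), "3 instruments")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # three ratios 0, 1, 2 with equal weights -> 1 by interpolation
  inp <- mk_input(c(0.1, 0.1, 0.1), c(0, 0.1, 0.2), se_o = rep(0.05, 3))
  est <- mr_weighted_median(inp, n_boot = 50, seed = 1)
  expect_equal(est$b, 1, tolerance = 1e-12)
  # all ratios equal c -> c
  inp <- mk_input(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), se_o = c(0.03, 0.05, 0.02))
  expect_equal(mr_weighted_median(inp, n_boot = 50, seed = 1)$b, 0.5, tolerance = 1e-12)
  expect_error(mr_weighted_median(mk_input(c(0.1, 0.2), c(0, 0))), "3 instruments")
})

test_that("mode estimators find the dominant ratio cluster", {
  inp <- mk_input(rep(0.1, 4), rep(0.03, 4))
  expect_equal(mr_mode(inp, weighted = FALSE, n_boot = 50, seed = 1)$b, 0.3,
               tolerance = 1e-9)
  set.seed(14)
  bx <- rep(0.1, 25)
  by <- c(rnorm(20, 0.1 * 1, 0.001), rnorm(5, 0.1 * 3, 0.001))  # modes at 1 and 3
  inp <- mk_input(bx, by)
  expect_equal(mr_mode(inp, weighted = FALSE, n_boot = 50, seed = 1)$b, 1,
               tolerance = 0.1)
  expect_error(mr_mode(mk_input(c(0.1, 0.2), c(0, 0))), "3 instruments")
})

test_that("estimators are invariant to flipping the coded allele of any SNP", {
  set.seed(15)
  inp <- mk_input(rnorm(15, 0.1, 0.05), rnorm(15, 0.03, 0.05))
  flip <- c(2, 5, 11)
  inp2 <- inp
  inp2$beta_exposure[flip] <- -inp2$beta_exposure[flip]
  inp2$beta_outcome[flip] <- -inp2$beta_outcome[flip]
  expect_equal(mr_ivw(inp)$b, mr_ivw(inp2)$b, tolerance = 1e-12)
  expect_equal(mr_egger(inp)$estimate$b, mr_egger(inp2)$estimate$b, tolerance = 1e-12)
  expect_equal(mr_weighted_median(inp, n_boot = 50, seed = 2)$b,
               mr_weighted_median(inp2, n_boot = 50, seed = 2)$b, tolerance = 1e-12)
  expect_equal(mr_mode(inp, n_boot = 50, seed = 2)$b,
               mr_mode(inp2, n_boot = 50, seed = 2)$b, tolerance = 1e-12)
})

test_that("confidence intervals are the exponentiated normal bounds", {
  set.seed(16)
  inp <- mk_input(rnorm(10, 0.1, 0.02), rnorm(10, 0.05, 0.03))
  fit <- mr_fit(inp, n_boot = 50, seed = 3)
  est <- fit$estimates
  expect_equal(est$or, exp(est$b), tolerance = 1e-12)
  expect_equal(est$or_lci95, exp(est$b - 1.96 * est$se), tolerance = 1e-12)
  expect_equal(est$or_uci95, exp(est$b + 1.96 * est$se), tolerance = 1e-12)
  expect_true(all(est$or_lci95 <= est$or & est$or <= est$or_uci95))
  td <- tidy(fit)
  expect_true(all(c("method", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("harmonization re-signs outcome effects and applies palindrome policy", {
  ex <- toy_sumstats(4, seed = 30)
  out <- ex
  out$beta <- c(0.1, -0.2, 0.05, 0.3)
  # SNP 2 coded on the other allele in the outcome study
  out$effect_allele[2] <- ex$other_allele[2]
  out$other_allele[2] <- ex$effect_allele[2]
  out$eaf[2] <- 1 - ex$eaf[2]
  h <- harmonize(ex, out, action = 2)
  expect_equal(nrow(h), 4)
  expect_equal(h$beta_outcome[h$snp_id == "rs0002"], 0.2)
  # palindromic with eaf 0.50: dropped under action 2 and 3, kept under action 1
  ex$effect_allele[1] <- "A"; ex$other_allele[1] <- "T"; ex$eaf[1] <- 0.5
  out$effect_allele[1] <- "A"; out$other_allele[1] <- "T"; out$eaf[1] <- 0.5
  expect_equal(nrow(suppressMessages(harmonize(ex, out, action = 2))), 3)
  expect_equal(nrow(suppressMessages(harmonize(ex, out, action = 3))), 3)
  expect_equal(nrow(harmonize(ex, out, action = 1)), 4)
})

test_that("instrument selection recovers planted independent hits", {
  panel <- toy_panel(n_snps = 20, n_samples = 100, block = 5, r_ld = 0.95, seed = 40)
  exposure <- tibble::tibble(
    snp_id = colnames(panel),
    pval = rep(0.5, 20)
  )
  # three hits on distinct blocks, plus a linked neighbour of the first
  exposure$pval[c(1, 6, 11)] <- c(1e-12, 1e-10, 1e-9)
  exposure$pval[2] <- 1e-8  # same block as snp001, high LD
  ivs <- select_instruments(exposure, panel, p_threshold = 5e-8, r2_max = 0.1)
  expect_setequal(ivs, c("snp001", "snp006", "snp011"))
  expect_warning(
    empty <- select_instruments(dplyr::mutate(exposure, pval = 0.5), panel),
    "no SNP"
  )
  expect_length(empty, 0)
})

test_that("bi-directional runs recover a planted forward effect and flag dead directions", {
  sim <- simulate_mr_instruments(100, true_slope = 0.5, seed = 50)
  est <- mr_ivw(sim$input)
  expect_lt(abs(est$b - 0.5), 2 * est$se)
  # noiseless limit is exact
  exact <- simulate_mr_instruments(50, true_slope = 0.3, noise = FALSE, seed = 51)
  expect_equal(mr_ivw(exact$input)$b, 0.3, tolerance = 1e-10)
  # a direction with no genome-wide hits is reported not estimable
  spec <- mixture_spec(n_snps = 400, pi = c(1, 0, 0, 0), seed = 52)
  sim2 <- simulate_sumstats_pair(spec)
  panel <- simulate_reference_panel(spec, n_samples = 60)
  tbl <- suppressWarnings(run_bidirectional(sim2$trait1, sim2$trait2, panel,
                                            n_boot = 20, seed = 1))
  expect_true(all(tbl$method == "not estimable"))
  expect_true(all(is.na(tbl$b)))
})
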