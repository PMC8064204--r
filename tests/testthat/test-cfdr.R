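test_that("genomic lambda is 1 at the null median and tracks inflation", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1, tolerance = 1e-12)
  set.seed(101)
  expect_equal(genomic_lambda(runif(1e5)), 1, tolerance = 0.02)
  # chi-square statistics inflated by a factor 1.2
  set.seed(102)
  p <- pchisq(1.2 * rchisq(1e5, df = 1), df = 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p), 1.2, tolerance = 0.03)
  expect_error(genomic_lambda(numeric(0)), "nonempty")
})

test_that("cFDR reduces to the empirical FDR under uninformative conditioning", {
  p1 <- c(0.01, 0.2, 0.5, 0.9, 1.0)
  got <- empirical_cfdr(p1, rep(0.3, 5))
  expect_equal(got, pmin(1, p1 * 5 / rank(p1)), tolerance = 1e-12)
  expect_equal(got[1], 0.05)
  expect_equal(empirical_cfdr(0.37, 0.5), 0.37)  # single SNP
  expect_error(empirical_cfdr(runif(3), runif(4)), "equal length")
})

test_that("cFDR matches the double-loop counting oracle, including ties", {
  set.seed(7)
  p1 <- round(runif(8), 1)  # rounding forces ties
  p2 <- round(runif(8), 1)
  expect_equal(empirical_cfdr(p1, p2), cfdr_oracle(p1, p2), tolerance = 1e-12)
  for (seed in 1:4) {
    set.seed(seed)
    p1 <- runif(200); p2 <- runif(200)
    expect_equal(empirical_cfdr(p1, p2), cfdr_oracle(p1, p2), tolerance = 1e-12)
  }
})

test_that("cFDR is invariant to monotone transforms of the conditional p-values", {
  set.seed(11)
  p1 <- runif(300); p2 <- runif(300)
  base <- empirical_cfdr(p1, p2)
  expect_equal(empirical_cfdr(p1, p2^3), base, tolerance = 1e-12)
  expect_equal(empirical_cfdr(p1, rank(p2) / 301), base, tolerance = 1e-12)
})

test_that("conjunction cFDR is the element-wise maximum", {
  expect_equal(conjunction_cfdr(c(0.01, 0.2), c(0.2, 0.1)), c(0.2, 0.2))
  x <- runif(50)
  expect_equal(conjunction_cfdr(x, x), x)
  set.seed(3)
  a <- runif(100); b <- runif(100)
  cc <- conjunction_cfdr(a, b)
  expect_true(all(cc >= a & cc >= b))
  expect_error(conjunction_cfdr(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("significance calls use an inclusive threshold", {
  expect_true(call_significant(0.05, 0.05))
  expect_false(any(call_significant(rep(1, 10), 0.05)))
  expect_error(call_significant(0.5, 1.5), "inside")
  set.seed(5)
  v <- runif(500)
  expect_true(sum(call_significant(v, 0.01)) <= sum(call_significant(v, 0.05)))
})

test_that("with constant conditioning, monotonized cFDR calls equal BH step-up calls", {
  set.seed(21)
  p1 <- c(runif(50, 0, 1e-4), runif(1950))  # signal + null mix, no ties
  cfdr <- empirical_cfdr(p1, rep(0.5, length(p1)))
  ord <- order(p1)
  monotone <- rev(cummin(rev(cfdr[ord])))
  bh <- p.adjust(p1, method = "BH")[ord]
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_identical(monotone <= alpha, bh <= alpha)
    # raw pointwise calls are a subset of the BH rejections
    expect_true(all(which(cfdr[ord] <= alpha) %in% which(bh <= alpha)))
  }
})

test_that("conditional Q-Q curves behave at the null and for degenerate strata", {
  n <- 2000
  panel <- tibble::tibble(
    snp_id = sprintf("s%04d", 1:n), chrom = "1", pos = 1:n,
    p1 = (1:n) / n, p2 = rep(c(0.05, 0.5), n / 2)
  )
  qq <- conditional_qq(panel, strata = c(1, 0.1))
  base <- qq[qq$threshold == 1, ]
  expect_lt(max(abs(base$nominal - base$empirical)), 0.05)
  # nested sizes
  sizes <- unique(qq[, c("threshold", "n")])
  expect_true(all(diff(sizes$n) <= 0))
  one <- conditional_qq(tibble::tibble(p1 = 0.01, p2 = 0.001), strata = c(1, 0.1))
  expect_equal(nrow(one), 2)
  expect_warning(
    conditional_qq(tibble::tibble(p1 = 0.5, p2 = 0.5), strata = c(1, 0.001)),
    "empty"
  )
})

test_that("enrichment of stricter strata shows as increasing Q-Q deflection", {
  spec <- mixture_spec(n_snps = 20000, seed = 13)
  sim <- simulate_sumstats_pair(spec)
  panel <- tibble::tibble(p1 = sim$trait1$pval, p2 = sim$trait2$pval)
  qq <- conditional_qq(panel)
  defl <- vapply(split(qq, qq$threshold), function(d) {
    approx(rev(d$empirical), rev(d$nominal), xout = 2, ties = "ordered")$y
  }, numeric(1))
  defl <- defl[order(as.numeric(names(defl)), decreasing = TRUE)]
  expect_true(all(diff(defl) > 0))
})

test_that("fold enrichment is 1 for the full set and counts-forced elsewhere", {
  set.seed(31)
  n <- 100
  p1 <- c(runif(10, 0.001, 0.04), runif(90, 0.061, 1))
  panel <- tibble::tibble(p1 = p1, p2 = rep(c(0, 1), c(10, 90)))
  fe <- fold_enrichment(panel, strata = c(1, 0.5), gc_correct = FALSE)
  base <- fe[fe$threshold == 1, ]
  expect_true(all(abs(base$fold_enrichment - 1) < 1e-12))
  strat <- fe[fe$threshold == 0.5, ]
  # grid points between the 10th and 11th order statistic force FE = 10
  sel <- strat$neglog10_p > -log10(0.06) & strat$neglog10_p < -log10(0.04)
  expect_true(any(sel))
  expect_true(all(abs(strat$fold_enrichment[sel] - 10) < 1e-12))
})

test_that("stratum enrichment at -log10 p = 3 is monotone under pleiotropy", {
  spec <- mixture_spec(n_snps = 20000, seed = 17)
  sim <- simulate_sumstats_pair(spec)
  panel <- tibble::tibble(p1 = sim$trait1$pval, p2 = sim$trait2$pval)
  fe <- fold_enrichment(panel)
  at3 <- vapply(split(fe, fe$threshold), function(d) {
    approx(d$neglog10_p, d$fold_enrichment, xout = 3, ties = "ordered")$y
  }, numeric(1))
  at3 <- at3[order(as.numeric(names(at3)), decreasing = TRUE)]
  expect_true(all(diff(at3) >= 0))
})

test_that("novelty flags respect id lists and LD tagging", {
  ids <- c("a", "b", "c")
  expect_equal(exclude_known(ids, character(0)), c(TRUE, TRUE, TRUE))
  expect_equal(exclude_known(ids, "b"), c(TRUE, FALSE, TRUE))
  panel <- toy_panel(n_snps = 4, n_samples = 40, r_ld = 0, seed = 2)
  dup <- unclass(panel); dup[, 2] <- dup[, 1]  # snp002 in perfect LD with snp001
  panel <- genotype_panel(dup, attr(panel, "snp_info"))
  out <- exclude_known(c("snp002", "snp003"), "snp001", panel = panel)
  expect_equal(out, c(FALSE, TRUE))
})

test_that("manhattan data lays chromosomes out cumulatively", {
  res <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"), chrom = c("1", "1", "2", "10"),
    pos = c(10L, 50L, 20L, 5L),
    ccfdr = c(0.05, 0.5, 0.001, 0.2)
  )
  md <- manhattan_data(res, value = "ccfdr")
  expect_equal(md$neglog10[1], -log10(0.05), tolerance = 1e-6)
  expect_equal(attr(md, "ref_line"), -log10(0.05))
  expect_equal(md$significant, c(TRUE, FALSE, TRUE, FALSE))
  # chromosome offsets strictly increasing in numeric chromosome order
  offs <- tapply(md$pos_cum - md$pos, md$chrom, unique)
  expect_true(offs[["1"]] < offs[["2"]] & offs[["2"]] < offs[["10"]])
  one <- manhattan_data(res[res$chrom == "1", ], value = "ccfdr")
  expect_equal(one$pos_cum, one$pos)
})

test_that("cfdr_analyse assembles consistent per-SNP results", {
  spec <- mixture_spec(n_snps = 3000, seed = 19)
  sim <- simulate_sumstats_pair(spec)
  panel <- merge_traits(sim$trait1, sim$trait2, catalog = sim$cpg_catalog)
  res <- cfdr_analyse(panel, known_ids = panel$snp_id[1:5])
  expect_equal(res$ccfdr, pmax(res$cfdr_12, res$cfdr_21))
  expect_true(all(res$cfdr_12 > 0 & res$cfdr_12 <= 1))
  expect_true(all(res$sig05[res$sig01]))       # sig01 implies sig05
  expect_true(all(res$pleio05[res$pleio01]))
  expect_false(any(res$novel[res$snp_id %in% panel$snp_id[1:5]]))
  expect_false(attr(res, "monotonized"))
})
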