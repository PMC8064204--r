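#' Specification of a synthetic two-trait GWAS architecture
#'
#' Defines the four-component mixture from which paired summary statistics
#' are drawn: a fraction `pi[1]` of SNPs is null for both traits, `pi[2]`
#' carries a trait-1-only signal, `pi[3]` a trait-2-only signal, and `pi[4]`
#' is pleiotropic (signals in both traits with correlation `rho`). Non-null
#' signal means are drawn `N(0, sigma^2)` on the z-score scale. CpG flags are
#' Bernoulli(`f_cpg`), independent of class by default. Genotypes for the
#' matching reference panel use AR(1) latent correlation `r_ld` within blocks
#' of `block_size` SNPs.
#'
#' @param n_snps Number of SNPs.
#' @param pi Mixture proportions (null, trait-1-only, trait-2-only,
#'   pleiotropic); must be non-negative and sum to 1.
#' @param sigma1,sigma2 Signal SDs on the z scale for the two traits.
#' @param rho Correlation of the pleiotropic signal components, in `[-1, 1]`.
#' @param f_cpg CpG-SNP fraction.
#' @param cpg_enrichment Multiplier on `f_cpg` for non-null SNPs (1 =
#'   independence).
#' @param block_size LD block length in SNPs.
#' @param r_ld Within-block AR(1) latent correlation.
#' @param n1,n2 GWAS sample sizes behind the `se = 1/sqrt(2 n eaf (1-eaf))`
#'   heuristic.
#' @param seed Integer seed; every generator consuming the spec is
#'   reproducible given the seed.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(n_snps = 10000,
                         pi = c(null = 0.90, t1 = 0.04, t2 = 0.04, both = 0.02),
                         sigma1 = 3, sigma2 = 3, rho = 0.5,
                         f_cpg = 0.25, cpg_enrichment = 1,
                         block_size = 20, r_ld = 0.8,
                         n1 = 1e5, n2 = 1e5, seed = 1) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-12) {
    abort("`pi` must be 4 non-negative proportions summing to 1")
  }
  if (sigma1 <= 0 || sigma2 <= 0) abort("signal SDs must be positive")
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1]")
  if (block_size < 1 || r_ld < 0 || r_ld >= 1) abort("invalid LD block parameters")
  structure(
    list(n_snps = n_snps, pi = unname(pi), sigma1 = sigma1, sigma2 = sigma2,
         rho = rho, f_cpg = f_cpg, cpg_enrichment = cpg_enrichment,
         block_size = block_size, r_ld = r_ld, n1 = n1, n2 = n2, seed = seed),
    class = "mixture_spec"
  )
}

# deterministic SNP map: ids, 22 chromosomes in contiguous stretches,
# increasing positions, non-palindromic allele pairs
snp_map <- function(n_snps) {
  chrom <- as.character(rep(1:22, length.out = 22)[ceiling(seq_len(n_snps) / ceiling(n_snps / 22))])
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq(1e5, by = 5000, length.out = length(idx))
  }
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                    "G", "A", "C", "A", "G", "T", "C", "T"),
                  ncol = 2, byrow = TRUE)
  k <- ((seq_len(n_snps) - 1) %% nrow(pairs)) + 1
  tibble::tibble(
    snp_id = sprintf("rs%07d", seq_len(n_snps)),
    chrom = chrom, pos = pos,
    effect_allele = pairs[k, 1], other_allele = pairs[k, 2]
  )
}

#' Simulate a genotype reference panel with block LD
#'
#' Generates a latent Gaussian per sample with AR(1) correlation `r_ld`
#' inside consecutive blocks of `block_size` SNPs (independent across blocks
#' and chromosomes), and discretizes it to dosages `{0, 1, 2}` at the
#' Hardy-Weinberg quantiles of the SNP's allele frequency (drawn uniformly in
#' `[0.05, 0.5]`), so genotype margins follow Hardy-Weinberg proportions.
#' Because discretization attenuates correlation, the latent AR parameter is
#' inflated by the arcsine (tetrachoric-style) relation
#' `sin(pi/2 * r_ld)`, making `r_ld` approximately the correlation realized
#' on the dosage scale rather than the latent scale.
#'
#' @param spec A [mixture_spec()].
#' @param n_samples Number of diploid samples (at least 20).
#' @return A [genotype_panel()] with the spec's SNP map.
#' @export
simulate_reference_panel <- function(spec, n_samples = 200) {
  if (!inherits(spec, "mixture_spec")) abort("`spec` must be a mixture_spec")
  if (n_samples < 20) abort("`n_samples` must be at least 20")
  set.seed(spec$seed + 1L)
  map <- snp_map(spec$n_snps)
  maf <- runif(spec$n_snps, 0.05, 0.5)
  # arcsine inflation: target r_ld on the dosage scale after discretization
  r_lat <- sin(pi / 2 * spec$r_ld)
  z <- matrix(0, n_samples, spec$n_snps)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    for (b0 in seq(1, length(idx), by = spec$block_size)) {
      cols <- idx[b0:min(b0 + spec$block_size - 1, length(idx))]
      e <- matrix(rnorm(n_samples * length(cols)), n_samples)
      for (j in seq_along(cols)) {
        z[, cols[j]] <- if (j == 1) e[, j]
          else r_lat * z[, cols[j - 1]] + sqrt(1 - r_lat^2) * e[, j]
      }
    }
  }
  # Hardy-Weinberg cut points: P(0) = (1-maf)^2, P(0 or 1) = 1 - maf^2
  dos <- sweep(z, 2, qnorm((1 - maf)^2), `>`) + sweep(z, 2, qnorm(1 - maf^2), `>`)
  colnames(dos) <- map$snp_id
  rownames(dos) <- sprintf("S%04d", seq_len(n_samples))
  genotype_panel(dos, map[, c("snp_id", "chrom", "pos")])
}

#' Simulate a paired set of GWAS summary statistics with known truth
#'
#' Draws each SNP's latent class from the mixture, adds `N(0, sigma^2)`
#' signal means to unit normal noise (with correlation `rho` between the two
#' signal components of pleiotropic SNPs), and converts z-scores to two-sided
#' p-values `2 * pnorm(-|z|)` and effect sizes `beta = z * se` with the
#' allele-frequency/sample-size heuristic `se = 1/sqrt(2 n eaf (1 - eaf))`.
#' Signals sit on index SNPs only (no LD leakage into neighbours), keeping
#' the truth table crisp for FDR evaluation.
#'
#' @param spec A [mixture_spec()].
#' @return A list: `trait1`, `trait2` (summary-statistics tibbles as from
#'   [read_sumstats()]), `truth` (tibble `snp_id`, `class` in
#'   `{"00","10","01","11"}`, `mu1`, `mu2`, `cpg_flag`) and `cpg_catalog`
#'   (character vector).
#' @export
simulate_sumstats_pair <- function(spec) {
  if (!inherits(spec, "mixture_spec")) abort("`spec` must be a mixture_spec")
  set.seed(spec$seed)
  n <- spec$n_snps
  map <- snp_map(n)
  cls <- sample(c("00", "10", "01", "11"), n, replace = TRUE, prob = spec$pi)
  mu1 <- ifelse(cls %in% c("10", "11"), rnorm(n, 0, spec$sigma1), 0)
  mu2 <- numeric(n)
  solo2 <- cls == "01"
  mu2[solo2] <- rnorm(sum(solo2), 0, spec$sigma2)
  both <- cls == "11"
  # correlated pleiotropic signal: mu2 | mu1 via the bivariate normal
  mu2[both] <- spec$rho * (spec$sigma2 / spec$sigma1) * mu1[both] +
    sqrt(1 - spec$rho^2) * rnorm(sum(both), 0, spec$sigma2)
  z1 <- mu1 + rnorm(n)
  z2 <- mu2 + rnorm(n)
  p_cpg <- pmin(1, spec$f_cpg * ifelse(cls == "00", 1, spec$cpg_enrichment))
  cpg <- runif(n) < p_cpg
  eaf <- runif(n, 0.05, 0.95)
  make_trait <- function(z, nn, label) {
    se <- 1 / sqrt(2 * nn * eaf * (1 - eaf))
    out <- dplyr::bind_cols(map, tibble::tibble(
      eaf = eaf, beta = z * se, se = se,
      pval = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    ))
    attr(out, "trait_label") <- label
    attr(out, "n_samples") <- nn
    out
  }
  list(
    trait1 = make_trait(z1, spec$n1, "trait1"),
    trait2 = make_trait(z2, spec$n2, "trait2"),
    truth = tibble::tibble(snp_id = map$snp_id, class = cls,
                           mu1 = mu1, mu2 = mu2, cpg_flag = cpg),
    cpg_catalog = map$snp_id[cpg]
  )
}

#' Simulate harmonized MR instruments with a known causal slope
#'
#' Exposure betas are `|N(0, 0.05^2)| + 0.02` (bounded away from zero);
#' outcome betas are `theta * beta_exposure + alpha_i + noise`, with
#' per-instrument pleiotropy `alpha_i ~ N(pleiotropy_mean, pleiotropy_sd^2)`
#' (directional pleiotropy off by default) and noise `N(0, se_outcome^2)`.
#' Standard errors are fixed and small.
#'
#' @param n_snp Number of instruments (at least 2).
#' @param true_slope The causal slope theta.
#' @param pleiotropy_sd SD of balanced per-instrument pleiotropy.
#' @param pleiotropy_mean Mean pleiotropy (nonzero = directional).
#' @param se_exposure,se_outcome Fixed standard errors.
#' @param noise If `FALSE`, outcome noise is suppressed (noiseless limit).
#' @param seed Integer seed.
#' @return A list: `input` (an `mr_input` tibble) and `truth`
#'   (`list(slope, pleiotropy_mean, pleiotropy_sd)`).
#' @export
simulate_mr_instruments <- function(n_snp, true_slope, pleiotropy_sd = 0,
                                    pleiotropy_mean = 0, se_exposure = 0.005,
                                    se_outcome = 0.05, noise = TRUE, seed = 1) {
  if (n_snp < 2) abort("`n_snp` must be at least 2")
  set.seed(seed)
  bx <- abs(rnorm(n_snp, 0, 0.05)) + 0.02
  alpha <- rnorm(n_snp, pleiotropy_mean, pleiotropy_sd)
  by <- true_slope * bx + alpha + if (noise) rnorm(n_snp, 0, se_outcome) else 0
  eaf <- runif(n_snp, 0.1, 0.9)
  input <- tibble::tibble(
    snp_id = sprintf("iv%04d", seq_len(n_snp)),
    beta_exposure = bx, se_exposure = se_exposure,
    pval_exposure = 2 * pnorm(-abs(bx / se_exposure)),
    eaf_exposure = eaf,
    beta_outcome = by, se_outcome = se_outcome,
    pval_outcome = 2 * pnorm(-abs(by / se_outcome)),
    eaf_outcome = eaf
  )
  class(input) <- c("mr_input", class(input))
  list(input = input,
       truth = list(slope = true_slope, pleiotropy_mean = pleiotropy_mean,
                    pleiotropy_sd = pleiotropy_sd))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the two summary-statistics TSVs, the genotype dosage TSV with its
#' SNP-info table, the CpG catalog, the truth table, and a YAML manifest
#' recording the spec and seed. Re-running with the same spec reproduces
#' every file byte-identically.
#'
#' @param outdir Writable output directory (created if absent).
#' @param spec A [mixture_spec()].
#' @param n_samples Reference-panel sample count.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_bundle <- function(outdir, spec, n_samples = 200) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_sumstats_pair(spec)
  panel <- simulate_reference_panel(spec, n_samples = n_samples)
  paths <- c(
    trait1 = file.path(outdir, "trait1.tsv"),
    trait2 = file.path(outdir, "trait2.tsv"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    snp_info = file.path(outdir, "snp_info.tsv"),
    cpg_catalog = file.path(outdir, "cpg_catalog.txt"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.yaml")
  )
  write_sumstats(sim$trait1, paths[["trait1"]])
  write_sumstats(sim$trait2, paths[["trait2"]])
  write_genotype_panel(panel, paths[["genotypes"]], paths[["snp_info"]])
  readr::write_lines(sim$cpg_catalog, paths[["cpg_catalog"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  yaml::write_yaml(c(unclass(spec), list(n_samples = n_samples)), paths[["manifest"]])
  invisible(paths)
}
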