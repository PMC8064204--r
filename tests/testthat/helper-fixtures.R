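# shared fixtures and independent oracle implementations

# dialect matching the package's own canonical column names
canon_dialect <- function(...) {
  sumstats_dialect(
    snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", ...
  )
}

toy_sumstats <- function(n = 20, seed = 1, chrom = "1") {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))
  k <- ((seq_len(n) - 1) %% 4) + 1
  tibble::tibble(
    snp_id = sprintf("rs%04d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(seq(1000, by = 1000, length.out = n)),
    effect_allele = pairs[k, 1],
    other_allele = pairs[k, 2],
    eaf = round(runif(n, 0.1, 0.9), 3),
    beta = round(rnorm(n, 0, 0.05), 5),
    se = round(runif(n, 0.01, 0.05), 5),
    pval = round(runif(n), 6)
  )
}

write_toy_file <- function(tbl, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

# brute-force 3-mer CpG oracle: write out both alleles' trimer and compare the
# positions at which "CG" occurs
cpg_oracle <- function(l, r, a, b) {
  sites <- function(al) {
    m <- gregexpr("CG", paste0(l, al, r))[[1]]
    as.integer(m[m > 0])
  }
  !identical(sites(a), sites(b))
}

# independent double-loop cFDR oracle
cfdr_oracle <- function(p1, p2) {
  n <- length(p1)
  vapply(seq_len(n), function(i) {
    n2 <- sum(p2 <= p2[i])
    n12 <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(1, p1[i] * n2 / n12)
  }, numeric(1))
}

# second implementation of the windowed pruning procedure, coded against a
# precomputed full r-squared matrix rather than per-window recomputation
oracle_prune <- function(panel, pvals = NULL, window = 50, step = 5, r2_max = 0.2) {
  info <- attr(panel, "snp_info")
  M <- suppressWarnings(cor(unclass(panel), use = "pairwise.complete.obs"))^2
  M[!is.finite(M)] <- 0
  kept_all <- character(0)
  pass <- function(k, by) {
    changed <- FALSE
    s <- 1
    while (s <= length(k)) {
      repeat {
        win <- k[s:min(s + window - 1, length(k))]
        if (length(win) < 2) break
        hit <- NULL
        for (i in seq_len(length(win) - 1)) {
          for (j in (i + 1):length(win)) {
            if (M[win[i], win[j]] > r2_max) { hit <- c(i, j); break }
          }
          if (!is.null(hit)) break
        }
        if (is.null(hit)) break
        a <- win[hit[1]]; b <- win[hit[2]]
        drop_id <- if (!is.null(pvals) && !is.na(pvals[a]) && !is.na(pvals[b]) &&
                       pvals[a] != pvals[b]) {
          if (pvals[a] > pvals[b]) a else b
        } else b
        k <- setdiff(k, drop_id)
        changed <- TRUE
      }
      if (s + window - 1 >= length(k)) break
      s <- s + by
    }
    list(k = k, changed = changed)
  }
  for (ch in unique(info$chrom)) {
    k <- info$snp_id[info$chrom == ch]
    repeat {
      repeat {
        r <- pass(k, step); k <- r$k
        if (!r$changed) break
      }
      r <- pass(k, 1); k <- r$k
      if (!r$changed) break
    }
    kept_all <- c(kept_all, k)
  }
  kept_all
}

# small genotype panel with planted LD blocks
toy_panel <- function(n_snps = 12, n_samples = 30, block = 4, r_ld = 0.8,
                      seed = 1, chrom = "1") {
  set.seed(seed)
  z <- matrix(0, n_samples, n_snps)
  for (b0 in seq(1, n_snps, by = block)) {
    cols <- b0:min(b0 + block - 1, n_snps)
    e <- matrix(rnorm(n_samples * length(cols)), n_samples)
    for (j in seq_along(cols)) {
      z[, cols[j]] <- if (j == 1) e[, j]
        else r_ld * z[, cols[j - 1]] + sqrt(1 - r_ld^2) * e[, j]
    }
  }
  maf <- runif(n_snps, 0.2, 0.5)
  dos <- sweep(z, 2, qnorm(maf), `<`) +
    sweep(matrix(rnorm(n_samples * n_snps), n_samples), 2, qnorm(maf), `<`)
  colnames(dos) <- sprintf("snp%03d", seq_len(n_snps))
  genotype_panel(dos, tibble::tibble(
    snp_id = colnames(dos), chrom = chrom,
    pos = as.integer(seq(1000, by = 1000, length.out = n_snps))
  ))
}

# no retained pair with r2 above the ceiling inside any positional window
assert_pruned_clean <- function(panel, kept, window = 50, r2_max = 0.2) {
  info <- attr(panel, "snp_info")
  info <- info[info$snp_id %in% kept, , drop = FALSE]
  ok <- TRUE
  for (ch in unique(info$chrom)) {
    ids <- info$snp_id[info$chrom == ch]
    if (length(ids) < 2) next
    for (s in seq_len(max(1, length(ids) - 1))) {
      win <- ids[s:min(s + window - 1, length(ids))]
      if (length(win) < 2) next
      M <- suppressWarnings(cor(unclass(panel)[, win], use = "pairwise.complete.obs"))^2
      M[!is.finite(M)] <- 0
      diag(M) <- 0
      if (max(M) > r2_max) ok <- FALSE
    }
  }
  ok
}

# nominal -log10 p of a Q-Q stratum at a given empirical quantile
qq_deflection_at <- function(qq, xout = 2) {
  defl <- vapply(split(qq, qq$threshold), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    approx(rev(d$empirical), rev(d$nominal), xout = xout, ties = "ordered")$y
  }, numeric(1))
  defl[order(as.numeric(names(defl)), decreasing = TRUE)]
}
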