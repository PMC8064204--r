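VALID_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(COMPLEMENT[x])

is_palindromic <- function(a, b) complement_allele(a) == b

#' @noRd
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  n <- suppressWarnings(as.numeric(x))
  n[toupper(x) == "X"] <- 23
  n[toupper(x) == "Y"] <- 24
  n[toupper(x) %in% c("MT", "M")] <- 25
  n
}

# clamp p = 0 to the smallest positive double (needed for -log10 transforms);
# counts clamped values so callers can log them
clamp_pvals <- function(p) {
  n0 <- sum(p == 0, na.rm = TRUE)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  if (n0 > 0) {
    inform(paste0(n0, " p-value(s) of exactly 0 clamped to the smallest positive double"))
  }
  p
}

check_prob <- function(x, name = "alpha") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    abort(paste0("`", name, "` must lie strictly inside (0, 1)"))
  }
  invisible(x)
}
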