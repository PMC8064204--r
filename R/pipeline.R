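#' Assemble and validate a pipeline run configuration
#'
#' Collects the file paths and parameters of a full cross-trait run. Paths
#' are checked at validation time; parameters are checked against their
#' documented ranges.
#'
#' @param trait1,trait2 Summary-statistics TSV paths (trait 1 is principal).
#' @param genotypes,snp_info Genotype-panel TSV paths ([read_genotype_panel()]).
#' @param cpg_catalog Path to a CpG-SNP id list (one per line), or `NULL` to
#'   skip CpG filtering.
#' @param known_ids Optional path to a known-loci id list for novelty flags.
#' @param qtl_table Optional path to a QTL annotation TSV (columns `snp_id`,
#'   `qtl_class`, `target`, `tissue`, `p`).
#' @param outdir Output directory.
#' @param labels Character pair of trait labels.
#' @param strata Conditional-trait stratum thresholds.
#' @param prune List `window`, `step`, `r2` for LD pruning.
#' @param alphas cFDR significance thresholds.
#' @param mr List `p_threshold`, `r2`, `action`, `n_boot`, `seed` for the MR
#'   stage.
#' @param dialect1,dialect2 Column dialects for the two inputs.
#' @return A validated `run_config` list.
#' @export
run_config <- function(trait1, trait2, genotypes, snp_info,
                       cpg_catalog = NULL, known_ids = NULL, qtl_table = NULL,
                       outdir = tempfile("pleiocfdr_run_"),
                       labels = c("trait1", "trait2"),
                       strata = c(1, 0.1, 0.01, 0.001),
                       prune = list(window = 50, step = 5, r2 = 0.2),
                       alphas = c(0.05, 0.01),
                       mr = list(p_threshold = 5e-8, r2 = 0.001, action = 2,
                                 n_boot = 1000, seed = 20200527),
                       dialect1 = sumstats_dialect(
                         snp_id = "snp_id", chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele", other_allele = "other_allele",
                         eaf = "eaf", beta = "beta", se = "se", pval = "pval"),
                       dialect2 = dialect1) {
  paths <- c(trait1 = trait1, trait2 = trait2, genotypes = genotypes,
             snp_info = snp_info, cpg_catalog = cpg_catalog,
             known_ids = known_ids, qtl_table = qtl_table)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    abort(paste0("config path(s) do not exist: ", paste(missing, collapse = ", ")))
  }
  if (prune$window <= 1 || prune$step < 1 || prune$r2 <= 0 || prune$r2 > 1) {
    abort("invalid prune parameters")
  }
  check_prob(alphas, "alphas")
  check_strata(strata)
  structure(
    list(trait1 = trait1, trait2 = trait2, genotypes = genotypes,
         snp_info = snp_info, cpg_catalog = cpg_catalog, known_ids = known_ids,
         qtl_table = qtl_table, outdir = outdir, labels = labels,
         strata = strata, prune = prune, alphas = alphas, mr = mr,
         dialect1 = dialect1, dialect2 = dialect2),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  fix <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  for (k in c("trait1", "trait2", "genotypes", "snp_info", "cpg_catalog",
              "known_ids", "qtl_table")) {
    if (!is.null(y[[k]])) y[[k]] <- fix(y[[k]])
  }
  do.call(run_config, y)
}

#' Run the full cross-trait cFDR + MR pipeline
#'
#' Executes merge, CpG filtering, LD pruning, stratified Q-Q and
#' fold-enrichment curves, per-SNP cFDR/ccFDR with significance and novelty
#' calls, the bi-directional MR suite, and optional QTL annotation. All
#' stage outputs are written as TSV to the configured output directory, with
#' a row-count ledger recording how many SNPs each stage dropped. The run is
#' deterministic given the config (the only randomness, the MR bootstrap,
#' is seeded from the config).
#'
#' @param config A `run_config` (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list: `cfdr` (a `cfdr_result`), `qq`, `enrichment`
#'   (both orderings), `manhattan`, `mr` (bi-directional estimate table),
#'   `annotated` (if a QTL table was given), `counts` (stage row counts) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  t1 <- read_sumstats(config$trait1, config$dialect1, trait_label = config$labels[1])
  t2 <- read_sumstats(config$trait2, config$dialect2, trait_label = config$labels[2])
  geno <- read_genotype_panel(config$genotypes, config$snp_info)
  catalog <- if (!is.null(config$cpg_catalog)) read_cpg_catalog(config$cpg_catalog)
  known <- if (!is.null(config$known_ids)) read_cpg_catalog(config$known_ids) else character(0)

  counts <- list(trait1 = nrow(t1), trait2 = nrow(t2))
  panel <- merge_traits(t1, t2, catalog = catalog)
  counts$merged <- nrow(panel)
  if (!is.null(catalog)) panel <- filter_cpg(panel, catalog)
  counts$cpg_filtered <- nrow(panel)

  geno_sub <- geno[, intersect(panel_info(geno)$snp_id, panel$snp_id), drop = FALSE]
  pr <- indep_pairwise(geno_sub, pvals = setNames(panel$p1, panel$snp_id),
                       window = config$prune$window, step = config$prune$step,
                       r2_max = config$prune$r2)
  panel <- panel[panel$snp_id %in% pr$kept, , drop = FALSE]
  counts$pruned <- nrow(panel)

  res <- cfdr_analyse(panel, alphas = config$alphas, known_ids = known, geno = geno_sub)
  qq12 <- conditional_qq(panel, config$strata, principal = "p1")
  qq21 <- conditional_qq(panel, config$strata, principal = "p2")
  fe12 <- fold_enrichment(panel, config$strata, principal = "p1")
  fe21 <- fold_enrichment(panel, config$strata, principal = "p2")
  man <- manhattan_data(res, value = "ccfdr", alpha = config$alphas[1])
  counts$sig05 <- sum(res$sig05)
  counts$pleio05 <- sum(res$pleio05)

  mr_tbl <- run_bidirectional(t1, t2, geno,
                              p_threshold = config$mr$p_threshold,
                              r2_max = config$mr$r2, action = config$mr$action,
                              n_boot = config$mr$n_boot, seed = config$mr$seed)

  annotated <- NULL
  if (!is.null(config$qtl_table)) {
    qtl <- readr::read_tsv(config$qtl_table, col_types = readr::cols(), progress = FALSE)
    annotated <- annotate_qtl(res, qtl)
  }

  files <- c(
    cfdr = file.path(config$outdir, "cfdr_results.tsv"),
    qq = file.path(config$outdir, "conditional_qq.tsv"),
    enrichment = file.path(config$outdir, "fold_enrichment.tsv"),
    manhattan = file.path(config$outdir, "manhattan.tsv"),
    mr = file.path(config$outdir, "mr_results.tsv"),
    counts = file.path(config$outdir, "stage_counts.tsv")
  )
  readr::write_tsv(tibble::as_tibble(res), files[["cfdr"]], progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(`1|2` = qq12, `2|1` = qq21, .id = "ordering"),
                   files[["qq"]], progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(`1|2` = fe12, `2|1` = fe21, .id = "ordering"),
                   files[["enrichment"]], progress = FALSE)
  readr::write_tsv(tibble::as_tibble(man), files[["manhattan"]], progress = FALSE)
  readr::write_tsv(mr_tbl, files[["mr"]], progress = FALSE)
  readr::write_tsv(tibble::enframe(unlist(counts), "stage", "n_snps"),
                   files[["counts"]], progress = FALSE)
  if (!is.null(annotated)) {
    files[["annotated"]] <- file.path(config$outdir, "cfdr_annotated.tsv")
    readr::write_tsv(annotated, files[["annotated"]], progress = FALSE)
  }

  invisible(list(cfdr = res, qq = list(`1|2` = qq12, `2|1` = qq21),
                 enrichment = list(`1|2` = fe12, `2|1` = fe21),
                 manhattan = man, mr = mr_tbl, annotated = annotated,
                 counts = counts, files = files))
}

QTL_CLASSES <- c("eQTL", "meQTL", "metaQTL")

#' Annotate cFDR results with QTL memberships
#'
#' Left-joins one or more QTL annotation tables (columns `snp_id`,
#' `qtl_class` in `{eQTL, meQTL, metaQTL}`, plus free-form `target`,
#' `tissue`, `p`) onto the result and derives per-SNP membership flags
#' `has_eqtl`, `has_meqtl`, `has_metaqtl` and the combined `any_qtl`.
#'
#' @param result A `cfdr_result` tibble.
#' @param tables A QTL annotation tibble, or a list of them.
#' @return The result tibble with the four flag columns appended.
#' @export
annotate_qtl <- function(result, tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  qtl <- dplyr::bind_rows(tables)
  if (nrow(qtl) > 0 && any(!qtl$qtl_class %in% QTL_CLASSES)) {
    abort(paste0("unknown qtl_class value(s): ",
                 paste(unique(setdiff(qtl$qtl_class, QTL_CLASSES)), collapse = ", ")))
  }
  flag <- function(class) result$snp_id %in% qtl$snp_id[qtl$qtl_class == class]
  out <- dplyr::mutate(
    tibble::as_tibble(result),
    has_eqtl = flag("eQTL"),
    has_meqtl = flag("meQTL"),
    has_metaqtl = flag("metaQTL"),
    any_qtl = .data$has_eqtl | .data$has_meqtl | .data$has_metaqtl
  )
  out
}

#' Render the standard figure set for a pipeline run
#'
#' Writes the stratified Q-Q, fold-enrichment, and conjunction Manhattan
#' figures (the latter with the `-log10(0.05) = 1.301` reference line) for a
#' [run_pipeline()] bundle. Figures are deterministic given the bundle.
#'
#' @param bundle The list returned by [run_pipeline()].
#' @param outdir Output directory for the figures.
#' @param format `"png"` or `"svg"` (svg requires the svglite package; falls
#'   back to png).
#' @return Named vector of figure paths, invisibly.
#' @export
render_plots <- function(bundle, outdir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (format == "svg" && !requireNamespace("svglite", quietly = TRUE)) {
    warn("svglite not installed; writing png instead")
    format <- "png"
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    qq = file.path(outdir, paste0("conditional_qq.", format)),
    enrichment = file.path(outdir, paste0("fold_enrichment.", format)),
    manhattan = file.path(outdir, paste0("manhattan.", format))
  )
  ggplot2::ggsave(paths[["qq"]], plot_conditional_qq(bundle$qq[["1|2"]]),
                  width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(paths[["enrichment"]], plot_fold_enrichment(bundle$enrichment[["1|2"]]),
                  width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(paths[["manhattan"]], plot_manhattan(bundle$manhattan),
                  width = 9, height = 4, dpi = 150)
  invisible(paths)
}
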