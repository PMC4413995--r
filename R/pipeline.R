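#' Synthesize gene models for a simulated cohort
#'
#' Places one gene inside a fraction of the planted regions (covering most
#' of the region, class copied from the region so OR regions carry OR
#' genes) plus diploid background genes outside any region — enough
#' structure to exercise annotation and partitioning end to end.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param frac_genic fraction of planted regions that receive a gene.
#' @param n_background diploid background genes.
#' @param seed integer seed.
#' @return gene data.frame `chrom`, `start`, `end`, `name`, `class`.
#' @export
synth_gene_models <- function(cohort, frac_genic = 0.6,
                              n_background = 50, seed = 1L) {
  set.seed(seed)
  reg <- cohort$regions
  genic <- sort(sample(nrow(reg), round(frac_genic * nrow(reg))))
  genes <- do.call(rbind, lapply(genic, function(i) {
    w <- reg$end[i] - reg$start[i]
    pad <- round(0.05 * w)
    data.frame(chrom = reg$chrom[i], start = reg$start[i] + pad,
               end = reg$end[i] - pad,
               name = sprintf("%s%04d",
                              ifelse(reg$class[i] == "OR", "OR", "GENE"), i),
               class = as.character(reg$class[i]))
  }))
  grid <- cohort$grid
  free <- setdiff(seq_len(nrow(grid)), bins_in_regions(grid, reg))
  bg <- sort(sample(free, min(n_background, length(free))))
  genes <- rbind(genes, data.frame(
    chrom = grid$chrom[bg], start = grid$start[bg],
    end = grid$start[bg] + 800,
    name = sprintf("BG%04d", seq_along(bg)), class = "nonOR"))
  genes[order(genes$chrom, genes$start), ]
}

#' Default pipeline configuration
#'
#' @param out_dir run directory for artifacts.
#' @param simulate list of [simulate_cohort()] arguments (ignored when a
#'   cohort is passed to [run_pipeline()] directly).
#' @param thresholds named list overriding any of: `bin_size` 1000,
#'   `min_unmasked` 300, `seed_cn` 2.5, `min_bins` 6, `sd` 0.7,
#'   `overlap` 0.70, `cnd` 2.
#' @param groups named list of population groups for group ascertainment.
#' @param bayes `NULL` to skip Bayesian model comparison, or a list with
#'   `steps`, `n_per_step`, `models` (see [sus_constraint_models()]),
#'   `partition` (`"or"`, `"nonor"` or `"all"`) and `max_loci`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("suscape_run_"),
                            simulate = list(),
                            thresholds = list(),
                            groups = list(
                              scrofa = c("Europe", "China", "Sumatra"),
                              isea = c("Sbar", "Sver", "Sceb", "Scel")),
                            bayes = NULL,
                            seed = 1L) {
  th <- list(bin_size = 1000, min_unmasked = 300, seed_cn = 2.5,
             min_bins = 6, sd = 0.7, overlap = 0.70, cnd = 2)
  th[names(thresholds)] <- thresholds
  if (any(vapply(th, function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop("all thresholds must be positive numbers")
  structure(list(out_dir = out_dir, simulate = simulate, thresholds = th,
                 groups = groups, bayes = bayes, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Executes simulate -> depth-to-CN -> CNVR ascertainment -> gene
#' annotation and OR partitioning -> CND/SNP distances and trees ->
#' optional Bayesian model comparison, writing all artifacts and a
#' manifest into the run directory. Identical config and seed reproduce
#' byte-identical interval outputs. When `genes` is `NULL` and the cohort
#' is simulated, gene models are synthesized; passing `genes = NA` skips
#' annotation (with a warning) while still producing CNVR-ALL results.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built [simulate_cohort()] object.
#' @param genes optional gene data.frame (or path to a 5-column BED);
#'   `NA` to skip annotation.
#' @return list with all stage results (`cohort`, `cn`, `cnvrs`,
#'   `gene_table`, `partitions`, `rates`, `trees`, `groups`, `bayes`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         genes = NULL) {
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[suscape] ", msg)
  }

  ## stage: simulate
  if (is.null(cohort)) {
    args <- config$simulate
    args$seed <- args$seed %||% config$seed
    cohort <- do.call(simulate_cohort, args)
    note("simulate: %d bins, %d planted regions, %d individuals",
         nrow(cohort$grid), nrow(cohort$regions), ncol(cohort$depth))
  }
  grid <- cohort$grid
  pops <- cohort$populations
  write_bed(cohort$genome$mask, out("mask.bed"))
  write_bed(cohort$seed_regions, out("seed_regions.bed"))
  ape::write.tree(cohort$tree$phylo, out("species_tree.nwk"))

  ## stage: cn
  cn_mat <- matrix(NA_real_, nrow(grid), length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    idx <- which(cohort$ind_pop == p)
    res <- population_cn(cohort$depth[, idx, drop = FALSE], grid,
                         cohort$seed_regions)
    cn_mat[, p] <- res$cn
    write_track_tsv(grid, res$cn, out(paste0("cn_", p, ".tsv")))
  }
  note("cn: estimated CN for %d populations", length(pops))

  ## stage: cnvr
  cnvrs <- call_cnvrs(cn_mat, grid, seed_threshold = th$seed_cn,
                      min_bins = th$min_bins, sd_threshold = th$sd)
  note("cnvr: %d CNVRs ascertained", nrow(cnvrs$regions))
  bed <- cbind(cnvrs$regions[, c("chrom", "start", "end")],
               name = sprintf("cnvr%04d", seq_len(nrow(cnvrs$regions))),
               sd = round(cnvrs$regions$sd, 4))
  write_bed(bed, out("cnvrs.bed"))
  write.table(cbind(bed, round(cnvrs$cn, 4)), out("cnvr_cn_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: annotate
  gene_table <- NULL
  partitions <- NULL
  if (is.null(genes)) genes <- synth_gene_models(cohort,
                                                 seed = config$seed)
  if (length(genes) == 1 && is.na(genes)) {
    warning("no gene models supplied: annotation and OR/non-OR ",
            "partitioned analyses skipped; CNVR-ALL results produced")
    note("annotate: skipped (no gene models)")
  } else {
    if (is.character(genes))
      genes <- read_bed(genes, extra_cols = c("name", "class"))
    gene_table <- overlap_genes(cnvrs, genes, min_frac = th$overlap)
    partitions <- partition_by_class(cnvrs, gene_table)
    note("annotate: %d genes in CNVRs (OR %d / nonOR %d CNVRs)",
         nrow(gene_table), partitions$counts[["or"]],
         partitions$counts[["nonor"]])
    write.table(gene_table, out("gene_cn.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## stage: distances + trees (individual-level CND, per partition)
  ind_cnvr_cn <- score_regions(cnvrs$regions,
                               ind_cn_matrix(cohort, grid), grid)$cn
  sets <- list(all = seq_len(nrow(cnvrs$regions)))
  if (!is.null(partitions)) {
    sets$or <- partitions$or
    sets$nonor <- partitions$nonor
  }
  snp <- snp_rate(cohort$genotypes)
  trees <- list()
  rates <- list(snp = snp)
  for (nm in names(sets)) {
    idx <- sets[[nm]]
    if (length(idx) < 1) next
    cnd <- cnd_rate(binary_cnd(ind_cnvr_cn[idx, , drop = FALSE],
                               threshold = th$cnd), length(idx))
    rates[[paste0("cnd_", nm)]] <- cnd
    write_phylip_dist(cnd, out(paste0("cnd_", nm, ".phylip.dist")))
    trees[[paste0("nj_", nm)]] <- nj_tree(unclass(cnd))
  }
  trees$nj_snp <- nj_tree(unclass(snp))
  trees$cluster <- cn_cluster(cnvrs$cn)
  for (nm in names(trees))
    ape::write.tree(trees[[nm]], out(paste0(nm, ".nwk")))
  ratio <- tryCatch(rate_ratio(rates$cnd_all, snp), error = function(e) NULL)
  if (!is.null(ratio))
    note("rates: mean CND/SNP ratio %.2f (min %.2f, max %.2f)",
         ratio$mean, ratio$min, ratio$max)

  ## stage: group ascertainment
  groups <- NULL
  if (length(config$groups) >= 2) {
    groups <- lapply(config$groups, function(g)
      group_ascertain(cn_mat, grid, g, seed_threshold = th$seed_cn,
                      min_bins = th$min_bins, sd_threshold = th$sd))
    cmp <- compare_groups(groups[[1]], groups[[2]])
    note("groups: %s=%d, %s=%d CNVRs, shared %d",
         names(groups)[1], nrow(groups[[1]]$regions),
         names(groups)[2], nrow(groups[[2]]$regions), cmp$n_shared_a)
    groups$comparison <- cmp
  }

  ## stage: bayes (optional)
  bayes <- NULL
  if (!is.null(config$bayes)) {
    b <- config$bayes
    part <- b$partition %||% "all"
    idx <- sets[[part]] %||% sets$all
    disc <- discretize_cn(cnvrs$cn[idx, , drop = FALSE])
    if (!is.null(b$max_loci) && nrow(disc$states) > b$max_loci)
      disc$states <- disc$states[seq_len(b$max_loci), , drop = FALSE]
    write_nexus_standard(disc$states, out("cn_discrete.nex"))
    models <- b$models %||% sus_constraint_models()
    est <- lapply(seq_along(models), function(i)
      stepping_stone_mkv(disc$states, k = disc$k,
                         constraints = models[[i]],
                         steps = b$steps %||% 10,
                         n_per_step = b$n_per_step %||% 200,
                         seed = config$seed + i,
                         model = names(models)[i]))
    names(est) <- names(models)
    bayes <- list(estimates = est, table = compare_models(est))
    write.table(bayes$table, out("model_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("bayes: best model %s",
         bayes$table$model[which.min(bayes$table$delta)])
  }

  ## manifest
  manifest <- c(
    sprintf("suscape version: %s",
            as.character(utils::packageVersion("suscape"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %d", config$seed),
    sprintf("thresholds: %s",
            paste(names(th), unlist(th), sep = "=", collapse = " ")),
    log_lines)
  writeLines(manifest, out("manifest.txt"))

  invisible(list(cohort = cohort, cn = cn_mat, cnvrs = cnvrs,
                 gene_table = gene_table, partitions = partitions,
                 rates = rates, ratio = ratio, trees = trees,
                 groups = groups, bayes = bayes,
                 out_dir = config$out_dir))
}

## individual-level per-bin CN matrix (truth-free: re-estimated from each
## individual's own depth against the population calibration would double
## the runtime; individual CN uses the pooled population calibration)
ind_cn_matrix <- function(cohort, grid) {
  inds <- colnames(cohort$depth)
  out <- matrix(NA_real_, nrow(grid), length(inds),
                dimnames = list(NULL, inds))
  for (p in cohort$populations) {
    idx <- which(cohort$ind_pop == p)
    pooled <- population_cn(cohort$depth[, idx, drop = FALSE], grid,
                            cohort$seed_regions)
    for (i in idx) {
      ## per-individual depth, same GC model + calibration, scaled by the
      ## individual's share of pooled depth
      share <- sum(cohort$depth[, i]) / sum(rowSums(
        cohort$depth[, idx, drop = FALSE]))
      gc_fac <- pooled$depth / pmax(rowSums(
        cohort$depth[, idx, drop = FALSE]), 1e-9)
      corr <- cohort$depth[, i] * gc_fac
      out[, colnames(cohort$depth)[i]] <-
        2 * corr / (pooled$cal$d2 * share)
    }
  }
  out
}
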