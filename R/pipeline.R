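#' Write a TSV with optional comment header
#'
#' @param df data frame.
#' @param path destination.
#' @param header character vector of comment lines (written with a leading
#'   `# `).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV and sample sheet into a count matrix
#'
#' The counts file has the transcript id in the first column and one column
#' per sample; the sample sheet is a TSV with columns `sample, assay,
#' condition, replicate`.
#'
#' @param counts_path,samples_path file paths.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read.table(counts_path, header = TRUE, sep = "\t",
                   comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  samples <- read.table(samples_path, header = TRUE, sep = "\t",
                        comment.char = "#", stringsAsFactors = FALSE)
  count_matrix(K[, samples$sample, drop = FALSE], samples)
}

#' Write a count matrix as counts TSV + sample sheet
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path destinations.
#' @param header optional comment lines for both files.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, samples_path, header = NULL) {
  df <- data.frame(id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path, header = header)
  write_tsv(cm$samples, samples_path, header = header)
  invisible(counts_path)
}

#' Write a transcript annotation as GTF plus biotype sidecar
#'
#' Coordinates are converted back to 1-based closed GTF convention.
#'
#' @param tx a [transcript_table()].
#' @param gtf_path,biotype_path destinations.
#' @return `gtf_path`, invisibly.
#' @export
write_annotation <- function(tx, gtf_path, biotype_path) {
  attrs <- sprintf('transcript_id "%s"; transcript_biotype "%s";',
                   tx$id, tx$biotype)
  gtf <- data.frame(tx$chrom, "dsRNAtools", "transcript", tx$start + 1L,
                    tx$end, ".", tx$strand, ".", attrs)
  write.table(gtf, gtf_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(tx$id, tx$biotype), biotype_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(gtf_path)
}

#' Assemble a pipeline run configuration
#'
#' @param outdir output directory for all artifacts.
#' @param sim a [sim_config()] describing the synthetic experiment.
#' @param alpha adjusted-p significance threshold.
#' @param lfc_min minimum absolute log2 fold change for distribution calls.
#' @param min_overlap_fraction pairing threshold for [find_pairs()].
#' @param count_threshold low-count filter threshold.
#' @param normalization coverage-profile normalization mode.
#' @param seed run seed; overrides `sim$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, sim = sim_config(), alpha = 0.05,
                       lfc_min = 0, min_overlap_fraction = 0.5,
                       count_threshold = 40,
                       normalization = c("max", "sum", "none"),
                       seed = sim$seed) {
  normalization <- match.arg(normalization)
  stopifnot(alpha > 0, alpha <= 1, lfc_min >= 0,
            min_overlap_fraction > 0, min_overlap_fraction <= 1)
  sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, sim = sim, alpha = alpha, lfc_min = lfc_min,
              min_overlap_fraction = min_overlap_fraction,
              count_threshold = count_threshold,
              normalization = normalization, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `sim` key holds
#' [sim_config()] fields.
#'
#' @param path YAML file.
#' @param outdir optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  y$sim <- sim
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(run_config, y)
}

# stable short hash of the configuration (for artifact headers); the output
# location is excluded so identical analyses hash identically anywhere
.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "outdir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], file = tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}

.artifact_header <- function(cfg) {
  c(paste0("dsRNAtools ", as.character(packageVersion("dsRNAtools"))),
    paste0("config_hash=", .config_hash(unclass(cfg))),
    paste0("seed=", cfg$seed))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> pair -> enrich (fractionation, J2, stress) -> classify ->
#' propensity groups -> coverage profiles -> DMS deltas -> integration
#' report. Every artifact is a TSV under `cfg$outdir` carrying a comment
#' header with the package version, a hash of the configuration, and the
#' seed; identical configurations produce byte-identical artifacts. A
#' machine-readable `manifest.json` lists the artifacts. Stage failures
#' abort with a stage-named error.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results (`sim`, `pairs`,
#'   `enrichment`, `calls`, `groups`, `profiles`, `dms`, `report`) and the
#'   artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .artifact_header(cfg)
  paths <- list()
  art <- function(name) {
    paths[[name]] <<- file.path(cfg$outdir, paste0(name, ".tsv"))
    paths[[name]]
  }

  sim <- stage("simulate", simulate_experiment(cfg$sim))
  stage("simulate", {
    write_annotation(sim$annotation, file.path(cfg$outdir, "annotation.gtf"),
                     file.path(cfg$outdir, "biotypes.tsv"))
    write_tsv(sim$truth, art("truth"), hdr)
    for (a in names(sim$counts))
      write_counts(sim$counts[[a]],
                   file.path(cfg$outdir, paste0("counts_", a, ".tsv")),
                   file.path(cfg$outdir, paste0("samples_", a, ".tsv")), hdr)
  })

  pairs <- stage("pair",
    find_pairs(sim$annotation, min_fraction = cfg$min_overlap_fraction))
  stage("pair", write_pairs(pairs, art("pairs"), hdr))

  enr <- stage("enrich", list(
    fractionation = enrichment_test(sim$counts$fractionation,
                                    c("cytoplasm", "total"),
                                    cfg$count_threshold),
    j2 = enrichment_test(sim$counts$j2, c("J2_eluate", "J2_unbound"),
                         cfg$count_threshold),
    stress = enrichment_test(sim$counts$stress, c("stress", "control"),
                             cfg$count_threshold)))
  stage("enrich", for (nm in names(enr))
    write_tsv(as.data.frame(enr[[nm]]), art(paste0("enrichment_", nm)), hdr))

  calls <- stage("classify", list(
    fractionation = classify_distribution(enr$fractionation, cfg$alpha,
                                          cfg$lfc_min),
    j2 = classify_distribution(enr$j2, cfg$alpha, cfg$lfc_min,
                               labels = c("enriched", "depleted"))))
  groups <- stage("classify",
    data.frame(id = sim$rnai$id,
               group = propensity_group(sim$rnai$log2_ratio)))
  stage("classify", {
    for (nm in names(calls))
      write_tsv(calls[[nm]], art(paste0("calls_", nm)), hdr)
    write_tsv(groups, art("propensity_groups"), hdr)
  })

  profiles <- stage("coverage", {
    prof <- t(vapply(seq_len(nrow(sim$annotation)), function(i)
      gene_body_profile(sim$coverage, sim$annotation[i, ]), numeric(100)))
    aggregate_by_class(prof, sim$annotation, normalize = cfg$normalization)
  })
  stage("coverage", {
    agg <- do.call(rbind, lapply(names(profiles), function(cl)
      data.frame(class = cl, t(profiles[[cl]]$profile))))
    colnames(agg) <- c("class", paste0("bin_", seq_len(100)))
    write_tsv(agg, art("coverage_profiles"), hdr)
  })

  dms <- stage("dms", {
    d <- reactivity_delta_all(sim$reactivity$wt, sim$reactivity$dbp2d)
    g <- groups$group[match(d$id, groups$id)]
    list(deltas = d, by_group = delta_by_propensity(d$delta, g))
  })
  stage("dms", {
    write_tsv(dms$deltas, art("dms_deltas"), hdr)
    write_tsv(dms$by_group, art("dms_by_group"), hdr)
  })

  report <- stage("report", {
    bt <- sim$annotation$biotype[match(enr$fractionation$id,
                                       sim$annotation$id)]
    grp <- ifelse(bt == "mRNA", "mRNA",
                  ifelse(bt %in% .LNC_CLASSES, "asRNA", bt))
    dist_pct <- distribution_percentages(calls$fractionation, grp)
    j2_cyto <- cytoplasmic_fraction_of_enriched(calls$j2,
                                                calls$fractionation,
                                                enriched_label = "enriched")
    truth <- sim$truth
    est <- enr$fractionation
    t_idx <- est$tested
    rho <- spearman(truth$pi_ds[match(est$id[t_idx], truth$id)],
                    est$log2fc[t_idx])
    ratio <- setNames(truth$mu[match(pairs$antisense_id, truth$id)] /
                      truth$mu[match(pairs$sense_id, truth$id)],
                      pairs$sense_id)
    mfc <- est$log2fc[est$tested & est$id %in% sim$annotation$id[
      sim$annotation$biotype == "mRNA"]]
    names(mfc) <- est$id[est$tested & est$id %in% sim$annotation$id[
      sim$annotation$biotype == "mRNA"]]
    ratio_loc <- asrna_ratio_localization(ratio, mfc)
    stress_pct <- stress_asrna_fraction(
      enr$stress[enr$stress$id %in% pairs$sense_id, ],
      enr$stress[enr$stress$id %in% pairs$antisense_id, ],
      pairs, cfg$alpha)
    list(distribution_percentages = dist_pct,
         j2_enriched_cytoplasmic_pct = j2_cyto,
         propensity_localization_spearman = rho,
         asrna_ratio_localization = ratio_loc,
         stress_asrna_up_pct = stress_pct)
  })
  stage("report", {
    write_tsv(report$distribution_percentages, art("report_distribution"), hdr)
    write_tsv(report$asrna_ratio_localization, art("report_ratio_bins"), hdr)
    write_tsv(data.frame(
      metric = c("j2_enriched_cytoplasmic_pct",
                 "propensity_localization_spearman",
                 "stress_asrna_up_pct"),
      value = c(report$j2_enriched_cytoplasmic_pct,
                report$propensity_localization_spearman,
                report$stress_asrna_up_pct)), art("report_scalars"), hdr)
    manifest <- list(tool = "dsRNAtools",
                     version = as.character(packageVersion("dsRNAtools")),
                     seed = cfg$seed,
                     config_hash = .config_hash(unclass(cfg)),
                     artifacts = sort(list.files(cfg$outdir)))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(sim = sim, pairs = pairs, enrichment = enr, calls = calls,
                 groups = groups, profiles = profiles, dms = dms,
                 report = report, paths = paths))
}
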