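#' Default configuration for an end-to-end demonstration run
#'
#' A single hierarchical list (serialisable as YAML) holding every stage's
#' parameters and seeds. Sizes default to a small but complete demonstration
#' that runs in a few minutes on one CPU.
#'
#' @param seed master seed; per-stage seeds are derived as fixed offsets.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    genus = list(n_pm = 150, n_rt = 150, depth = 7000),
    enterotype = list(iterations = 25, k_range = 2:5),
    quantgen = list(trait = "prevotella"),
    scheme = list(n_replicates = 3),
    shotgun = list(n_mgs = 30, n_per_group = 15, n_planted = 8)
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stage DAG — genus-table generation, rarefaction and
#' diversity, enterotype clustering, study-design phenotype simulation and
#' animal-model REML, the selection-scheme simulation, the response
#' contrasts, and the shotgun differential-abundance/enrichment layer —
#' writing each stage's outputs as TSV under `out_dir` and a manifest (the
#' config, seeds, file checksums and timestamps) as JSON. Stages only
#' communicate through files on disk; the run stops at the first failing
#' stage.
#'
#' @param config configuration list, or path to a YAML file holding one
#'   (see [default_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = tempfile("holosel_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("seed", "genus", "enterotype", "scheme", "shotgun")) {
    if (is.null(config[[key]])) stop("config is missing the required key: ", key)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  files <- character(0)
  log <- function(...) message("[holosel] ", ...)

  log("stage 1/6: synthetic genus table")
  gg <- generate_genus_table(n_pm = config$genus$n_pm, n_rt = config$genus$n_rt,
                             seed = seed + 10L)
  f <- file.path(out_dir, "genus_counts.tsv")
  write_abundance_tsv(gg$table, f); files <- c(files, f)
  utils::write.table(data.frame(sample_id = names(gg$labels), label = gg$labels),
                     file.path(out_dir, "genus_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, file.path(out_dir, "genus_truth.tsv"))

  log("stage 2/6: rarefaction + alpha diversity")
  counts <- read_abundance_tsv(file.path(out_dir, "genus_counts.tsv"), kind = "counts")
  rar <- rarefy(counts, depth = config$genus$depth, seed = seed + 20L)
  f <- file.path(out_dir, "genus_rarefied.tsv")
  write_abundance_tsv(rar, f); files <- c(files, f)
  div <- alpha_diversity(rar)
  f <- file.path(out_dir, "alpha_diversity.tsv")
  utils::write.table(div, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  log("stage 3/6: enterotype clustering")
  rar <- read_abundance_tsv(file.path(out_dir, "genus_rarefied.tsv"), kind = "counts")
  d <- jsd_distance(rar)
  k <- optimal_k(d, k_range = config$enterotype$k_range, seed = seed + 30L)
  ass <- assign_enterotypes(rar, iterations = config$enterotype$iterations,
                            seed = seed + 31L)
  ass$optimal_k <- as.integer(k)
  f <- file.path(out_dir, "enterotypes.tsv")
  utils::write.table(ass, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  log("stage 4/6: study-design phenotypes + animal-model REML")
  gp <- generate_study_phenotypes(seed = seed + 40L)
  f <- file.path(out_dir, "pedigree.tsv")
  utils::write.table(as.data.frame(gp$ped), f, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "0")
  files <- c(files, f)
  f <- file.path(out_dir, "phenotypes.tsv")
  utils::write.table(gp$data, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  ped <- read_pedigree_tsv(file.path(out_dir, "pedigree.tsv"))
  phe <- utils::read.delim(file.path(out_dir, "phenotypes.tsv"), stringsAsFactors = FALSE)
  fml <- stats::reformulate(c("sex", "batch"), response = config$quantgen$trait)
  fit <- animal_reml(fml, phe, ped)
  vc <- data.frame(trait = config$quantgen$trait,
                   sigma2_a = fit$varcomp$a[1, 1], sigma2_c = fit$varcomp$c[1, 1],
                   sigma2_e = fit$varcomp$e[1, 1],
                   h2 = fit$h2[1, 1], h2_se = fit$h2[1, 2],
                   c2 = fit$c2[1, 1], c2_se = fit$c2[1, 2])
  f <- file.path(out_dir, "variance_components.tsv")
  utils::write.table(vc, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  log("stage 5/6: selection-scheme simulation + response contrasts")
  rs <- run_scheme(n_replicates = config$scheme$n_replicates, seed = seed + 50L)
  f <- file.path(out_dir, "trajectory.tsv")
  utils::write.table(rs$summary, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  pop <- simulate_population(seed = seed + 51L)
  sel <- pop$ped$generation %in% c("G1", "G2", "G3")
  resp_data <- data.frame(pop$ped[sel, c("line", "generation", "sex", "batch")],
                          pop$pheno[sel, , drop = FALSE])
  rt <- line_contrasts(resp_data, features = c("prevotella", "treponema", "adg"))
  rt <- rt[order(match(rt$feature, rank_differences(rt))), ]
  f <- file.path(out_dir, "response.tsv")
  utils::write.table(rt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  log("stage 6/6: shotgun layer")
  sf <- generate_shotgun_fixture(n_mgs = config$shotgun$n_mgs,
                                 n_per_group = config$shotgun$n_per_group,
                                 n_planted_pm = config$shotgun$n_planted,
                                 n_planted_rt = config$shotgun$n_planted,
                                 seed = seed + 60L)
  mgs <- mgs_abundance(sf$genes$counts, sf$genes$length_bp, sf$catalog,
                       relative = TRUE)
  da <- diff_abundance(mgs, sf$groups)
  f <- file.path(out_dir, "mgs_diff.tsv")
  utils::write.table(da, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  ko <- ko_abundance(sf$genes$counts, sf$genes$length_bp, sf$gene2ko, relative = TRUE)
  dk <- diff_abundance(ko, sf$groups, cd_min = 0.5)
  hit_ko <- dk$feature[dk$enriched_in != "none"]
  enr <- enrich_pathways(hit_ko, dk$feature, sf$ko2pathway)
  f <- file.path(out_dir, "pathway_enrichment.tsv")
  utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  manifest <- list(config = config,
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   package_version = as.character(utils::packageVersion("holosel")),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(p) list(path = p,
                                                   md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("done: ", out_dir)
  invisible(manifest)
}
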