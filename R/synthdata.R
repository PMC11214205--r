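#' Configuration for the two-enterotype genus-table generator
#'
#' Mean percent profiles of the enterotype-defining genera default to the
#' shotgun-derived group means (Prevotella 44.9 PM / 25.7 RT; Mitsuokella
#' 1.2 / 0.4; Ruminococcus 0.5 / 1.3; Treponema 1.2 / 8.7; Rikenellaceae RC9
#' 1.8 / 5.0); the per-taxon log-scale dispersions are matched to the
#' reported between-animal SDs via the lognormal relation
#' `sdlog^2 = log(1 + CV^2)`. The remaining mass is spread over `n_background`
#' genera with a power-law profile; the RT enterotype receives both more
#' background mass and a flatter power law, which realises the higher alpha
#' diversity of RT animals.
#'
#' @param n_background number of background genera.
#' @param bg_exponent_pm,bg_exponent_rt power-law decay exponents of the
#'   background profile (taxon `i` has mean proportional to `i^-exponent`).
#' @param bg_cv between-sample coefficient of variation of background taxa.
#' @param depth_mean,depth_sd sequencing depth distribution (counts drawn per
#'   sample from a rounded lognormal).
#' @return A list of class `"genus_config"` with `mean_pm`, `mean_rt`
#'   (named percent vectors summing to 100) and `sdlog_pm`, `sdlog_rt`.
#' @export
genus_table_config <- function(n_background = 120, bg_exponent_pm = 1.1,
                               bg_exponent_rt = 0.7, bg_cv = 0.8,
                               depth_mean = 20000, depth_sd = 4000) {
  named <- c("Prevotella", "Mitsuokella", "Ruminococcus", "Treponema",
             "Rikenellaceae_RC9")
  mean_pm <- c(44.9, 1.2, 0.5, 1.2, 1.8)
  mean_rt <- c(25.7, 0.4, 1.3, 8.7, 5.0)
  sd_pm <- c(8.3, 1.2, 0.5, 1.4, 1.1)
  sd_rt <- c(10.0, 0.5, 0.8, 6.5, 2.3)
  names(mean_pm) <- names(mean_rt) <- names(sd_pm) <- names(sd_rt) <- named
  bg <- paste0("Genus_", sprintf("%03d", seq_len(n_background)))
  bg_pm <- seq_len(n_background)^(-bg_exponent_pm)
  bg_rt <- seq_len(n_background)^(-bg_exponent_rt)
  bg_pm <- bg_pm / sum(bg_pm) * (100 - sum(mean_pm))
  bg_rt <- bg_rt / sum(bg_rt) * (100 - sum(mean_rt))
  names(bg_pm) <- names(bg_rt) <- bg
  cv_pm <- c(sd_pm / mean_pm, rep(bg_cv, n_background))
  cv_rt <- c(sd_rt / mean_rt, rep(bg_cv, n_background))
  structure(list(mean_pm = c(mean_pm, bg_pm), mean_rt = c(mean_rt, bg_rt),
                 sdlog_pm = sqrt(log(1 + cv_pm^2)),
                 sdlog_rt = sqrt(log(1 + cv_rt^2)),
                 depth_mean = depth_mean, depth_sd = depth_sd),
            class = "genus_config")
}

#' Generate a two-enterotype genus count table
#'
#' Per sample, a logistic-normal composition is drawn around the
#' enterotype's mean profile (each taxon's mean is multiplied by a mean-one
#' lognormal deviate with the taxon's configured log-dispersion, then the
#' vector is renormalised) and counts are drawn multinomially at the
#' sample's sequencing depth. True labels are returned for oracle use.
#'
#' @param n_pm,n_rt number of PM / RT samples.
#' @param config a [genus_table_config()].
#' @param seed integer seed.
#' @return A list with `table` (an `abundance_table` of counts), `labels`
#'   (named "PM"/"RT" vector) and `config`.
#' @export
generate_genus_table <- function(n_pm = 500, n_rt = 500,
                                 config = genus_table_config(), seed = 1) {
  set.seed(as.integer(seed))
  if (sum(config$mean_pm) > 100 + 1e-8 || sum(config$mean_rt) > 100 + 1e-8) {
    stop("mean profiles must sum to at most 100")
  }
  m <- length(config$mean_pm)
  n <- n_pm + n_rt
  labels <- c(rep("PM", n_pm), rep("RT", n_rt))
  depth <- pmax(1000L, as.integer(round(stats::rlnorm(
    n, log(config$depth_mean) - 0.5 * log(1 + (config$depth_sd / config$depth_mean)^2),
    sqrt(log(1 + (config$depth_sd / config$depth_mean)^2))))))
  counts <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (labels[i] == "PM") { mu <- config$mean_pm; sl <- config$sdlog_pm }
    else { mu <- config$mean_rt; sl <- config$sdlog_rt }
    x <- mu * stats::rlnorm(m, -sl^2 / 2, sl)   # mean-one multiplicative noise
    counts[i, ] <- stats::rmultinom(1, depth[i], x / sum(x))
  }
  dimnames(counts) <- list(sprintf("%s_%04d", labels, seq_len(n)), names(config$mean_pm))
  tab <- abundance_table(counts, kind = "counts")
  list(table = tab, labels = stats::setNames(labels, rownames(counts)),
       config = config)
}

#' Generate a synthetic shotgun fixture (gene counts + MGS catalog + KO maps)
#'
#' Builds a marker-gene count matrix for `n_mgs` metagenomic species with
#' planted PM- and RT-enriched species: per sample, each MGS has a lognormal
#' "true" coverage, multiplied by the planted fold-change in the enriched
#' group; marker-gene counts are Poisson around coverage x gene length (kb)
#' with per-gene-per-sample dropout. Genes are annotated to toy KOs (one KO
#' per block of genes) and KOs to toy pathways, with the KOs of planted MGS
#' concentrated in dedicated pathways so that enrichment is recoverable.
#'
#' @param n_mgs number of metagenomic species.
#' @param markers_per_mgs marker genes per species.
#' @param n_per_group samples per enterotype group.
#' @param n_planted_pm,n_planted_rt planted differentially abundant species.
#' @param fold fold-change of planted species in their enriched group.
#' @param dropout probability a marker gene is missed in a sample.
#' @param genes_per_ko marker genes pooled into one KO.
#' @param seed integer seed.
#' @return A list with `genes` (list: `counts` gene x sample, `length_bp`),
#'   `catalog` (MGS -> marker gene ids), `lineage` (MGS -> genus), `gene2ko`,
#'   `ko2pathway`, `groups` (sample labels) and `truth` (planted enrichment).
#' @export
generate_shotgun_fixture <- function(n_mgs = 40, markers_per_mgs = 100,
                                     n_per_group = 15, n_planted_pm = 12,
                                     n_planted_rt = 12, fold = 4,
                                     dropout = 0.05, genes_per_ko = 20,
                                     seed = 1) {
  set.seed(as.integer(seed))
  stopifnot(n_planted_pm + n_planted_rt <= n_mgs)
  mgs_ids <- sprintf("MGS%03d", seq_len(n_mgs))
  planted_pm <- mgs_ids[seq_len(n_planted_pm)]
  planted_rt <- mgs_ids[n_planted_pm + seq_len(n_planted_rt)]
  n_genes <- n_mgs * markers_per_mgs
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  length_bp <- sample(500:3000, n_genes, replace = TRUE)
  catalog <- stats::setNames(split(gene_ids, rep(mgs_ids, each = markers_per_mgs)), mgs_ids)
  samples <- c(sprintf("PM_%02d", seq_len(n_per_group)),
               sprintf("RT_%02d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("PM", "RT"), each = n_per_group), samples)
  base <- stats::rlnorm(n_mgs, meanlog = 1, sdlog = 0.8)
  counts <- matrix(0L, n_genes, length(samples), dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    cov_mgs <- base * stats::rlnorm(n_mgs, -0.125, 0.5)
    mult <- rep(1, n_mgs)
    if (groups[j] == "PM") mult[mgs_ids %in% planted_pm] <- fold
    else mult[mgs_ids %in% planted_rt] <- fold
    cov_mgs <- cov_mgs * mult
    lam <- rep(cov_mgs, each = markers_per_mgs) * (length_bp / 1000)
    lam <- lam * (stats::runif(n_genes) > dropout)
    counts[, j] <- stats::rpois(n_genes, lam)
  }
  lineage <- data.frame(mgs = mgs_ids,
                        genus = paste0("g__", sprintf("Taxon%02d", ((seq_len(n_mgs) - 1) %/% 2) + 1)),
                        stringsAsFactors = FALSE)
  n_ko <- ceiling(n_genes / genes_per_ko)
  ko_ids <- sprintf("K%05d", seq_len(n_ko))
  gene2ko <- data.frame(gene = gene_ids, ko = rep(ko_ids, each = genes_per_ko)[seq_len(n_genes)],
                        stringsAsFactors = FALSE)
  # pathway design: KOs from planted-PM MGS -> pw_PM, planted-RT -> pw_RT,
  # the rest spread over neutral pathways
  ko_mgs <- rep(mgs_ids, each = markers_per_mgs)[match(gene2ko$gene, gene_ids)]
  ko_main <- tapply(ko_mgs, gene2ko$ko, function(v) v[1])
  pw <- ifelse(ko_main %in% planted_pm, "pw_PM",
               ifelse(ko_main %in% planted_rt, "pw_RT",
                      paste0("pw_neutral_", (seq_along(ko_main) %% 6) + 1)))
  ko2pathway <- data.frame(ko = names(ko_main), pathway = unname(pw),
                           stringsAsFactors = FALSE)
  list(genes = list(counts = counts, length_bp = stats::setNames(length_bp, gene_ids)),
       catalog = catalog, lineage = lineage, gene2ko = gene2ko,
       ko2pathway = ko2pathway, groups = groups,
       truth = list(planted_pm = planted_pm, planted_rt = planted_rt, fold = fold))
}

#' Simulate phenotypes on the published study design without selection
#'
#' Thin wrapper over [simulate_population()] with `select = FALSE`: a
#' random-mating population on the printed four-generation design with known
#' heritabilities, litter effects and genetic correlations, plus injected
#' sex and batch effects — the input for parameter-recovery studies of the
#' animal-model REML machinery.
#'
#' @param scheme a [breeding_scheme()].
#' @param arch a [genetic_architecture()].
#' @param seed integer seed.
#' @return A list with `ped` (a [pedigree()] incl. unphenotyped founders)
#'   and `data` (one row per phenotyped animal: id, sex, batch, litter,
#'   generation, line, one column per trait, enterotype label).
#' @export
generate_study_phenotypes <- function(scheme = breeding_scheme(),
                                      arch = genetic_architecture(),
                                      seed = 1) {
  pop <- simulate_population(scheme, arch, seed = seed, select = FALSE)
  phen <- which(pop$ped$generation != "F")
  data <- data.frame(pop$ped[phen, c("animal", "sex", "batch", "litter",
                                     "generation", "line")],
                     pop$pheno[phen, , drop = FALSE],
                     enterotype = pop$enterotype[phen],
                     stringsAsFactors = FALSE, row.names = NULL)
  list(ped = pedigree(pop$ped[, c("animal", "sire", "dam", "generation", "line", "sex")]),
       data = data, pop = pop)
}
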