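#' Configuration for the synthetic longitudinal study generator
#'
#' Defines the study conditions emulated by [simulate_study()]: a crossover
#' design with 10 subjects sampled 4 times each (Pre/Iso/Post plus one
#' Control collected in a different experiment phase), a 54-genus 16S table,
#' and a 47-metabolite targeted panel set (5 SCFA, 16 BA, 26 AA).
#'
#' The latent model plants known structure so downstream stages have ground
#' truth to recover: a low-abundance keystone genus whose within-subject
#' temporal signal is coupled into `keystone_n_links` metabolites (7 of the
#' `n_da_metabolites` condition-shifted metabolites overlap that linked set,
#' when possible), a bacteria-bacteria hub genus sharing a latent factor with
#' `hub_bb_links` other genera, one extra planted keystone-genus
#' bacteria-bacteria partner, and a dominant high-abundance genus.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param samples_per_subject Samples per subject (default 4).
#' @param n_genera Number of genera (default 54).
#' @param panel_sizes Named integer vector of panel sizes
#'   (default `c(SCFA = 5, BA = 16, AA = 26)`).
#' @param subject_effect_sd SD of subject random intercepts on the latent
#'   scale (default 1).
#' @param ar_coefficient AR(1) coefficient of the within-subject temporal
#'   signal, in `[0, 1)` (default 0.3).
#' @param keystone_genus_index Index of the planted keystone genus (default 50).
#' @param keystone_n_links Number of metabolites coupled to the keystone
#'   latent signal (default 15).
#' @param keystone_effect Coupling coefficient in latent-SD units (default 2,
#'   chosen so planted links show the residual correlation strength,
#'   `|rho| ~ 0.6-0.8`, that a significant association at this sample size
#'   implies; see the vignette).
#' @param dominant_genus_index Index of the genus with elevated mean
#'   log-abundance (default 1).
#' @param hub_genus_index Index of the planted bacteria-bacteria hub (default 30).
#' @param hub_bb_links Number of genera sharing the hub's latent factor
#'   (default 8).
#' @param hub_loading Loading of hub partners on the shared factor (default 0.75).
#' @param n_da_metabolites Number of metabolites given condition-level log2
#'   shifts so the differential stage has true positives (default 10; shift
#'   -2.2 in Pre, and -1.2 in Iso for two of them, vs Control).
#' @param library_size_mean Mean sequencing depth (default 20000).
#' @param n_low_depth_samples Samples forced below 1,000 reads (default 2).
#' @param metabolite_missing_rate Completely-at-random missingness rate for
#'   metabolite cells, in `[0, 1)` (default 0.05).
#' @param noise_sd SD of the Gaussian noise added on the latent scales
#'   (default 0.35).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   studies.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, samples_per_subject = 4, n_genera = 54,
                       panel_sizes = c(SCFA = 5, BA = 16, AA = 26),
                       subject_effect_sd = 1, ar_coefficient = 0.3,
                       keystone_genus_index = 50, keystone_n_links = 15,
                       keystone_effect = 2, dominant_genus_index = 1,
                       hub_genus_index = 30, hub_bb_links = 8, hub_loading = 0.75,
                       n_da_metabolites = 10,
                       library_size_mean = 20000, n_low_depth_samples = 2,
                       metabolite_missing_rate = 0.05, noise_sd = 0.35,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, samples_per_subject = samples_per_subject,
              n_genera = n_genera, panel_sizes = panel_sizes,
              subject_effect_sd = subject_effect_sd, ar_coefficient = ar_coefficient,
              keystone_genus_index = keystone_genus_index,
              keystone_n_links = keystone_n_links, keystone_effect = keystone_effect,
              dominant_genus_index = dominant_genus_index,
              hub_genus_index = hub_genus_index, hub_bb_links = hub_bb_links,
              hub_loading = hub_loading, n_da_metabolites = n_da_metabolites,
              library_size_mean = library_size_mean,
              n_low_depth_samples = n_low_depth_samples,
              metabolite_missing_rate = metabolite_missing_rate,
              noise_sd = noise_sd, seed = as.integer(seed))
  n_metab <- sum(panel_sizes)
  with(cfg, {
    if (n_subjects < 2 || samples_per_subject < 2)
      stop("need at least 2 subjects with 2 samples each")
    if (n_genera < 3) stop("need at least 3 genera")
    if (is.null(names(panel_sizes)) || any(panel_sizes < 1))
      stop("`panel_sizes` must be a named vector of positive counts")
    if (keystone_n_links > n_metab)
      stop("`keystone_n_links` exceeds the number of metabolites")
    if (n_da_metabolites > n_metab)
      stop("`n_da_metabolites` exceeds the number of metabolites")
    if (subject_effect_sd <= 0 || noise_sd <= 0)
      stop("standard deviations must be positive")
    if (ar_coefficient < 0 || ar_coefficient >= 1)
      stop("`ar_coefficient` must lie in [0, 1)")
    if (any(c(keystone_genus_index, dominant_genus_index, hub_genus_index) > n_genera) ||
        any(c(keystone_genus_index, dominant_genus_index, hub_genus_index) < 1))
      stop("genus indices out of range")
    if (hub_bb_links > n_genera - 3)
      stop("`hub_bb_links` too large for the number of genera")
    if (metabolite_missing_rate < 0 || metabolite_missing_rate >= 1)
      stop("`metabolite_missing_rate` must lie in [0, 1)")
    if (n_low_depth_samples > n_subjects * samples_per_subject)
      stop("more low-depth samples than samples")
  })
  structure(cfg, class = "sim_config")
}

# internal: stationary AR(1) series of marginal SD 1
ar1_series <- function(n, phi) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) for (t in 2:n)
    z[t] <- phi * z[t - 1] + stats::rnorm(1, sd = sqrt(1 - phi^2))
  z
}

#' Simulate a paired longitudinal microbiome/metabolome study
#'
#' Generates a genus-level 16S count table, a targeted metabolomics table with
#' missing cells, sample metadata, and the planted ground truth, under the
#' latent model described in the package vignette: per-genus log-abundance =
#' genus mean + subject intercept + AR(1) temporal signal (+ planted factor
#' couplings) + noise, counts drawn multinomially from the per-sample softmax
#' at a negative-binomial library size; per-metabolite log2 abundance =
#' baseline + subject intercept + keystone coupling (planted links) +
#' condition shift (planted DA metabolites) + noise, exponentiated to a
#' positive scale.
#'
#' @param config A [sim_config()].
#' @return A list with elements `microbiome` (count `feature_table`),
#'   `metabolome` (`feature_table` with `NA` for missing cells), `metadata`
#'   (data frame with `Sample`, `Subject`, `Relative_Day`,
#'   `Treatment_Condition`, `Treatment_Group`, `Sex`, `Age`, `total_reads`)
#'   and `truth` (class `ground_truth`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_sub <- cfg$n_subjects
  n_tp <- cfg$samples_per_subject
  n_samp <- n_sub * n_tp
  n_gen <- cfg$n_genera
  n_met <- sum(cfg$panel_sizes)

  subjects <- sprintf("Subj_%02d", seq_len(n_sub))
  genera <- sprintf("Genus_%02d", seq_len(n_gen))
  panels <- rep(names(cfg$panel_sizes), cfg$panel_sizes)
  metabs <- unlist(lapply(names(cfg$panel_sizes), function(p)
    sprintf("%s_%02d", p, seq_len(cfg$panel_sizes[[p]]))))

  ## ---- design: crossover layout with Control in the opposite phase ----
  group <- rep(c("G1", "G2"), length.out = n_sub)
  meta <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    jit <- sample(-2:2, 4, replace = TRUE)
    if (group[s] == "G1") {        # isolated first, control 3 weeks after
      days <- c(0, 6, 12, 33) + c(0, jit[2:4])
      cond <- c("Pre", "Iso", "Post", "Control")
    } else {                       # control ~4 weeks before isolation
      days <- c(0, 28, 34, 40) + c(0, jit[2:4])
      cond <- c("Control", "Pre", "Iso", "Post")
    }
    o <- order(days)
    data.frame(Subject = subjects[s], Relative_Day = days[o],
               Treatment_Condition = cond[o], Treatment_Group = group[s],
               stringsAsFactors = FALSE)
  }))
  meta$Sex <- rep(sample(c("M", "F"), n_sub, replace = TRUE), each = n_tp)
  meta$Age <- rep(sample(1:9, n_sub, replace = TRUE), each = n_tp)
  meta$Sample <- sprintf("%s_D%02d", meta$Subject, meta$Relative_Day)
  meta <- meta[, c("Sample", "Subject", "Relative_Day", "Treatment_Condition",
                   "Treatment_Group", "Sex", "Age")]

  ## ---- latent temporal signals (marginal SD 1 per series) ----
  phi <- cfg$ar_coefficient
  u <- array(0, dim = c(n_samp, n_gen))            # per-genus temporal signal
  f_hub <- numeric(n_samp)                          # shared hub factor
  for (s in seq_len(n_sub)) {
    idx <- which(meta$Subject == subjects[s])
    for (g in seq_len(n_gen)) u[idx, g] <- ar1_series(n_tp, phi)
    f_hub[idx] <- ar1_series(n_tp, phi)
  }
  ks <- cfg$keystone_genus_index
  hub <- cfg$hub_genus_index
  # time-driven shift in keystone activity: Pre samples sit ~0.8 latent-SD
  # lower, so linked metabolites inherit condition contrasts through the
  # coupling itself rather than through independent label noise
  if (cfg$keystone_effect != 0)
    u[, ks] <- u[, ks] - 0.8 * (meta$Treatment_Condition == "Pre")
  w <- cfg$hub_loading
  hub_partners <- integer(0)
  if (cfg$hub_bb_links > 0) {
    pool <- setdiff(seq_len(n_gen), c(ks, hub, cfg$dominant_genus_index))
    hub_partners <- sort(sample(pool, cfg$hub_bb_links))
    u[, hub] <- f_hub
    for (g in hub_partners) u[, g] <- w * f_hub + sqrt(1 - w^2) * u[, g]
  }
  ## one planted keystone bacteria-bacteria partner
  bb_partner <- integer(0)
  if (cfg$keystone_effect != 0) {
    pool <- setdiff(seq_len(n_gen),
                    c(ks, hub, hub_partners, cfg$dominant_genus_index))
    bb_partner <- sample(pool, 1)
    # weaker than the hub loading: the partner should share the keystone's
    # temporal signal without duplicating its metabolite edge profile
    u[, bb_partner] <- 0.5 * u[, ks] + sqrt(1 - 0.25) * u[, bb_partner]
  }
  ## a small mutually-correlated clique (second dense bacteria-bacteria region)
  clique <- integer(0)
  if (cfg$hub_bb_links > 0 && n_gen >= cfg$hub_bb_links + 8) {
    pool <- setdiff(seq_len(n_gen),
                    c(ks, hub, hub_partners, bb_partner, cfg$dominant_genus_index))
    clique <- sort(sample(pool, 3))
    f_cl <- numeric(n_samp)
    for (s in seq_len(n_sub))
      f_cl[meta$Subject == subjects[s]] <- ar1_series(n_tp, phi)
    for (g in clique) u[, g] <- 0.8 * f_cl + sqrt(1 - 0.8^2) * u[, g]
  }

  ## ---- microbiome counts ----
  mu_g <- stats::rnorm(n_gen, 0, 1)
  mu_g[cfg$dominant_genus_index] <- 3.5   # dominant genus (~1/4 of reads)
  mu_g[ks] <- 0                           # keystone rare (~1% on average)
  b_g <- matrix(stats::rnorm(n_sub * n_gen, 0, cfg$subject_effect_sd),
                n_sub, n_gen)
  lam <- matrix(0, n_samp, n_gen)
  for (i in seq_len(n_samp)) {
    s <- match(meta$Subject[i], subjects)
    lam[i, ] <- mu_g + b_g[s, ] + u[i, ] +
      stats::rnorm(n_gen, 0, cfg$noise_sd)
  }
  lib <- stats::rnbinom(n_samp, mu = cfg$library_size_mean, size = 15)
  lib <- pmax(lib, 2000L)
  if (cfg$n_low_depth_samples > 0) {
    low <- sample(n_samp, cfg$n_low_depth_samples)
    lib[low] <- sample(200:999, cfg$n_low_depth_samples, replace = TRUE)
  }
  counts <- t(vapply(seq_len(n_samp), function(i) {
    p <- exp(lam[i, ] - max(lam[i, ]))
    as.numeric(stats::rmultinom(1, lib[i], p / sum(p)))
  }, numeric(n_gen)))
  dimnames(counts) <- list(meta$Sample, genera)

  ## ---- metabolome ----
  ks_links <- if (cfg$keystone_effect == 0) integer(0) else
    sort(sample(n_met, cfg$keystone_n_links))
  n_da <- cfg$n_da_metabolites
  da_idx <- integer(0)
  if (n_da > 0) {
    n_overlap <- min(7, n_da, length(ks_links))
    da_idx <- sort(c(sample(ks_links, n_overlap),
                     if (n_da > n_overlap)
                       sample(setdiff(seq_len(n_met), ks_links), n_da - n_overlap)))
  }
  iso_idx <- if (length(da_idx) >= 2) sort(sample(da_idx, 2)) else da_idx
  beta_m <- stats::rnorm(n_met, 5, 2)
  b_m <- matrix(stats::rnorm(n_sub * n_met, 0, cfg$subject_effect_sd),
                n_sub, n_met)
  log2_met <- matrix(0, n_samp, n_met)
  for (i in seq_len(n_samp)) {
    s <- match(meta$Subject[i], subjects)
    x <- beta_m + b_m[s, ] + stats::rnorm(n_met, 0, cfg$noise_sd)
    x[ks_links] <- x[ks_links] + cfg$keystone_effect * u[i, ks]
    if (meta$Treatment_Condition[i] == "Pre") x[da_idx] <- x[da_idx] - 2.2
    if (meta$Treatment_Condition[i] == "Iso") x[iso_idx] <- x[iso_idx] - 1.2
    log2_met[i, ] <- x
  }
  met <- 2^log2_met
  if (cfg$metabolite_missing_rate > 0) {
    miss <- matrix(stats::runif(n_samp * n_met) < cfg$metabolite_missing_rate,
                   n_samp, n_met)
    met[miss] <- NA_real_
  }
  dimnames(met) <- list(meta$Sample, metabs)

  truth <- structure(list(
    planted_bact_met_edges = data.frame(genus = rep(genera[ks], length(ks_links)),
                                        metabolite = metabs[ks_links],
                                        stringsAsFactors = FALSE),
    planted_bact_bact_edges = data.frame(
      genus_1 = genera[c(rep(hub, length(hub_partners)),
                         rep(ks, length(bb_partner)),
                         if (length(clique)) clique[c(1, 1, 2)])],
      genus_2 = genera[c(hub_partners, bb_partner,
                         if (length(clique)) clique[c(2, 3, 3)])],
      stringsAsFactors = FALSE),
    keystone_genus = genera[ks],
    dominant_genus = genera[cfg$dominant_genus_index],
    hub_genus = genera[hub],
    da_metabolites = metabs[da_idx]), class = "ground_truth")

  list(
    microbiome = feature_table(counts,
                               data.frame(feature = genera, genus = genera,
                                          stringsAsFactors = FALSE),
                               type = "microbiome"),
    metabolome = feature_table(met,
                               data.frame(feature = metabs, panel = panels,
                                          stringsAsFactors = FALSE),
                               type = "metabolome"),
    metadata = meta,
    truth = truth)
}

#' Write planted ground truth to a TSV file
#'
#' The file stores one row per planted edge plus `#`-prefixed header lines for
#' the scalar fields; [read_ground_truth()] round-trips it losslessly.
#'
#' @param truth `ground_truth` object from [simulate_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#keystone_genus\t%s", truth$keystone_genus),
               sprintf("#dominant_genus\t%s", truth$dominant_genus),
               sprintf("#hub_genus\t%s", truth$hub_genus),
               sprintf("#da_metabolites\t%s",
                       paste(truth$da_metabolites, collapse = ";")),
               "edge_type\tfeature_1\tfeature_2"), con)
  bm <- truth$planted_bact_met_edges
  if (nrow(bm)) writeLines(sprintf("bact-met\t%s\t%s", bm$genus, bm$metabolite), con)
  bb <- truth$planted_bact_bact_edges
  if (nrow(bb)) writeLines(sprintf("bact-bact\t%s\t%s", bb$genus_1, bb$genus_2), con)
  invisible(path)
}

#' Read planted ground truth written by [export_ground_truth()]
#'
#' @param path File written by [export_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) {
    x <- sub(paste0("#", key, "\t"), "", hdr[startsWith(hdr, paste0("#", key, "\t"))])
    if (length(x)) x else ""
  }
  body <- lines[!startsWith(lines, "#")][-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  et <- vapply(parts, `[`, "", 1)
  f1 <- vapply(parts, `[`, "", 2)
  f2 <- vapply(parts, `[`, "", 3)
  da <- val("da_metabolites")
  structure(list(
    planted_bact_met_edges = data.frame(genus = f1[et == "bact-met"],
                                        metabolite = f2[et == "bact-met"],
                                        stringsAsFactors = FALSE),
    planted_bact_bact_edges = data.frame(genus_1 = f1[et == "bact-bact"],
                                         genus_2 = f2[et == "bact-bact"],
                                         stringsAsFactors = FALSE),
    keystone_genus = val("keystone_genus"),
    dominant_genus = val("dominant_genus"),
    hub_genus = val("hub_genus"),
    da_metabolites = if (nzchar(da)) strsplit(da, ";", fixed = TRUE)[[1]]
                     else character(0)), class = "ground_truth")
}

#' Write a simulated study to a directory as plain TSV/YAML files
#'
#' Materializes the three study inputs (microbiome counts, metabolite table,
#' sample metadata), the planted ground truth, and the generating
#' configuration.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @param config Optional [sim_config()] to record alongside the tables.
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(sim$microbiome, file.path(dir, "microbiome_counts.tsv"))
  write_feature_table(sim$metabolome, file.path(dir, "metabolites.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  export_ground_truth(sim$truth, file.path(dir, "ground_truth.tsv"))
  if (!is.null(config)) write_sim_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
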