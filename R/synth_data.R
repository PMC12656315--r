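#' Configuration for the synthetic amendment study
#'
#' Emulates a randomized block field trial with four amendment doses
#' (control plus three application rates), four replicates (16 plots)
#' and three crop seasons, plus the downstream products the pipeline
#' consumes: soil indicator tables, sieve-fraction masses, two amplicon
#' feature tables and a linear-Gaussian structural model.
#'
#' Indicator baselines use the pre-trial topsoil measurements where
#' available (pH 4.67, EA 3.31, SOM 26.67, AN 145.25, AP 24.44,
#' AK 309.50, ExK 1.12, ExNa 0.72, ExCa 3.06, ExMg 0.28); indicators
#' without a measured baseline carry plausible synthetic values for an
#' upland red soil, marked as such in the truth record.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @param doses named amendment doses in t/ha.
#' @param replicates replicates per treatment.
#' @param seasons crop season labels.
#' @param effect per-indicator dose-response slope (units per t/ha).
#' @param noise_sd per-indicator Gaussian noise sd.
#' @param sieve_d_true planted fractal dimension, in (2, 3).
#' @param sieve_noise_sd lognormal sd of the sieve mass noise.
#' @param n_taxa taxa per kingdom (named vector bacteria/fungi).
#' @param n_modules planted co-occurrence modules.
#' @param background_frac fraction of taxa left unstructured (no module;
#'   they buffer the compositional closure so planted blocks stay
#'   mutually independent in relative abundance).
#' @param block_rho within-module latent correlation, in (0, 1).
#' @param hub_excess extra cross-module loading for planted hub taxa.
#' @param treatment_shift composition shift per dose unit on block means.
#' @param depth mean sequencing depth per sample.
#' @param depth_jitter lognormal sd of per-sample depth (default 20
#'   percent).
#' @param sem_paths true path coefficients dose -> chemical -> quality
#'   -> yield.
#' @param sem_loading indicator loading on its latent in the structural
#'   generator.
#' @param sem_n samples for the structural generator.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         doses = c(CK = 0, `PTs-1` = 6, `PTs-2` = 9,
                                   `PTs-3` = 15),
                         replicates = 4,
                         seasons = c("LAP", "ESP", "SM"),
                         effect = NULL, noise_sd = NULL,
                         sieve_d_true = 2.6, sieve_noise_sd = 0.05,
                         n_taxa = c(bacteria = 300, fungi = 150),
                         n_modules = 3, background_frac = 0.5,
                         block_rho = 0.9,
                         hub_excess = 0.8, treatment_shift = 2.5,
                         depth = 20000, depth_jitter = 0.2,
                         sem_paths = c(dose_chemical = 0.7,
                                       chemical_quality = 0.6,
                                       quality_yield = 0.3),
                         sem_loading = 0.97, sem_n = 1000) {
  base <- c(pH = 4.67, EA = 3.31, ExH = 0.71, ExAl = 2.60, CEC = 15.0,
            ExK = 1.12, ExNa = 0.72, ExCa = 3.06, ExMg = 0.28,
            SOM = 26.67, TN = 1.60, TP = 0.90, TK = 14.0, AN = 145.25,
            AP = 24.44, AK = 309.50, CAT = 12.0, UE = 0.35, BD = 1.35)
  measured <- c("pH", "EA", "SOM", "AN", "AP", "AK", "ExK", "ExNa",
                "ExCa", "ExMg")
  if (is.null(effect)) {
    # per t/ha slopes: acidity falls, bases and fertility rise with dose
    effect <- c(pH = 0.07, EA = -0.12, ExH = -0.025, ExAl = -0.095,
                CEC = 0.20, ExK = 0.01, ExNa = 0.004, ExCa = 0.15,
                ExMg = 0.03, SOM = 0.30, TN = 0.012, TP = 0.010,
                TK = 0.05, AN = 1.20, AP = 0.50, AK = 2.50, CAT = 0.25,
                UE = 0.008, BD = -0.008)
  }
  if (is.null(noise_sd)) {
    noise_sd <- c(pH = 0.06, EA = 0.08, ExH = 0.03, ExAl = 0.07,
                  CEC = 0.40, ExK = 0.04, ExNa = 0.02, ExCa = 0.12,
                  ExMg = 0.02, SOM = 0.80, TN = 0.05, TP = 0.04,
                  TK = 0.40, AN = 4.00, AP = 1.20, AK = 8.00,
                  CAT = 0.50, UE = 0.02, BD = 0.02)
  }
  stopifnot(sieve_d_true > 2, sieve_d_true < 3,
            block_rho > 0, block_rho < 1, all(noise_sd >= 0))
  structure(list(seed = seed, doses = doses, replicates = replicates,
                 seasons = seasons, baseline = base,
                 baseline_measured = measured, effect = effect,
                 noise_sd = noise_sd, sieve_d_true = sieve_d_true,
                 sieve_noise_sd = sieve_noise_sd, n_taxa = n_taxa,
                 n_modules = n_modules, background_frac = background_frac,
                 block_rho = block_rho,
                 hub_excess = hub_excess,
                 treatment_shift = treatment_shift, depth = depth,
                 depth_jitter = depth_jitter, sem_paths = sem_paths,
                 sem_loading = sem_loading, sem_n = sem_n),
            class = "synth_config")
}

# independent but reproducible sub-streams from the master seed
derive_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% 2147483647L

#' Generate the synthetic soil indicator table
#'
#' Per plot x season: indicator = baseline + slope x dose + season
#' offset + Gaussian noise. TEB is derived exactly as the base-cation
#' sum, and the aggregate indices (R0.25, MWD, GMD, D) come from the
#' matching synthetic sieve data so the two artifacts agree.
#'
#' @param cfg `synth_config`.
#' @return list with `table` (validated `soil_table`), `sieves` (named
#'   list of `sieve_fractions`, one per plot x season) and `truth`
#'   (slopes, baselines, planted D per plot).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(derive_seed(cfg, 1L))
  treatments <- names(cfg$doses)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        treatment = treatments,
                        crop_season = cfg$seasons,
                        stringsAsFactors = FALSE)
  design$plot_id <- paste0(design$treatment, "-R", design$replicate)
  dose <- cfg$doses[design$treatment]
  nr <- nrow(design)
  ind <- names(cfg$baseline)
  season_offset <- setNames(seq_along(cfg$seasons) - 1, cfg$seasons)
  vals <- sapply(ind, function(i) {
    cfg$baseline[[i]] +
      cfg$effect[[i]] * dose +
      0.02 * cfg$baseline[[i]] * season_offset[design$crop_season] +
      rnorm(nr, 0, cfg$noise_sd[[i]])
  })
  vals <- as.data.frame(vals)
  # physical floors: concentrations cannot go negative
  for (i in ind) vals[[i]] <- pmax(vals[[i]], 0.01)
  vals$TEB <- vals$ExK + vals$ExNa + vals$ExCa + vals$ExMg
  sieves <- generate_sieve_data(cfg, design, dose)
  agg <- aggregate_indices_table(sieves$sets)
  tab <- cbind(design[, c("plot_id", "treatment", "crop_season",
                          "replicate")],
               vals, agg[, c("R0.25", "MWD", "GMD", "D")])
  tab <- validate_soil_table(tab)
  attr(tab, "polarity") <- default_polarity()[setdiff(names(tab),
                                                      design_columns())]
  list(table = tab, sieves = sieves$sets,
       truth = list(effect = cfg$effect, baseline = cfg$baseline,
                    baseline_measured = cfg$baseline_measured,
                    d_true = sieves$d_true))
}

#' Generate sieve-fraction masses with a planted fractal dimension
#'
#' Fraction masses are differenced from the exact cumulative power law
#' M(r < R_i)/M_T = (R_i / Rmax)^(3 - D) and multiplied by lognormal
#' noise. Amendment dose raises aggregate stability by lowering the
#' planted D slightly with dose.
#'
#' @param cfg `synth_config`.
#' @param design optional design data.frame (rows = plots x seasons);
#'   defaults to the full trial design.
#' @param dose optional dose vector matching `design`.
#' @return list with `sets` (named list of `sieve_fractions`) and
#'   `d_true` (named planted D per sample).
#' @export
generate_sieve_data <- function(cfg, design = NULL, dose = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(derive_seed(cfg, 2L))
  if (is.null(design)) {
    design <- expand.grid(replicate = seq_len(cfg$replicates),
                          treatment = names(cfg$doses),
                          crop_season = cfg$seasons,
                          stringsAsFactors = FALSE)
    design$plot_id <- paste0(design$treatment, "-R", design$replicate)
  }
  if (is.null(dose)) dose <- cfg$doses[design$treatment]
  apertures <- c(2, 1, 0.5, 0.25, 0.106)
  ids <- paste(design$plot_id, design$crop_season, sep = "_")
  d_true <- pmin(2.95, pmax(2.05,
                            cfg$sieve_d_true - 0.01 * dose))
  names(d_true) <- ids
  sets <- lapply(seq_along(ids), function(k) {
    s0 <- sieve_fractions(apertures, rep(1, length(apertures) + 1), 5, ids[k])
    d <- fraction_mean_diameters(s0)
    cum <- (d / d[1])^(3 - d_true[k])
    masses <- cum - c(cum[-1], 0)
    masses <- masses * 50                     # 50 g wet-sieved sample
    if (cfg$sieve_noise_sd > 0) {
      masses <- masses * rlnorm(length(masses), 0, cfg$sieve_noise_sd)
    }
    sieve_fractions(apertures, masses, 5, ids[k])
  })
  names(sets) <- ids
  list(sets = sets, d_true = d_true)
}

#' Generate bacterial and fungal feature tables with planted structure
#'
#' Latent Gaussian block-factor model: taxa within a module share a
#' factor at correlation `block_rho`; treatment shifts the block means
#' in proportion to dose; counts are multinomial draws per sample at a
#' lognormally jittered depth. Designated hub taxa additionally load on
#' the other modules, giving them excess cross-module connectivity.
#'
#' @param cfg `synth_config`.
#' @return list with `bacteria` and `fungi` feature tables and `truth`
#'   (module membership, hub taxa, shift per dose, depth per sample).
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(derive_seed(cfg, 3L))
  treatments <- names(cfg$doses)
  samples <- paste0(rep(treatments, each = cfg$replicates), "-R",
                    seq_len(cfg$replicates))
  ns <- length(samples)
  dose <- rep(cfg$doses, each = cfg$replicates)
  dose_z <- (dose - mean(dose)) / sd(dose)
  depth <- round(cfg$depth * rlnorm(ns, 0, cfg$depth_jitter))
  one_kingdom <- function(kingdom, n_taxa, prefix) {
    nm <- cfg$n_modules
    n_str <- floor(n_taxa * (1 - cfg$background_frac))
    # module 0 marks unstructured background taxa
    module <- c(rep(seq_len(nm), length.out = n_str),
                rep(0L, n_taxa - n_str))
    taxa <- sprintf("%s%04d", prefix, seq_len(n_taxa))
    hubs <- taxa[match(seq_len(nm), module)]    # one planted hub per module
    # block factors per sample, shifted by treatment dose
    shift_sign <- rep(c(1, -1), length.out = nm)
    f <- sapply(seq_len(nm), function(b)
      cfg$treatment_shift * shift_sign[b] * dose_z + rnorm(ns))
    rho <- cfg$block_rho
    lat <- sapply(seq_len(n_taxa), function(t) {
      if (module[t] == 0L) return(rnorm(ns))
      if (taxa[t] %in% hubs && nm > 1) {
        # hub taxa straddle their own and the next module's factor
        nxt <- module[t] %% nm + 1
        shared <- (f[, module[t]] + cfg$hub_excess * f[, nxt]) /
          sqrt(1 + cfg$hub_excess^2)
        sqrt(rho) * shared + sqrt(1 - rho) * rnorm(ns)
      } else {
        sqrt(rho) * f[, module[t]] + sqrt(1 - rho) * rnorm(ns)
      }
    })
    mu <- rnorm(n_taxa, 0, 1.2)               # lognormal abundance spread
    counts <- sapply(seq_len(ns), function(s) {
      w <- exp(mu + 0.8 * lat[s, ])
      drop(stats::rmultinom(1, depth[s], w / sum(w)))
    })
    rownames(counts) <- taxa
    colnames(counts) <- samples
    list(ft = feature_table(counts, kingdom = kingdom),
         module = setNames(module, taxa), hubs = hubs)
  }
  bac <- one_kingdom("bacteria", cfg$n_taxa[["bacteria"]], "bASV")
  fun <- one_kingdom("fungi", cfg$n_taxa[["fungi"]], "fASV")
  list(bacteria = bac$ft, fungi = fun$ft,
       truth = list(module = c(bac$module, fun$module),
                    hubs = c(bac$hubs, fun$hubs),
                    treatment_shift = cfg$treatment_shift,
                    depth = setNames(depth, samples)))
}

#' Generate linear-Gaussian data for the structural model
#'
#' Latent chain dose -> chemical -> quality -> yield with the configured
#' path coefficients; three indicators per downstream latent at the
#' configured loading (unit-variance indicators), dose observed
#' directly.
#'
#' @param cfg `synth_config`.
#' @param n samples; defaults to `cfg$sem_n`.
#' @param weak_indicator add an extra `chemical` indicator with loading
#'   0.3 (to exercise loading pruning).
#' @return list with `data` (data.frame), `spec` (`plspm_spec`) and
#'   `truth` (paths, loadings).
#' @export
generate_sem_data <- function(cfg, n = cfg$sem_n, weak_indicator = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(derive_seed(cfg, 4L))
  p <- cfg$sem_paths
  dose <- rnorm(n)
  chem <- p[["dose_chemical"]] * dose +
    sqrt(1 - p[["dose_chemical"]]^2) * rnorm(n)
  qual <- p[["chemical_quality"]] * chem +
    sqrt(1 - p[["chemical_quality"]]^2) * rnorm(n)
  yld <- p[["quality_yield"]] * qual +
    sqrt(1 - p[["quality_yield"]]^2) * rnorm(n)
  lam <- cfg$sem_loading
  reflect <- function(latent, k, prefix, loading = lam) {
    out <- sapply(seq_len(k), function(j)
      loading * latent + sqrt(1 - loading^2) * rnorm(n))
    colnames(out) <- paste0(prefix, seq_len(k))
    out
  }
  dat <- data.frame(dose = dose,
                    reflect(chem, 3, "chem"),
                    reflect(qual, 3, "qual"),
                    reflect(yld, 3, "yield"))
  blocks <- list(dose = "dose",
                 chemical = paste0("chem", 1:3),
                 quality = paste0("qual", 1:3),
                 yield = paste0("yield", 1:3))
  if (weak_indicator) {
    dat$chem_weak <- 0.3 * chem + sqrt(1 - 0.09) * rnorm(n)
    blocks$chemical <- c(blocks$chemical, "chem_weak")
  }
  spec <- plspm_spec(blocks,
                     rbind(c("dose", "chemical"),
                           c("chemical", "quality"),
                           c("quality", "yield")))
  list(data = dat, spec = spec,
       truth = list(paths = p, loading = lam,
                    weak_loading = if (weak_indicator) 0.3 else NULL))
}

#' Generate and write the full synthetic input bundle
#'
#' Writes the soil TSV, sieve CSV, two feature-table TSVs and a truth
#' JSON under `dir`.
#'
#' @param cfg `synth_config`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly; the generated objects
#'   as attributes.
#' @export
generate_study <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exp <- generate_experiment(cfg)
  com <- generate_community(cfg)
  paths <- list(
    soil = file.path(dir, "soil_table.tsv"),
    sieve = file.path(dir, "sieve_fractions.csv"),
    bacteria = file.path(dir, "feature_table_bacteria.tsv"),
    fungi = file.path(dir, "feature_table_fungi.tsv"),
    truth = file.path(dir, "truth.json"))
  write_soil_table(exp$table, paths$soil)
  write_sieve_csv(exp$sieves, paths$sieve)
  write_feature_table(com$bacteria, paths$bacteria)
  write_feature_table(com$fungi, paths$fungi)
  jsonlite::write_json(list(seed = cfg$seed,
                            effect = as.list(exp$truth$effect),
                            d_true = as.list(exp$truth$d_true),
                            module = as.list(com$truth$module),
                            hubs = com$truth$hubs),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  out <- lapply(paths, identity)
  attr(out, "experiment") <- exp
  attr(out, "community") <- com
  invisible(out)
}
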