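#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator. Defaults
#' emulate the study design: four perturbation libraries (a non-targeting
#' control line and a 49-guide activation line, each with and without
#' doxycycline), endothelial subpopulations with marker programs, nine
#' activation targets of which one (ZNF124) is a planted null, arterial
#' expansion upon induction (1.63-fold in the control line, 3.33-fold in
#' the activation line), and an IGFBP2-like downstream effector induced in
#' arterial cells that carry RUNX1T1-class guides.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_cells_per_library Cells simulated per library.
#' @param n_genes Total gene panel size (structured genes plus background).
#' @param populations Named list of populations, each with `base_fraction`
#'   and a named `markers` vector of negative-binomial means overriding the
#'   baseline for that population.
#' @param library_labels The four perturbation library labels, in the order
#'   (control -DOX, control +DOX, activation -DOX, activation +DOX).
#' @param targets `data.frame` with columns `gene` and `activation_fold`
#'   (multiplier >= 1; exactly one default target is fixed at 1 as the
#'   planted null).
#' @param guides_per_target Integer vector, guides designed per target
#'   (default sums to 49).
#' @param arterial_expansion_fold_NT,arterial_expansion_fold_AGM Fold
#'   applied to the arterial base fraction upon DOX induction in each line,
#'   then renormalised across populations.
#' @param effector_gene,effector_induction_fold,driver_target Downstream
#'   effector symbol, its induction fold in arterial carrier cells, and the
#'   target whose guide class drives it.
#' @param driver_arterial_weight Sampling weight multiplier for
#'   driver-class guides in arterial cells of the induced activation
#'   library (plants the guide-enrichment signal).
#' @param moi_lambda Mean of the zero-truncated Poisson guides-per-cell
#'   model for the activation line (MOI-10 infection).
#' @param capture_mean,capture_size Negative-binomial mean/size for capture
#'   counts of truly present guides.
#' @param capture_noise Per cell-by-guide probability of an ambient
#'   background count; `ambient_lambda` sets its (1 + Poisson) magnitude.
#' @param ambient_lambda See `capture_noise`.
#' @param baseline_mean,baseline_sdlog Log-normal hyper-parameters for
#'   background gene means.
#' @param dispersion Negative-binomial size shared by all genes.
#' @param mito_mean Mean count per mitochondrial gene (13 MT- genes).
#' @param reference Reference-panel settings, see [reference_config()].
#' @param seahorse Seahorse settings, see [seahorse_config()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_library = 2000L,
                       n_genes = 2000L,
                       populations = default_populations(),
                       library_labels = c("iSAM_NT", "iSAM_NT_DOX",
                                          "iSAM_AGM", "iSAM_AGM_DOX"),
                       targets = default_targets(),
                       guides_per_target = c(6L, 6L, 5L, 5L, 5L, 5L, 5L, 6L, 6L),
                       arterial_expansion_fold_NT = 1.63,
                       arterial_expansion_fold_AGM = 3.33,
                       effector_gene = "IGFBP2",
                       effector_induction_fold = 3,
                       driver_target = "RUNX1T1",
                       driver_arterial_weight = 2,
                       moi_lambda = 10,
                       capture_mean = 50,
                       capture_size = 4,
                       capture_noise = 0.01,
                       ambient_lambda = 0.3,
                       baseline_mean = 0.3,
                       baseline_sdlog = 1,
                       dispersion = 2,
                       mito_mean = 4,
                       reference = reference_config(),
                       seahorse = seahorse_config()) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_library = as.integer(n_cells_per_library),
              n_genes = as.integer(n_genes),
              populations = populations,
              library_labels = library_labels,
              targets = targets,
              guides_per_target = as.integer(guides_per_target),
              arterial_expansion_fold_NT = arterial_expansion_fold_NT,
              arterial_expansion_fold_AGM = arterial_expansion_fold_AGM,
              effector_gene = effector_gene,
              effector_induction_fold = effector_induction_fold,
              driver_target = driver_target,
              driver_arterial_weight = driver_arterial_weight,
              moi_lambda = moi_lambda,
              capture_mean = capture_mean,
              capture_size = capture_size,
              capture_noise = capture_noise,
              ambient_lambda = ambient_lambda,
              baseline_mean = baseline_mean,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion,
              mito_mean = mito_mean,
              reference = reference,
              seahorse = seahorse)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  list(
    arterial = list(base_fraction = 0.10,
                    markers = c(GJA4 = 4, DLL4 = 4, PECAM1 = 3, CDH5 = 3)),
    venous   = list(base_fraction = 0.60,
                    markers = c(NRP2 = 4, APLNR = 4, PECAM1 = 3, CDH5 = 3)),
    EHT      = list(base_fraction = 0.30,
                    markers = c(RUNX1 = 4, CD44 = 4,
                                PECAM1 = 0.6, CDH5 = 0.6))
  )
}

#' @rdname sim_config
#' @param active_fold Activation fold for the eight responsive targets.
#' @export
default_targets <- function(active_fold = 2) {
  genes <- c("RUNX1T1", "NR4A1", "GATA2", "SMAD7", "ZNF124",
             "SOX6", "ZNF33A", "NFAT5", "TFDP2")
  data.frame(gene = genes,
             activation_fold = ifelse(genes == "ZNF124", 1, active_fold),
             stringsAsFactors = FALSE)
}

#' Reference-panel settings
#'
#' Detection probabilities for the planted candidate TFs in each reference
#' population: above 0.5 in the in vivo haemogenic endothelium (aHEC) and
#' below 0.25 in the in vitro-derived endothelium, mirroring the
#' cross-dataset selection gates.
#'
#' @param detect_aHEC,detect_aEC,detect_vEC,detect_IVD_Endo,detect_IVD_HPC
#'   Planted per-cell detection probability of the candidate TFs in each
#'   population.
#' @param fractions_vivo,fractions_vitro Population fractions within each
#'   panel.
#' @param planted If `FALSE`, the candidate TFs are simulated at the
#'   uniform background detection level (null configuration).
#' @param background_detection Detection probability of the planted TFs in
#'   all populations under the null, and of decoy/extra TF genes always.
#' @export
reference_config <- function(detect_aHEC = 0.7,
                             detect_aEC = 0.2,
                             detect_vEC = 0.2,
                             detect_IVD_Endo = 0.1,
                             detect_IVD_HPC = 0.1,
                             fractions_vivo = c(aEC = 0.35, vEC = 0.35,
                                                aHEC = 0.30),
                             fractions_vitro = c(IVD_Endo = 0.70,
                                                 IVD_HPC = 0.30),
                             planted = TRUE,
                             background_detection = 0.3) {
  probs <- c(detect_aHEC, detect_aEC, detect_vEC,
             detect_IVD_Endo, detect_IVD_HPC, background_detection)
  if (any(probs < 0) || any(probs >= 1))
    stop("detection probabilities must lie in [0, 1)")
  if (length(fractions_vivo) == 0 || length(fractions_vitro) == 0)
    stop("reference populations must be non-empty")
  if (abs(sum(fractions_vivo) - 1) > 1e-9 ||
      abs(sum(fractions_vitro) - 1) > 1e-9)
    stop("reference population fractions must sum to 1")
  list(detect_aHEC = detect_aHEC, detect_aEC = detect_aEC,
       detect_vEC = detect_vEC, detect_IVD_Endo = detect_IVD_Endo,
       detect_IVD_HPC = detect_IVD_HPC,
       fractions_vivo = fractions_vivo, fractions_vitro = fractions_vitro,
       planted = planted, background_detection = background_detection)
}

#' Seahorse trace settings
#'
#' Per-condition OCR and ECAR phase means (basal, oligomycin,
#' rotenone/antimycin A) and additive noise. The default second condition
#' emulates the effector-treated state: lowered ECAR (reduced glycolysis)
#' with preserved respiration.
#'
#' @param conditions Condition labels.
#' @param wells_per_condition,reads_per_phase Plate layout.
#' @param ocr_means Matrix conditions x phases (basal, oligo, rot), must be
#'   non-increasing along each row.
#' @param ecar_means Matrix conditions x phases.
#' @param noise_ocr,noise_ecar Additive Gaussian noise SD.
#' @export
seahorse_config <- function(conditions = c("CTR", "IGFBP2"),
                            wells_per_condition = 3L,
                            reads_per_phase = 3L,
                            ocr_means = rbind(CTR = c(100, 40, 20),
                                              IGFBP2 = c(110, 42, 20)),
                            ecar_means = rbind(CTR = c(30, 40, 35),
                                               IGFBP2 = c(18, 26, 22)),
                            noise_ocr = 2,
                            noise_ecar = 1) {
  colnames(ocr_means) <- colnames(ecar_means) <- c("basal", "oligo", "rot")
  if (any(ocr_means[, "basal"] < ocr_means[, "oligo"]) ||
      any(ocr_means[, "oligo"] < ocr_means[, "rot"]))
    stop("phase means must satisfy basal >= oligo >= rot")
  if (any(ocr_means < 0) || any(ecar_means < 0))
    stop("phase means must be non-negative")
  list(conditions = conditions,
       wells_per_condition = as.integer(wells_per_condition),
       reads_per_phase = as.integer(reads_per_phase),
       ocr_means = ocr_means, ecar_means = ecar_means,
       noise_ocr = noise_ocr, noise_ecar = noise_ecar)
}

validate_sim_config <- function(cfg) {
  fr <- vapply(cfg$populations, function(p) p$base_fraction, numeric(1))
  if (length(fr) == 0) stop("populations must be non-empty")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population base fractions must sum to 1 (got ", sum(fr), ")")
  if (cfg$n_cells_per_library <= 0)
    stop("n_cells_per_library must be positive")
  if (any(cfg$targets$activation_fold < 1))
    stop("activation folds must be >= 1")
  if (length(cfg$guides_per_target) != nrow(cfg$targets))
    stop("guides_per_target length must match the target list")
  if (length(cfg$library_labels) != 4)
    stop("four library labels are required")
  if (!cfg$driver_target %in% cfg$targets$gene)
    stop("driver_target must be one of the targets")
  cfg
}

mt_genes <- function() {
  paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                  "CO1", "CO2", "CO3", "ATP6", "ATP8", "CYB"))
}

extra_tf_genes <- function() {
  c("GATA1", "TAL1", "LMO2", "SPI1", "MYB", "ERG", "FLI1",
    "SOX17", "HEY1", "FOXO1")
}

marker_genes <- function(populations) {
  unique(unlist(lapply(populations, function(p) names(p$markers))))
}

# Structured + background gene universe shared by the generators.
sim_gene_universe <- function(cfg, extra = character(0)) {
  structured <- unique(c(marker_genes(cfg$populations), cfg$targets$gene,
                         cfg$effector_gene, extra_tf_genes(), extra,
                         mt_genes()))
  n_bg <- cfg$n_genes - length(structured)
  if (n_bg < 0) stop("n_genes too small for the structured gene panel")
  c(structured, sprintf("BG%04d", seq_len(n_bg)))
}

# Baseline per-gene NB means (background lognormal; structured genes fixed).
sim_baseline_means <- function(cfg, genes) {
  mu <- rlnorm(length(genes), log(cfg$baseline_mean), cfg$baseline_sdlog)
  names(mu) <- genes
  mu[marker_genes(cfg$populations)] <- 0.2
  mu[cfg$targets$gene] <- 0.3
  mu[cfg$effector_gene] <- 0.5
  mu[extra_tf_genes()] <- 0.4
  mu[mt_genes()] <- cfg$mito_mean
  mu
}

#' Default guide library for the simulated activation line
#'
#' 49 targeting guides (5-7 per target across the nine targets) plus one
#' non-targeting control guide.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with `guide_id`, `target`, `class`.
#' @export
make_guide_library <- function(config = sim_config()) {
  tg <- config$targets$gene
  ids <- unlist(mapply(function(g, k) paste0(g, "_g", seq_len(k)),
                       tg, config$guides_per_target, SIMPLIFY = FALSE),
                use.names = FALSE)
  tgt <- rep(tg, config$guides_per_target)
  validate_guide_library(
    data.frame(guide_id = c(ids, "NT_g1"),
               target = c(tgt, ""),
               class = c(rep("targeting", length(ids)), "non_targeting"),
               stringsAsFactors = FALSE))
}

arterial_fractions <- function(cfg) {
  fr <- vapply(cfg$populations, function(p) p$base_fraction, numeric(1))
  expand <- function(fold) {
    w <- fr
    w["arterial"] <- w["arterial"] * fold
    w / sum(w)
  }
  labs <- cfg$library_labels
  out <- rbind(expand(1), expand(cfg$arterial_expansion_fold_NT),
               expand(1), expand(cfg$arterial_expansion_fold_AGM))
  rownames(out) <- labs
  out
}

#' Simulate the four-library perturbation experiment
#'
#' Generates UMI counts, guide-capture counts, cell metadata and the
#' planted ground truth for the control (single non-targeting guide) and
#' activation (49-guide pool) lines, each with and without DOX induction.
#' In the induced activation library, cells carrying a guide for a target
#' express it with mean scaled by its activation fold, the arterial
#' fraction is expanded (renormalised across populations), the effector
#' gene is induced in arterial carrier cells of the driver guide class,
#' and driver-class guides are over-sampled in arterial cells.
#'
#' @param config A [sim_config()].
#' @return List of class `perturb_sim` with elements `counts` (gene x cell
#'   sparse), `guide_counts` (guide x cell sparse), `metadata` (barcode,
#'   library, line, dox), `guide_library`, `truth` (per-cell populations
#'   and guide sets, per-target folds, planted population fractions), and
#'   `config`.
#' @export
simulate_perturbation_experiment <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  genes <- sim_gene_universe(cfg)
  mu0 <- sim_baseline_means(cfg, genes)
  glib <- make_guide_library(cfg)
  tguides <- glib$guide_id[glib$class == "targeting"]
  ttargets <- glib$target[glib$class == "targeting"]
  fracs <- arterial_fractions(cfg)
  labs <- cfg$library_labels
  n <- cfg$n_cells_per_library
  pops <- names(cfg$populations)

  # population means: baseline overridden by each population's marker program
  M <- matrix(mu0, nrow = length(genes), ncol = length(pops),
              dimnames = list(genes, pops))
  for (p in pops) {
    mk <- cfg$populations[[p]]$markers
    M[names(mk), p] <- mk
  }

  meta <- list(); truth_cells <- list()
  counts <- list(); gcounts <- list()
  for (lib in labs) {
    line <- if (grepl("AGM", lib)) "AGM" else "NT"
    dox <- grepl("DOX", lib)
    barcodes <- sprintf("%s_c%04d", lib, seq_len(n))
    pop <- sample(pops, n, replace = TRUE, prob = fracs[lib, pops])

    # guide sets
    if (line == "NT") {
      guide_sets <- rep(list("NT_g1"), n)
    } else {
      k <- pmin(rztpois(n, cfg$moi_lambda), length(tguides))
      guide_sets <- vector("list", n)
      driver_ids <- tguides[ttargets == cfg$driver_target]
      for (i in seq_len(n)) {
        w <- rep(1, length(tguides))
        if (dox && pop[i] == "arterial")
          w[tguides %in% driver_ids] <- cfg$driver_arterial_weight
        guide_sets[[i]] <- sample(tguides, k[i], prob = w)
      }
    }

    # expression means with planted activation and effector induction
    mu <- M[, pop, drop = FALSE]
    colnames(mu) <- barcodes
    if (line == "AGM" && dox) {
      cell_targets <- lapply(guide_sets, function(g)
        unique(ttargets[match(g, tguides)]))
      for (j in seq_len(nrow(cfg$targets))) {
        tgene <- cfg$targets$gene[j]
        fold <- cfg$targets$activation_fold[j]
        if (fold == 1) next
        carrier <- vapply(cell_targets, function(ts) tgene %in% ts,
                          logical(1))
        mu[tgene, carrier] <- mu[tgene, carrier] * fold
      }
      drv <- vapply(cell_targets, function(ts)
        cfg$driver_target %in% ts, logical(1))
      eff <- drv & pop == "arterial"
      mu[cfg$effector_gene, eff] <-
        mu[cfg$effector_gene, eff] * cfg$effector_induction_fold
    }
    x <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                        size = cfg$dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
    counts[[lib]] <- methods::as(Matrix::Matrix(x, sparse = TRUE),
                                 "CsparseMatrix")

    # guide capture: true guides at high mean, ambient low counts
    gc <- matrix(0L, nrow = nrow(glib), ncol = n,
                 dimnames = list(glib$guide_id, barcodes))
    for (i in seq_len(n)) {
      gs <- guide_sets[[i]]
      gc[gs, i] <- rnbinom(length(gs), mu = cfg$capture_mean,
                           size = cfg$capture_size)
    }
    if (cfg$capture_noise > 0) {
      amb <- runif(length(gc)) < cfg$capture_noise
      if (any(amb))
        gc[amb] <- gc[amb] + 1L + rpois(sum(amb), cfg$ambient_lambda)
    }
    gcounts[[lib]] <- methods::as(Matrix::Matrix(gc, sparse = TRUE),
                                  "CsparseMatrix")

    meta[[lib]] <- data.frame(barcode = barcodes, library = lib,
                              line = line, dox = dox,
                              stringsAsFactors = FALSE)
    truth_cells[[lib]] <- data.frame(
      barcode = barcodes, library = lib, population = pop,
      guides = vapply(guide_sets, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE)
  }

  out <- list(counts = do.call(cbind, counts),
              guide_counts = do.call(cbind, gcounts),
              metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
              guide_library = glib,
              truth = list(
                cells = do.call(rbind, c(truth_cells,
                                         make.row.names = FALSE)),
                activation = data.frame(
                  target = cfg$targets$gene,
                  fold = cfg$targets$activation_fold,
                  active = cfg$targets$activation_fold > 1),
                population_fractions = fracs,
                effector = cfg$effector_gene,
                driver_target = cfg$driver_target),
              config = cfg)
  class(out) <- "perturb_sim"
  out
}

#' Simulate the in vivo / in vitro reference panel pair
#'
#' Emulates the dataset pair behind candidate discovery: an in vivo panel
#' (aEC, vEC, aHEC) and an in vitro panel (IVD_Endo, IVD_HPC), with the
#' configured candidate TFs planted at high detection in aHEC and low
#' detection in the in vitro endothelium. Two non-TF decoy genes share the
#' planted profile so the TF gate is exercised.
#'
#' @param config A [sim_config()]; panel sizes come from
#'   `n_cells_per_library` and detection levels from `config$reference`.
#' @return List of class `reference_panel` with `in_vivo` / `in_vitro`
#'   (each `counts` + `labels`), `tf_list`, `truth`, `config`.
#' @export
simulate_reference_panel <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  ref <- cfg$reference
  set.seed(cfg$seed)
  decoys <- c("DECOY_NONTF_1", "DECOY_NONTF_2")
  genes <- sim_gene_universe(cfg, extra = decoys)
  mu0 <- sim_baseline_means(cfg, genes)
  mu0[decoys] <- 0.3
  planted <- if (ref$planted) cfg$targets$gene else character(0)
  profiled <- c(planted, decoys)
  size <- cfg$dispersion

  pop_mu <- function(pop) {
    mu <- mu0
    det <- switch(pop,
                  aHEC = ref$detect_aHEC, aEC = ref$detect_aEC,
                  vEC = ref$detect_vEC, IVD_Endo = ref$detect_IVD_Endo,
                  IVD_HPC = ref$detect_IVD_HPC)
    mu[profiled] <- mu_from_detection(det, size)
    mu[cfg$targets$gene[!cfg$targets$gene %in% planted]] <-
      mu_from_detection(ref$background_detection, size)
    mu[extra_tf_genes()] <- mu_from_detection(ref$background_detection, size)
    mu
  }

  draw_panel <- function(fractions, tag) {
    n <- cfg$n_cells_per_library
    pop <- sample(names(fractions), n, replace = TRUE, prob = fractions)
    barcodes <- sprintf("%s_c%04d", tag, seq_len(n))
    mus <- vapply(names(fractions), pop_mu,
                  numeric(length(genes)))
    mu <- mus[, pop, drop = FALSE]
    x <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                nrow = length(genes),
                dimnames = list(genes, barcodes))
    list(counts = methods::as(Matrix::Matrix(x, sparse = TRUE),
                              "CsparseMatrix"),
         labels = data.frame(barcode = barcodes, population = pop,
                             stringsAsFactors = FALSE))
  }

  out <- list(in_vivo = draw_panel(ref$fractions_vivo, "vivo"),
              in_vitro = draw_panel(ref$fractions_vitro, "vitro"),
              tf_list = unique(c(cfg$targets$gene, extra_tf_genes())),
              truth = list(planted = planted, decoys = decoys,
                           detect_aHEC = ref$detect_aHEC,
                           detect_IVD_Endo = ref$detect_IVD_Endo),
              config = cfg)
  class(out) <- "reference_panel"
  out
}

#' Simulate a Seahorse XF trace
#'
#' Per well, three reads per phase (basal, oligomycin, rotenone/AA) with
#' additive Gaussian noise around the configured per-condition phase
#' means; negative draws are clamped at zero.
#'
#' @param config A [sim_config()]; settings under `config$seahorse`.
#' @return `data.frame` trace with columns `well`, `condition`, `phase`,
#'   `read_index`, `OCR`, `ECAR`.
#' @export
simulate_seahorse <- function(config = sim_config()) {
  sh <- config$seahorse
  set.seed(config$seed)
  phases <- c("basal", "oligo", "rot")
  rows <- list()
  wi <- 0
  for (cond in sh$conditions) {
    for (w in seq_len(sh$wells_per_condition)) {
      wi <- wi + 1
      well <- sprintf("W%02d", wi)
      for (ph in phases) {
        ocr <- sh$ocr_means[cond, ph] +
          rnorm(sh$reads_per_phase, 0, sh$noise_ocr)
        ecar <- sh$ecar_means[cond, ph] +
          rnorm(sh$reads_per_phase, 0, sh$noise_ecar)
        rows[[length(rows) + 1]] <- data.frame(
          well = well, condition = cond, phase = ph,
          read_index = seq_len(sh$reads_per_phase),
          OCR = pmax(0, ocr), ECAR = pmax(0, ecar),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
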