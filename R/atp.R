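#' Seahorse ATP-rate constants
#'
#' The printed assay constants: molecular oxygen consumption rate 2,
#' P/O ratio 2.75, CO2 contribution factor 0.5, buffer factor 2.6 / mpH,
#' reaction volume 2.28 ul, and Kvol 1.1.
#'
#' @param o2_per_atp,p_o_ratio,co2_contribution Respiration constants.
#' @param buffer_factor,reaction_volume,kvol Proton-efflux constants.
#' @export
atp_constants <- function(o2_per_atp = 2, p_o_ratio = 2.75,
                          co2_contribution = 0.5, buffer_factor = 2.6,
                          reaction_volume = 2.28, kvol = 1.1) {
  k <- list(o2_per_atp = o2_per_atp, p_o_ratio = p_o_ratio,
            co2_contribution = co2_contribution,
            buffer_factor = buffer_factor,
            reaction_volume = reaction_volume, kvol = kvol)
  if (any(unlist(k) <= 0)) stop("all ATP constants must be positive")
  k
}

#' Per-well phase means of a Seahorse trace
#'
#' Averages OCR over the reads of each phase and ECAR over the basal
#' reads, per well. In strict mode each phase must have exactly
#' `reads_per_phase` reads.
#'
#' @param trace Trace `data.frame` (see [read_seahorse_csv()]).
#' @param strict Enforce the read count per phase.
#' @param reads_per_phase Expected reads per phase in strict mode.
#' @return `data.frame`: `well`, `condition`, `ocr_basal`, `ocr_oligo`,
#'   `ocr_rot`, `ecar_basal`.
#' @export
phase_means <- function(trace, strict = TRUE, reads_per_phase = 3L) {
  wells <- unique(trace$well)
  rows <- lapply(wells, function(w) {
    tw <- trace[trace$well == w, , drop = FALSE]
    for (ph in c("basal", "oligo", "rot")) {
      nr <- sum(tw$phase == ph)
      if (nr == 0)
        stop("well ", w, " is missing phase '", ph, "'")
      if (strict && nr != reads_per_phase)
        stop("well ", w, " has ", nr, " reads in phase '", ph,
             "' (expected ", reads_per_phase, ")")
    }
    data.frame(well = w,
               condition = tw$condition[1],
               ocr_basal = mean(tw$OCR[tw$phase == "basal"]),
               ocr_oligo = mean(tw$OCR[tw$phase == "oligo"]),
               ocr_rot = mean(tw$OCR[tw$phase == "rot"]),
               ecar_basal = mean(tw$ECAR[tw$phase == "basal"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' ATP production rates from phase means
#'
#' Implements the printed partitioning arithmetic per well:
#' `ocr_atp = ocr_basal - ocr_oligo`;
#' `mito_atp = ocr_atp * 2 * 2.75` (pmol ATP/min);
#' `mito_per = (ocr_basal - ocr_rot) * 0.5`;
#' `per = ecar_basal * 2.6 * 2.28 * 1.1`;
#' `glyco_atp = per - mito_per` (pmol ATP/min);
#' `total_atp = glyco_atp + mito_atp`;
#' `mito_glyco_ratio = mito_atp / glyco_atp`.
#' Wells violating the phase ordering `basal >= oligo >= rot` are flagged
#' invalid and their rates set to `NA` (never silently clamped); wells
#' with non-positive glycolytic ATP have an undefined ratio.
#'
#' @param means Per-well phase means from [phase_means()].
#' @param constants An [atp_constants()] list.
#' @return `data.frame` of class `atp_rates` with the phase means, the
#'   rates above (units pmol ATP/min), `valid`, and `reason`.
#' @export
compute_atp_rates <- function(means, constants = atp_constants()) {
  k <- constants
  valid <- means$ocr_basal >= means$ocr_oligo &
    means$ocr_oligo >= means$ocr_rot
  ocr_atp <- ifelse(valid, means$ocr_basal - means$ocr_oligo, NA_real_)
  mito_atp <- ocr_atp * k$o2_per_atp * k$p_o_ratio
  mito_per <- ifelse(valid,
                     (means$ocr_basal - means$ocr_rot) * k$co2_contribution,
                     NA_real_)
  per <- ifelse(valid,
                means$ecar_basal * k$buffer_factor * k$reaction_volume *
                  k$kvol,
                NA_real_)
  glyco_atp <- per - mito_per
  total_atp <- glyco_atp + mito_atp
  ratio <- ifelse(!is.na(glyco_atp) & glyco_atp > 0,
                  mito_atp / glyco_atp, NA_real_)
  out <- data.frame(
    well = means$well, condition = means$condition,
    ocr_basal = means$ocr_basal, ocr_oligo = means$ocr_oligo,
    ocr_rot = means$ocr_rot, ecar_basal = means$ecar_basal,
    ocr_atp = ocr_atp, mito_atp = mito_atp, mito_per = mito_per,
    per = per, glyco_atp = glyco_atp, total_atp = total_atp,
    mito_glyco_ratio = ratio,
    valid = valid,
    reason = ifelse(valid,
                    ifelse(!is.na(glyco_atp) & glyco_atp <= 0,
                           "ratio_undefined", "ok"),
                    "phase_order_violation"),
    stringsAsFactors = FALSE)
  class(out) <- c("atp_rates", class(out))
  out
}

#' Per-condition summary of ATP rates
#'
#' Mean and SD of the glycolytic, mitochondrial and total ATP production
#' rates and of the Mito/Glyco ratio over the valid wells of each
#' condition. Invalid wells are excluded and counted.
#'
#' @param rates A [compute_atp_rates()] table.
#' @return `data.frame` with one row per condition.
#' @export
condition_summary <- function(rates) {
  conds <- unique(rates$condition)
  rows <- lapply(conds, function(cc) {
    rc <- rates[rates$condition == cc & rates$valid, , drop = FALSE]
    if (nrow(rc) == 0)
      stop("condition '", cc, "' has no valid wells")
    msd <- function(x) c(mean(x), if (length(x) > 1) sd(x) else NA_real_)
    g <- msd(rc$glyco_atp); m <- msd(rc$mito_atp); t <- msd(rc$total_atp)
    r <- msd(rc$mito_glyco_ratio[!is.na(rc$mito_glyco_ratio)])
    data.frame(condition = cc, n_wells = nrow(rc),
               n_excluded = sum(rates$condition == cc & !rates$valid),
               glyco_atp_mean = g[1], glyco_atp_sd = g[2],
               mito_atp_mean = m[1], mito_atp_sd = m[2],
               total_atp_mean = t[1], total_atp_sd = t[2],
               ratio_mean = r[1], ratio_sd = r[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
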