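# Closed-form quantification utilities: NMR concentrations against
# internal standards, qPCR relative expression, behavioural and
# electrophysiological indices.

#' Quantify a fecal-water metabolite from NMR integrals
#'
#' Concentration against the TSP internal standard:
#' \deqn{C = \frac{I_{met} / nH_{met}}{I_{ref} / nH_{ref}} \cdot
#'   \frac{A_{ref}}{w}}
#' with \eqn{I} the signal integrals, \eqn{nH} the proton counts of the
#' integrated resonances, \eqn{A_{ref}} the amount of standard in the tube
#' (default 1.32 umol: TSP at 2 mM in a 660 uL sample) and \eqn{w} the
#' feces weight in g. TSP's trimethylsilyl resonance has 9 equivalent
#' protons. Result in umol per g stool.
#'
#' @param integral metabolite signal integral (arbitrary units, >= 0).
#' @param protons proton count of the integrated metabolite resonance.
#' @param ref_integral internal-standard integral (> 0).
#' @param weight_g feces weight in grams (> 0).
#' @param ref_amount_umol standard amount in the tube (default 1.32).
#' @param ref_protons standard proton count (default 9, TSP).
#' @return concentration in umol/g.
#' @examples
#' fecal_quantify(integral = 100, protons = 3, ref_integral = 100,
#'                weight_g = 0.1)  # 39.6 umol/g
#' @export
fecal_quantify <- function(integral, protons, ref_integral, weight_g,
                           ref_amount_umol = 1.32, ref_protons = 9) {
  stopifnot(integral >= 0, protons >= 1, ref_protons >= 1)
  if (any(ref_integral <= 0)) abort("Reference integral must be positive.")
  if (any(weight_g <= 0)) abort("Specimen weight must be positive.")
  (integral / protons) / (ref_integral / ref_protons) *
    ref_amount_umol / weight_g
}

#' Quantify a serum metabolite relative to creatine
#'
#' Proton-normalized integral ratio against the creatine CH2 resonance at
#' 3.95 ppm (2 protons): \eqn{(I_{met}/nH_{met}) / (I_{cr}/2)}, a
#' dimensionless mol-per-mol-creatine value.
#'
#' @param integral metabolite signal integral (>= 0).
#' @param protons proton count of the metabolite resonance.
#' @param creatine_integral creatine CH2 integral (> 0).
#' @param creatine_protons creatine reference proton count (default 2).
#' @return mol metabolite per mol creatine.
#' @export
serum_quantify <- function(integral, protons, creatine_integral,
                           creatine_protons = 2) {
  stopifnot(integral >= 0, protons >= 1)
  if (any(creatine_integral <= 0)) abort("Creatine integral must be positive.")
  (integral / protons) / (creatine_integral / creatine_protons)
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{gene,t} - Ct_{ref,t}) -
#' (Ct_{gene,c} - Ct_{ref,c})}: the target gene normalized to a reference
#' gene (e.g. gapdh) and expressed as fold change of treatment over
#' control.
#'
#' @param ct_gene_treat,ct_ref_treat target and reference Ct in the
#'   treated sample.
#' @param ct_gene_ctrl,ct_ref_ctrl target and reference Ct in the control
#'   sample.
#' @return fold change (1 = no change).
#' @export
ddct_fold_change <- function(ct_gene_treat, ct_ref_treat,
                             ct_gene_ctrl, ct_ref_ctrl) {
  cts <- c(ct_gene_treat, ct_ref_treat, ct_gene_ctrl, ct_ref_ctrl)
  if (any(cts <= 0 | cts >= 45)) {
    abort("Ct values must lie in (0, 45).")
  }
  ddct <- (ct_gene_treat - ct_ref_treat) - (ct_gene_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Novel-object discrimination index
#'
#' Default (`method = "difference"`): time on the novel object minus time
#' on the familiar one, divided by total exploration time — in
#' \eqn{[-1, 1]}, 0 at chance. `method = "ratio"` gives the alternative
#' novel/total form in \eqn{[0, 1]}, 0.5 at chance.
#'
#' @param t_novel,t_familiar exploration times in seconds (total > 0).
#' @param method `"difference"` or `"ratio"`.
#' @return the index.
#' @examples
#' discrimination_index(30, 20)  # 0.2
#' @export
discrimination_index <- function(t_novel, t_familiar,
                                 method = c("difference", "ratio")) {
  method <- match.arg(method)
  stopifnot(t_novel >= 0, t_familiar >= 0)
  total <- t_novel + t_familiar
  if (any(total <= 0)) abort("Total exploration time must be positive.")
  if (method == "difference") {
    (t_novel - t_familiar) / total
  } else {
    t_novel / total
  }
}

#' Paired-pulse ratio
#'
#' A2/A1: the field-potential amplitude evoked by the second of two paired
#' stimuli over the first. Values above 1 indicate facilitation, below 1
#' depression (higher release probability).
#'
#' @param a1 first-response amplitude (> 0).
#' @param a2 second-response amplitude.
#' @return the ratio A2/A1.
#' @export
paired_pulse_ratio <- function(a1, a2) {
  if (any(a1 <= 0)) abort("First amplitude must be positive.")
  a2 / a1
}

#' Baseline-normalized fEPSP time course
#'
#' Sweeps recorded every 20 s (3 per minute) are averaged per minute and
#' divided by the mean of the pre-induction baseline window, so the
#' baseline sits at 1 and potentiation reads directly as a ratio.
#'
#' @param amplitudes numeric vector of sweep amplitudes at 20 s intervals.
#' @param baseline_minutes length of the baseline window in minutes
#'   (default 1: the minute before induction).
#' @param sweeps_per_minute sweeps averaged per minute (default 3).
#' @return numeric vector of per-minute normalized amplitudes.
#' @examples
#' fepsp_normalize(c(2, 2, 2, 4, 4, 4))  # 1 then 2
#' @export
fepsp_normalize <- function(amplitudes, baseline_minutes = 1,
                            sweeps_per_minute = 3) {
  n_base <- baseline_minutes * sweeps_per_minute
  if (length(amplitudes) < n_base) {
    abort("Need at least the baseline window of sweeps.")
  }
  n_min <- floor(length(amplitudes) / sweeps_per_minute)
  per_min <- vapply(seq_len(n_min), function(i) {
    mean(amplitudes[((i - 1) * sweeps_per_minute + 1):(i * sweeps_per_minute)])
  }, numeric(1))
  base <- mean(amplitudes[seq_len(n_base)])
  if (base == 0) abort("Baseline mean is zero.")
  per_min / base
}
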