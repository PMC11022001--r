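#' Embedded study tables
#'
#' The published per-subject measurement tables shipped with the package:
#' luminal volumes per acquisition condition, identified material constants
#' per flow rate, and the systole-peak stress-state summary. Used as input
#' fixtures for the consistency checks and the worked examples.
#'
#' @return A list of data frames: \code{volumes}, \code{constants},
#'   \code{stress}.
#' @export
study_tables <- function() {
  rd <- function(f) utils::read.csv(system.file("extdata", f, package = "aneufit"),
                                    stringsAsFactors = FALSE)
  list(volumes = rd("table1_luminal_volumes.csv"),
       constants = rd("table2_material_constants.csv"),
       stress = rd("table3_stress_state.csv"))
}

#' Recompute the published derived quantities from their source columns
#'
#' Self-consistency check on the embedded study tables: recomputes every
#' experimental volume variation (mm^3, and the extreme percentages at two
#' decimals / one decimal), and the D2-to-D3 relative decreases of the
#' stiffness constant a (nearest integer percent), comparing each against
#' its printed value.
#'
#' @return Data frame with columns \code{item}, \code{computed},
#'   \code{printed}, \code{pass}.
#' @export
reproduce_reference_values <- function() {
  tb <- study_tables()
  vols <- tb$volumes
  rows <- list()
  add <- function(item, computed, printed, tol) {
    rows[[length(rows) + 1]] <<- data.frame(
      item = item, computed = computed, printed = printed,
      pass = abs(computed - printed) <= tol)
  }
  for (subj in unique(vols$subject)) {
    v1 <- vols$luminal_volume_mm3[vols$subject == subj & vols$condition == "C1"]
    sub <- vols[vols$subject == subj & vols$condition != "C1", ]
    for (i in seq_len(nrow(sub))) {
      rep_i <- volume_report(v1, sub$luminal_volume_mm3[i])
      add(sprintf("%s %s dV_exp (mm^3)", subj, sub$condition[i]),
          round(rep_i$delta_v, 2), sub$dv_exp_printed_mm3[i], 0.005)
    }
  }
  # extreme percentage variations as printed in the text
  min_pct <- volume_report(12.98, 13.10)$delta_v_pct
  max_pct <- volume_report(9.81, 10.84)$delta_v_pct
  add("S1 C2-D1 dV_exp (%)", round(min_pct, 2), 0.92, 0.005)
  add("S2 C2-D3 dV_exp (%)", round(max_pct, 1), 10.5, 0.05)
  # D2 -> D3 decrease of the stiffness constant, nearest integer percent
  cons <- tb$constants
  for (subj in unique(cons$subject)) {
    a_d2 <- cons$a_kpa[cons$subject == subj & cons$condition == "C2-D2"]
    a_d3 <- cons$a_kpa[cons$subject == subj & cons$condition == "C2-D3"]
    dec <- (a_d2 - a_d3) / a_d2 * 100
    printed <- if (subj == "S1") 25 else 26
    add(sprintf("%s a decrease D2->D3 (%%)", subj), round(dec), printed, 0.5)
  }
  do.call(rbind, rows)
}

#' Provisional stress-to-pressure criterion ratio
#'
#' Ratio of the mean first principal Cauchy stress on the aneurysm wall to
#' the mean pressure applied to it, \code{<sigma1>/<P>}, per condition.
#' The combination of stress components entering an eventual rupture
#' criterion is not settled; this simplest instance is emitted as a
#' provisional indicator and labelled as such.
#'
#' @param sigma1_mean Mean first principal Cauchy stress, kPa.
#' @param p_mean Mean applied pressure, kPa (> 0).
#' @return Dimensionless ratio (scale-invariant).
#' @export
criterion_ratio <- function(sigma1_mean, p_mean) {
  if (any(p_mean == 0)) stop("criterion ratio undefined for zero mean pressure")
  sigma1_mean / p_mean
}

#' Assemble a per-subject study table with derived columns recomputed
#'
#' Joins the embedded volume, material-constant and stress tables into one
#' long table and recomputes every derived column (volume variation in
#' mm^3 and percent, the provisional criterion ratio) from its sources.
#'
#' @return Data frame, one row per subject x stimulated condition.
#' @export
assemble_study_table <- function() {
  tb <- study_tables()
  vols <- tb$volumes
  out <- list()
  for (subj in unique(vols$subject)) {
    v1 <- vols$luminal_volume_mm3[vols$subject == subj & vols$condition == "C1"]
    sub <- vols[vols$subject == subj & vols$condition != "C1", ]
    for (i in seq_len(nrow(sub))) {
      cond <- sub$condition[i]
      rep_i <- volume_report(v1, sub$luminal_volume_mm3[i])
      cons <- tb$constants[tb$constants$subject == subj &
                           tb$constants$condition == cond, ]
      str <- tb$stress[tb$stress$subject == subj & tb$stress$condition == cond, ]
      out[[length(out) + 1]] <- data.frame(
        subject = subj, condition = cond,
        v_c1_mm3 = v1, v_c2_mm3 = sub$luminal_volume_mm3[i],
        dv_exp_mm3 = round(rep_i$delta_v, 2),
        dv_exp_pct = round(rep_i$delta_v_pct, 1),
        a_kpa = cons$a_kpa, b = cons$b, delta_t_s = cons$delta_t_s,
        e_pct = cons$e_pct_printed,
        p_mean_kpa = str$p_mean_kpa, sigma1_mean_kpa = str$sigma1_mean_kpa,
        dp_pct = str$dp_pct, dsigma1_pct = str$dsigma1_pct,
        criterion_ratio_provisional = round(
          criterion_ratio(str$sigma1_mean_kpa, str$p_mean_kpa), 2))
    }
  }
  do.call(rbind, out)
}
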