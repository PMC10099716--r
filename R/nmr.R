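#' Heteronuclear NOE ratio
#'
#' Steady-state 1H->15N heteronuclear NOE: the ratio of peak intensity with
#' proton saturation to the reference intensity. Low values flag
#' picosecond-nanosecond backbone flexibility (the wild-type BAF
#' N-terminus); values near 1 flag rigidity.
#'
#' @param i_sat,i_ref Saturated and reference intensities (vectorised).
#' @return `i_sat / i_ref`.
#' @export
het_noe <- function(i_sat, i_ref) {
  if (any(i_ref == 0)) stop("domain error: zero reference intensity")
  i_sat / i_ref
}

#' Project a peak onto the open-closed exchange axis
#'
#' Amide peaks of the BAF species lie on a line between two reference
#' positions, the open (unphosphorylated wild-type) and closed
#' (di-phosphorylated) states, because the species exchange between the
#' same two conformational ensembles. This projects a peak orthogonally
#' onto the open->closed segment in scaled (1H, 15N) chemical-shift space
#' and reports the fractional position (0 = open, 1 = closed, clipped to
#' \[0, 1\]) plus the perpendicular deviation from the axis. Nitrogen shifts
#' are divided by `n_scale` before any distance is computed (conventional
#' combined-shift weighting, default 1/0.14).
#'
#' @param peak,open_ref,closed_ref Lists/rows with `shift_h` and `shift_n`
#'   (ppm).
#' @param n_scale 15N/1H scale factor; 15N shifts are multiplied by it
#'   (default 0.14).
#' @return List with `fraction_closed` and `collinearity_deviation`
#'   (scaled ppm).
#' @export
two_state_projection <- function(peak, open_ref, closed_ref,
                                 n_scale = 0.14) {
  pt <- function(p) c(p$shift_h, p$shift_n * n_scale)
  p <- pt(peak); a <- pt(open_ref); b <- pt(closed_ref)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps)
    stop("degenerate axis: open and closed references coincide")
  t_raw <- sum((p - a) * ab) / len2
  perp <- (p - a) - t_raw * ab
  list(fraction_closed = min(1, max(0, t_raw)),
       collinearity_deviation = sqrt(sum(perp^2)))
}

#' Tabulate heteronuclear NOE ratios per residue
#'
#' @param intensities data.frame with columns `residue_number`, `i_sat`,
#'   `i_ref` (and optionally replicate rows per residue).
#' @return data.frame `residue_number`, `ratio`, `replicate_sd` (NA when a
#'   residue has a single replicate).
#' @export
het_noe_table <- function(intensities) {
  stopifnot(all(c("residue_number", "i_sat", "i_ref") %in%
                  colnames(intensities)))
  ratios <- het_noe(intensities$i_sat, intensities$i_ref)
  agg <- split(ratios, intensities$residue_number)
  data.frame(
    residue_number = as.integer(names(agg)),
    ratio = vapply(agg, mean, numeric(1)),
    replicate_sd = vapply(agg, function(x)
      if (length(x) > 1) stats::sd(x) else NA_real_, numeric(1)),
    row.names = NULL)
}
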