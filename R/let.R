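# Lethal electric field threshold (LET) estimation.
#
# A lesion's LET is the field magnitude whose exceedance isovolume in the
# model equals the measured lesion volume; volume_above() is monotone
# nonincreasing in the threshold, so bisection inverts it. Per-dose medians
# and a power-law fit LET(N) = a * N^b summarise the dose dependence.

#' Myocardial volume above a field threshold
#'
#' @param solution a [solve_field()] result.
#' @param mesh the mesh it was computed on.
#' @param threshold field threshold, V/cm.
#' @return volume in mm^3 of myocardial tissue (including scar/border cells,
#'   which are myocardial) with `E >= threshold`.
#' @export
volume_above <- function(solution, mesh, threshold) {
  stopifnot(threshold > 0)
  myo <- mesh$region[solution$cells] == REGION["myocardium"]
  sel <- myo & solution$E_mag_Vcm >= threshold
  if (!any(sel)) return(0)
  sum(cell_volumes(mesh, solution$cells[sel])) * 1e9
}

#' Invert a lesion volume into a lethal field threshold
#'
#' Bisection on [volume_above()] over `bracket` (V/cm) down to `tol` V/cm.
#'
#' @param solution,mesh field solution and mesh.
#' @param target_volume measured lesion volume, mm^3.
#' @param bracket search interval, V/cm.
#' @param tol threshold tolerance, V/cm.
#' @return list with `let_value` (V/cm), `achieved_volume` (mm^3) and
#'   `bisection_iters`.
#' @export
estimate_let <- function(solution, mesh, target_volume,
                         bracket = c(50, 3000), tol = 1) {
  stopifnot(target_volume > 0)
  v_lo <- volume_above(solution, mesh, bracket[1])  # largest achievable
  v_hi <- volume_above(solution, mesh, bracket[2])
  if (target_volume > v_lo || target_volume < v_hi)
    stop(sprintf("target volume %.1f mm^3 outside achievable range [%.1f, %.1f] for bracket [%g, %g] V/cm",
                 target_volume, v_hi, v_lo, bracket[1], bracket[2]),
         call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  iters <- 0L
  while (hi - lo > tol) {
    iters <- iters + 1L
    mid <- (lo + hi) / 2
    if (volume_above(solution, mesh, mid) >= target_volume) lo <- mid else hi <- mid
  }
  let <- (lo + hi) / 2
  list(let_value = let, achieved_volume = volume_above(solution, mesh, let),
       bisection_iters = iters)
}

#' Estimate LETs for a lesion-observation table
#'
#' @param observations data.frame with at least `lesion_id`,
#'   `measured_volume` (mm^3) and the dose metadata columns (`amplitude`,
#'   `n_trains`, `timepoint`); see [gen_lesion_observations()].
#' @param solutions named list of field solutions keyed by
#'   `segment<net>:amp<amplitude>` as produced by the study runners, or a
#'   single solution applied to all lesions.
#' @param mesh mesh (or named list of meshes matching `solutions`).
#' @inheritParams estimate_let
#' @return `observations` with `let_value`, `achieved_volume`,
#'   `bisection_iters` columns appended; lesions whose volume is outside the
#'   achievable range are dropped with a warning.
#' @export
estimate_let_table <- function(observations, solutions, mesh,
                               bracket = c(50, 3000), tol = 1) {
  single <- inherits(solutions, "pfa_field")
  out <- observations
  out$let_value <- NA_real_
  out$achieved_volume <- NA_real_
  out$bisection_iters <- NA_integer_
  for (r in seq_len(nrow(observations))) {
    key <- sprintf("segment%d:amp%g", observations$segment_id[r],
                   observations$amplitude[r])
    sol <- if (single) solutions else solutions[[key]]
    msh <- if (inherits(mesh, "pfa_mesh")) mesh else mesh[[key]]
    est <- tryCatch(
      estimate_let(sol, msh, observations$measured_volume[r], bracket, tol),
      error = function(e) NULL)
    if (is.null(est)) next
    out$let_value[r] <- est$let_value
    out$achieved_volume[r] <- est$achieved_volume
    out$bisection_iters[r] <- est$bisection_iters
  }
  dropped <- sum(is.na(out$let_value))
  if (dropped > 0)
    warning(dropped, " lesion(s) outside the achievable volume range were dropped")
  out[!is.na(out$let_value), , drop = FALSE]
}

#' Median LET per dose group
#'
#' @param estimates data.frame with `let_value` and the grouping columns.
#' @param by character vector of grouping column names (default dose and
#'   imaging timepoint).
#' @return data.frame of group keys, `median_let` (V/cm) and `n`.
#' @export
group_medians <- function(estimates, by = c("n_trains", "timepoint")) {
  stopifnot(all(by %in% names(estimates)), "let_value" %in% names(estimates))
  key <- interaction(estimates[by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(estimates, key), function(d) {
    cbind(d[1, by, drop = FALSE],
          data.frame(median_let = stats::median(d$let_value), n = nrow(d)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}

#' Fit the LET-dose power law
#'
#' Ordinary least squares on `log(LET) = log(a) + b * log(N)`.
#'
#' @param points data.frame (or matrix) with columns `n_trains` and
#'   `median_let` (V/cm), all positive.
#' @return list with `a` (V/cm), `b`, `r_squared` and the fitted `lm`.
#' @export
fit_let_power <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("n_trains", "median_let") %in% names(points)))
  if (length(unique(points$n_trains)) < 2)
    stop("power fit requires at least 2 distinct train counts", call. = FALSE)
  stopifnot(all(points$median_let > 0))
  fit <- stats::lm(log(median_let) ~ log(n_trains), data = points)
  co <- stats::coef(fit)
  list(a = exp(unname(co[1])), b = unname(co[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit)
}

#' Predicted lesion volumes per LV segment
#'
#' @param solutions named list of field solutions, one per segment (names
#'   are segment ids).
#' @param meshes matching named list of meshes (or one mesh for all).
#' @param let_value threshold, V/cm.
#' @return data.frame `segment_id`, `predicted_mm3`.
#' @export
predict_segment_volumes <- function(solutions, meshes, let_value) {
  ids <- names(solutions)
  vols <- vapply(ids, function(id) {
    msh <- if (inherits(meshes, "pfa_mesh")) meshes else meshes[[id]]
    volume_above(solutions[[id]], msh, let_value)
  }, 0)
  data.frame(segment_id = as.integer(ids), predicted_mm3 = unname(vols))
}
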