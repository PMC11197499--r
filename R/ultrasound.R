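#' Synthetic ultrasound / pressure measurement panel
#'
#' Emulates the per-artery Doppler ultrasound measurements and the brachial
#' cuff pressure that drive the boundary conditions: peak systolic and
#' diastolic velocity and lumen radius for each inflow artery, plus one
#' brachial pressure. Values are drawn from physiologically plausible adult
#' ranges (systolic velocity 0.4--1.2 m/s, diastolic fraction 0.3--0.6 of
#' systolic, radius 1.5--3.5 mm, brachial pressure 80--120 mmHg), so
#' every draw satisfies `v_systole >= v_diastole >= 0` and `r > 0` by
#' construction.
#'
#' @param n_arteries number of inflow arteries (>= 1).
#' @param seed RNG seed (mandatory; generation never touches global RNG
#'   state).
#' @param v_sys_range systolic velocity range, m/s.
#' @param dia_frac_range diastolic/systolic velocity ratio range.
#' @param radius_range lumen radius range, m.
#' @param pressure_range brachial pressure range, mmHg.
#' @return list with `panel` (data.frame: `artery_id`, `v_systole_m_s`,
#'   `v_diastole_m_s`, `radius_m`) and `pressure_pa` (brachial pressure, Pa).
#' @export
#' @examples
#' p <- make_ultrasound_panel(4, seed = 7)
#' all(p$panel$v_systole_m_s >= p$panel$v_diastole_m_s)
make_ultrasound_panel <- function(n_arteries, seed,
                                  v_sys_range = c(0.4, 1.2),
                                  dia_frac_range = c(0.3, 0.6),
                                  radius_range = c(1.5e-3, 3.5e-3),
                                  pressure_range = c(80, 120)) {
  if (n_arteries < 1L) stop("`n_arteries` must be >= 1", call. = FALSE)
  .with_seed(seed, {
    v_sys <- stats::runif(n_arteries, v_sys_range[1], v_sys_range[2])
    v_dia <- v_sys * stats::runif(n_arteries, dia_frac_range[1],
                                  dia_frac_range[2])
    r <- stats::runif(n_arteries, radius_range[1], radius_range[2])
    p_mmhg <- stats::runif(1, pressure_range[1], pressure_range[2])
    list(panel = data.frame(artery_id = sprintf("artery_%02d",
                                                seq_len(n_arteries)),
                            v_systole_m_s = v_sys,
                            v_diastole_m_s = v_dia,
                            radius_m = r,
                            stringsAsFactors = FALSE),
         pressure_pa = mmhg_to_pa(p_mmhg))
  })
}

#' Write / read an ultrasound panel as CSV with a JSON pressure sidecar
#'
#' The CSV uses the header `artery_id,v_systole_m_s,v_diastole_m_s,radius_m`;
#' the brachial pressure (Pa) is written to `<path>.json`.
#'
#' @param panel the list returned by [make_ultrasound_panel()].
#' @param path CSV file path.
#' @return the path, invisibly (writer); the panel list (reader).
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel$panel, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(pressure_pa = panel$pressure_pa),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("artery_id", "v_systole_m_s", "v_diastole_m_s", "radius_m")
  if (!all(need %in% names(panel)))
    stop("panel CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  side <- paste0(path, ".json")
  pressure <- if (file.exists(side))
    jsonlite::read_json(side)$pressure_pa else NA_real_
  list(panel = panel, pressure_pa = as.numeric(pressure))
}
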