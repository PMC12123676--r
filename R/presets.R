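# Named parameter presets replicating the worked examples: each expands
# to a full model + drive + initial-condition specification.

preset_table <- function() {
  fhn_base <- list(model = "fhn", R0 = 0.5, Ra = 0.417, tau0 = 0.01,
                   I0 = 0.507)
  st <- list(model = "stype", a = 50, b = 0.2, c = 1, tau_k = 0.01)
  list(
    fig2  = c(fhn_base, list(eps = 0.4, init = c(u = 1, x = 0.5))),
    fig5  = c(fhn_base, list(eps = 0.01, init = c(u = 1, x = 0.5))),
    fig8a = c(st, list(mode = "constant_current", I0 = 0.2, C0 = 0.0101,
                       init = c(u = 0.18, x = 0.2))),
    fig8c = c(st, list(mode = "constant_current", I0 = 0.2, C0 = 10,
                       init = c(u = 0.18, x = 0.2))),
    fig8e = c(st, list(mode = "constant_current", I0 = 0.1, C0 = 1,
                       init = c(u = 0.18, x = 0.2))),
    fig10a = c(st, list(mode = "constant_voltage", Va = 1, R0 = 4,
                        C0 = 0.001, init = c(u = 0.1, x = 0.1))),
    fig10c = c(st, list(mode = "constant_voltage", Va = 1, R0 = 4,
                        C0 = 0.0127, init = c(u = 0.1, x = 0.1))),
    fig10e = c(st, list(mode = "constant_voltage", Va = 1, R0 = 4,
                        C0 = 1, init = c(u = 0.1, x = 0.1)))
  )
}

#' Named parameter presets
#'
#' Returns the configuration behind a named preset (`fig2`, `fig5`,
#' `fig8a`, `fig8c`, `fig8e`, `fig10a`, `fig10c`, `fig10e`): model
#' parameters, drive, and the initial condition of the corresponding
#' worked example. `overrides` (named list) replaces individual fields.
#'
#' @param name preset name; `preset()` with no argument lists all names.
#' @param overrides named list of fields to replace after expansion.
#' @return List with elements `params` ([fhn_params()] or
#'   [stype_params()]), `drive` (or NULL for FHN) and `init`.
#' @examples
#' preset("fig8c")$drive   # I0 = 0.2 A, C0 = 10 F
#' @export
preset <- function(name = NULL, overrides = list()) {
  tab <- preset_table()
  if (is.null(name)) return(names(tab))
  if (!name %in% names(tab))
    stop(sprintf("unknown preset '%s'; known: %s", name,
                 paste(names(tab), collapse = ", ")))
  cfg <- utils::modifyList(tab[[name]], overrides)
  build_setup(cfg)
}

# Turn a flat config list into params/drive/init objects.
build_setup <- function(cfg) {
  if (cfg$model == "fhn") {
    params <- fhn_params(R0 = cfg$R0, Ra = cfg$Ra, tau0 = cfg$tau0,
                         eps = cfg$eps, I0 = cfg$I0)
    drive <- NULL
  } else {
    params <- stype_params(a = cfg$a, b = cfg$b, c = cfg$c,
                           tau_k = cfg$tau_k)
    drive <- if (cfg$mode == "constant_current")
      drive_current(I0 = cfg$I0, C0 = cfg$C0)
    else
      drive_voltage(Va = cfg$Va, R0 = cfg$R0, C0 = cfg$C0,
                    tau_k = cfg$tau_k)
  }
  init <- if (!is.null(cfg$init)) state_point(cfg$init[["u"]],
                                              cfg$init[["x"]]) else NULL
  list(params = params, drive = drive, init = init)
}
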