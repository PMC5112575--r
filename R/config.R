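#' Read a YAML run configuration
#'
#' Loads uptake and numerical-control settings from a YAML file.  Both the
#' readable keys (icps, ihth, beta, zr_max, jthaw, jmatur, lambda,
#' r_coeffs, h1, h2, h4, l0, dt, k_ext, h_dry, kmean) and the historical
#' uppercase aliases (ICPSN, IHTH, BETA, ZRMAX, JTHAW, JMATUR) are accepted;
#' unknown keys are rejected.  Values are validated through
#' [uptake_config()] and [run_control()].
#'
#' @param path YAML file path
#' @return list with `uptake` (an [uptake_config()]) and `control`
#'   (a [run_control()])
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_parse(path, NULL, "file not found")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  aliases <- c(ICPSN = "icps", ICPS = "icps", IHTH = "ihth",
               BETA = "beta", ZRMAX = "zr_max", JTHAW = "jthaw",
               JMATUR = "jmatur", LAMBDA = "lambda")
  names(raw) <- ifelse(names(raw) %in% names(aliases),
                       aliases[names(raw)], names(raw))
  uptake_keys <- c("icps", "ihth", "beta", "zr_max", "jthaw", "jmatur",
                   "lambda", "r_coeffs", "h1", "h2", "h4", "l0",
                   "tp1", "tp2")
  control_keys <- c("dt", "k_ext", "h_dry", "kmean", "sat_tol", "engine")
  unknown <- setdiff(names(raw), c(uptake_keys, control_keys))
  if (length(unknown))
    stop_parse(path, NULL, "unknown configuration key(s): %s",
               paste(unknown, collapse = ", "))
  up <- raw[intersect(names(raw), uptake_keys)]
  ct <- raw[intersect(names(raw), control_keys)]
  if (!is.null(up$r_coeffs)) up$r_coeffs <- as.numeric(up$r_coeffs)
  list(uptake = do.call(uptake_config, up),
       control = do.call(run_control, ct))
}
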