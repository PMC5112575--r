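# Plain-text input/output dialects.  The file families keep the historical
# names (soil/ALS, INITF, TERMF, WEA2 inputs; OUTS, OUTS2, INFS, WUE run
# outputs; ARD, C_AEVA, C_ATRA, WBELOW, WADD, BIGI, PCTDIF search grids)
# but the layouts are the documented whitespace-delimited dialects below,
# not byte replicas of the legacy fixed-format templates.  All files are
# '#'-commented; depths are meters positive downward with the surface at
# zero and block centers at (i - 0.5) * dz.

.read_tokens <- function(path) {
  if (!file.exists(path)) stop_parse(path, NULL, "file not found")
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[i])
    toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks)) out[[length(out) + 1L]] <- list(line = i, tokens = toks)
  }
  out
}

.num_tokens <- function(path, row) {
  v <- suppressWarnings(as.numeric(row$tokens))
  if (anyNA(v))
    stop_parse(path, row$line, "non-numeric field '%s'",
               row$tokens[which(is.na(v))[1]])
  v
}

#' Read a soil + grid file
#'
#' Dialect: first data line `nz dz`; second `nlayers`; then one layer
#' record per layer, top first.  A van Genuchten layer is a single line
#' `vg bottom_depth theta_r theta_s K_s alpha n`; a tabulated layer is a
#' line `tab bottom_depth n_nodes` followed by `n_nodes` lines
#' `h theta K` (h in m, theta in m3/m3, K in m/s).
#'
#' @param path file path
#' @return list with `profile` (a [soil_profile()]) and `grid`
#'   (a [flow_grid()])
#' @export
read_soil <- function(path) {
  rows <- .read_tokens(path)
  if (length(rows) < 3) stop_parse(path, NULL, "truncated soil file")
  hd <- .num_tokens(path, rows[[1]])
  if (length(hd) != 2)
    stop_parse(path, rows[[1]]$line, "expected 'nz dz', got %d fields",
               length(hd))
  grid <- flow_grid(hd[1], hd[2])
  nl <- .num_tokens(path, rows[[2]])
  if (length(nl) != 1 || nl < 1 || nl != round(nl))
    stop_parse(path, rows[[2]]$line, "expected a positive layer count")
  models <- list(); depths <- numeric(0)
  r <- 3L
  for (j in seq_len(nl)) {
    if (r > length(rows))
      stop_parse(path, NULL, "missing record for layer %d", j)
    row <- rows[[r]]
    kind <- row$tokens[1]
    if (kind == "vg") {
      v <- suppressWarnings(as.numeric(row$tokens[-1]))
      if (length(v) != 6 || anyNA(v))
        stop_parse(path, row$line,
                   "vg layer needs 6 numeric fields: bottom theta_r theta_s K_s alpha n")
      depths <- c(depths, v[1])
      models[[j]] <- vg_model(v[2], v[3], alpha = v[5], n = v[6], K_s = v[4])
      r <- r + 1L
    } else if (kind == "tab") {
      v <- suppressWarnings(as.numeric(row$tokens[-1]))
      if (length(v) != 2 || anyNA(v) || v[2] < 2)
        stop_parse(path, row$line,
                   "tab layer needs 'tab bottom n_nodes' with n_nodes >= 2")
      depths <- c(depths, v[1])
      nn <- as.integer(v[2])
      tab <- matrix(NA_real_, nn, 3)
      for (k in seq_len(nn)) {
        if (r + k > length(rows))
          stop_parse(path, NULL, "missing tabulated node %d of layer %d", k, j)
        nv <- .num_tokens(path, rows[[r + k]])
        if (length(nv) != 3)
          stop_parse(path, rows[[r + k]]$line,
                     "tabulated node needs 3 fields: h theta K")
        tab[k, ] <- nv
      }
      models[[j]] <- tabulated_model(tab[, 1], tab[, 2], tab[, 3])
      r <- r + 1L + nn
    } else {
      stop_parse(path, row$line, "unknown layer form '%s' (want vg or tab)",
                 kind)
    }
  }
  profile <- soil_profile(models, depths)
  if (abs(profile$z_max - grid$z_max) > 1e-9)
    stop_parse(path, NULL,
               "deepest layer bottom (%g m) != nz*dz (%g m)",
               profile$z_max, grid$z_max)
  list(profile = profile, grid = grid)
}

#' Write a soil + grid file in the [read_soil()] dialect
#' @param profile a [soil_profile()]
#' @param grid a [flow_grid()]
#' @param path output path
#' @export
write_soil <- function(profile, grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# rootflow soil file",
               "# nz dz  (blocks, block thickness m); depths m positive downward",
               sprintf("%d %.6g", grid$nz, grid$dz),
               "# number of layers",
               sprintf("%d", length(profile$models))), con)
  for (j in seq_along(profile$models)) {
    m <- profile$models[[j]]
    if (m$form == 1L) {
      writeLines(sprintf("vg %.6g %.8g %.8g %.8g %.8g %.8g",
                         profile$depths[j], m$theta_r, m$theta_s,
                         m$K_s, m$alpha, m$n), con)
    } else {
      writeLines(sprintf("tab %.6g %d", profile$depths[j],
                         length(m$tab_h)), con)
      writeLines(sprintf("%.8g %.8g %.8g", m$tab_h, m$tab_theta,
                         m$tab_k), con)
    }
  }
  invisible(path)
}

#' Read an initial water-content profile
#'
#' Dialect: nz numeric values (one or more per line), one water content per
#' block from the surface down.
#'
#' @param path file path
#' @param grid a [flow_grid()]; the value count must equal `grid$nz`
#' @return numeric vector of length nz
#' @export
read_init <- function(path, grid) {
  rows <- .read_tokens(path)
  vals <- unlist(lapply(rows, function(r) .num_tokens(path, r)))
  if (length(vals) != grid$nz)
    stop_parse(path, NULL, "expected nz = %d water contents, found %d",
               grid$nz, length(vals))
  if (any(vals <= 0) || any(vals >= 1))
    stop_parse(path, NULL, "water contents must lie in (0, 1)")
  vals
}

#' Write an initial profile in the [read_init()] dialect
#' @param theta per-block water contents
#' @param path output path
#' @export
write_init <- function(theta, path) {
  writeLines(c("# rootflow initial water-content profile",
               "# one theta (m3/m3) per block, surface block first",
               sprintf("%.8g", theta)), path)
  invisible(path)
}

#' Read measured (terminating) water contents
#'
#' Dialect: either two columns `depth theta` (observations on the last
#' simulated day) or three columns `day depth theta`.  No interpolation is
#' applied to these observations.
#'
#' @param path file path
#' @return data.frame with columns day (NA when absent), depth, theta
#' @export
read_term <- function(path) {
  rows <- .read_tokens(path)
  if (!length(rows)) stop_parse(path, NULL, "no observations")
  ncol1 <- length(rows[[1]]$tokens)
  if (!ncol1 %in% 2:3)
    stop_parse(path, rows[[1]]$line,
               "expected 2 (depth theta) or 3 (day depth theta) columns")
  recs <- lapply(rows, function(r) {
    v <- .num_tokens(path, r)
    if (length(v) != ncol1)
      stop_parse(path, r$line, "expected %d columns, found %d",
                 ncol1, length(v))
    v
  })
  m <- do.call(rbind, recs)
  out <- if (ncol1 == 2)
    data.frame(day = NA_real_, depth = m[, 1], theta = m[, 2])
  else data.frame(day = m[, 1], depth = m[, 2], theta = m[, 3])
  if (any(out$theta <= 0))
    stop_parse(path, NULL, "observed water contents must be > 0")
  out
}

#' Write observations in the [read_term()] dialect
#' @param obs data.frame with depth, theta and optionally day
#' @param path output path
#' @export
write_term <- function(obs, path) {
  hdr <- "# rootflow measured water contents"
  if (!is.null(obs$day) && !all(is.na(obs$day))) {
    writeLines(c(hdr, "# day depth(m) theta(m3/m3)",
                 sprintf("%g %.6g %.8g", obs$day, obs$depth, obs$theta)),
               path)
  } else {
    writeLines(c(hdr, "# depth(m) theta(m3/m3)",
                 sprintf("%.6g %.8g", obs$depth, obs$theta)), path)
  }
  invisible(path)
}

#' Read a daily weather file
#'
#' Dialect: six columns in fixed order
#' `day et0 tair rain rh lai` (Julian day; potential ET mm/day; air
#' temperature degC; rainfall mm/day; relative humidity fraction; leaf area
#' index).  Days must be contiguous.  Air temperature and relative humidity
#' are carried through for format fidelity but unused by the default
#' physics.
#'
#' @param path file path
#' @return data.frame of weather records
#' @export
read_weather <- function(path) {
  rows <- .read_tokens(path)
  if (!length(rows)) stop_parse(path, NULL, "no weather records")
  recs <- lapply(rows, function(r) {
    v <- .num_tokens(path, r)
    if (length(v) != 6)
      stop_parse(path, r$line,
                 "expected 6 columns (day et0 tair rain rh lai), found %d",
                 length(v))
    v
  })
  m <- do.call(rbind, recs)
  wx <- data.frame(day = m[, 1], et0 = m[, 2], tair = m[, 3],
                   rain = m[, 4], rh = m[, 5], lai = m[, 6])
  validate_weather(wx, path)
  wx
}

validate_weather <- function(wx, path = "<weather>") {
  if (any(wx$et0 < 0)) stop_parse(path, NULL, "et0 must be >= 0")
  if (any(wx$rain < 0)) stop_parse(path, NULL, "rain must be >= 0")
  if (any(wx$rh < 0 | wx$rh > 1))
    stop_parse(path, NULL, "rh must be a fraction in [0, 1]")
  if (any(wx$lai < 0)) stop_parse(path, NULL, "lai must be >= 0")
  if (nrow(wx) > 1 && any(diff(wx$day) != 1))
    stop_parse(path, NULL, "weather days must be contiguous")
  invisible(wx)
}

#' Write a weather file in the [read_weather()] dialect
#' @param wx weather data.frame (day, et0, tair, rain, rh, lai)
#' @param path output path
#' @export
write_weather <- function(wx, path) {
  writeLines(c("# rootflow daily weather",
               "# day et0(mm/day) tair(degC) rain(mm/day) rh(frac) lai(-)",
               sprintf("%g %.6g %.6g %.6g %.6g %.6g", wx$day, wx$et0,
                       wx$tair, wx$rain, wx$rh, wx$lai)), path)
  invisible(path)
}

#' Interpolate sparse measurements onto block centers
#'
#' Linear interpolation of (depth, theta) pairs to every block center, with
#' flat extrapolation beyond the outermost measurements, so that every
#' depth increment has a water content.
#'
#' @param pairs data.frame or 2-column matrix of (depth m, theta)
#' @param grid a [flow_grid()]
#' @return per-block theta (length nz)
#' @export
interpolate_profile <- function(pairs, grid) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("depth", "theta")
  if (nrow(pairs) < 2)
    stop_domain("need at least 2 (depth, theta) pairs to interpolate")
  if (anyDuplicated(pairs$depth))
    stop_domain("duplicate measurement depths")
  if (any(pairs$depth < 0) || any(pairs$depth > grid$z_max))
    stop_domain("measurement depths must lie within [0, z_max]")
  stats::approx(pairs$depth, pairs$theta, xout = grid$z, rule = 2)$y
}

.fmt_table <- function(df, digits = 6) {
  body <- apply(df, 1, function(r)
    paste(formatC(as.numeric(r), digits = digits, format = "g",
                  width = 13), collapse = " "))
  c(paste0("# ", paste(formatC(names(df), width = 13), collapse = " ")),
    body)
}

#' Write the run / search output files
#'
#' For a simulation run (class `als_run`) writes four files into `dir`:
#' `OUTS.DAT` (daily water-balance components), `OUTS2.DAT` (daily pressure
#' head and water content at every block center), `INFS.DAT` (daily and
#' cumulative surface flux and drainage) and `WUE.DAT` (daily cumulative
#' water-loss summary).  For a grid search (class `als_search`) writes the
#' seven matrices `ARD.DAT`, `C_AEVA.DAT`, `C_ATRA.DAT`, `WBELOW.DAT`,
#' `WADD.DAT`, `BIGI.DAT`, `PCTDIF.DAT`, each laid out with a beta label
#' column and a Zr label row.  All files are deterministic fixed-format
#' text.
#'
#' @param x an `als_run` or `als_search` object
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "als_run")) .write_run_outputs(x, dir)
  else if (inherits(x, "als_search")) .write_search_outputs(x, dir)
  else stop_domain("write_outputs needs an als_run or als_search object")
}

.write_run_outputs <- function(run, dir) {
  d <- run$daily
  hdr <- function(title) c(
    sprintf("# %s", title),
    "# depths m positive downward, surface 0, block centers (i-0.5)*dz")
  p1 <- file.path(dir, "OUTS.DAT")
  writeLines(c(hdr("daily water balance components (mm)"),
               .fmt_table(d[, c("day", "rain", "et0", "Ep", "Tp", "inf_mm",
                                "evap_mm", "tran_mm", "drain_mm",
                                "storage_mm")])), p1)
  p2 <- file.path(dir, "OUTS2.DAT")
  prof <- data.frame(day = rep(d$day, each = run$grid$nz),
                     depth = rep(run$grid$z, times = nrow(d)),
                     h = as.vector(t(run$h)),
                     theta = as.vector(t(run$theta)))
  writeLines(c(hdr("daily pressure head (m) and water content (m3/m3)"),
               .fmt_table(prof, digits = 8)), p2)
  p3 <- file.path(dir, "INFS.DAT")
  inf <- data.frame(day = d$day, inf_mm = d$inf_mm,
                    cum_inf = cumsum(d$inf_mm),
                    drain_mm = d$drain_mm, cum_drain = cumsum(d$drain_mm))
  writeLines(c(hdr("daily and cumulative surface flux and drainage (mm)"),
               .fmt_table(inf)), p3)
  p4 <- file.path(dir, "WUE.DAT")
  wue <- data.frame(day = d$day,
                    cum_evap = cumsum(d$evap_mm),
                    cum_tran = cumsum(d$tran_mm),
                    cum_drain = cumsum(d$drain_mm),
                    cum_rain = cumsum(d$rain))
  writeLines(c(hdr("daily cumulative water loss (mm)"), .fmt_table(wue)), p4)
  invisible(c(p1, p2, p3, p4))
}

.write_search_outputs <- function(sr, dir) {
  files <- c(ard = "ARD.DAT", c_aeva = "C_AEVA.DAT", c_atra = "C_ATRA.DAT",
             wbelow = "WBELOW.DAT", wadd = "WADD.DAT", bigi = "BIGI.DAT",
             pctdif = "PCTDIF.DAT")
  units <- c(ard = "-", c_aeva = "mm", c_atra = "mm", wbelow = "mm",
             wadd = "mm", bigi = "mm", pctdif = "%")
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(dir, files[[nm]])
    m <- sr[[nm]]
    lines <- c(sprintf("# %s (%s): rows = beta, columns = zr_max (m)",
                       files[[nm]], units[[nm]]),
               paste(c(formatC("beta\\zr", width = 10),
                       formatC(sr$zrmaxs, digits = 4, format = "g",
                               width = 12)), collapse = " "))
    if (length(sr$betas))
      lines <- c(lines, vapply(seq_along(sr$betas), function(i)
        paste(c(formatC(sr$betas[i], digits = 4, format = "g", width = 10),
                formatC(m[i, ], digits = 6, format = "g", width = 12)),
              collapse = " "), character(1)))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
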