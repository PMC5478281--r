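# Internal unit system: lengths in micrometres, forces/tensions/adhesion in
# nanonewtons (1 nN = 1 nJ/m of tensile energy density), time in seconds.
# Energies are therefore in nN*um = 1e-15 J. All conversions to/from the
# mixed units used in the literature (pN, Pa*s, N*s/m, J/min) go through
# this table; nothing else in the package hard-codes a conversion factor.

#' Unit conversion constants
#'
#' Named list of the conversion factors used throughout the package.
#' Internal units are micrometre / nanonewton / second.
#'
#' @format A named list:
#' \describe{
#'   \item{pN_per_nN}{1000 pN in one nN.}
#'   \item{J_per_nN_um}{1e-15 J in one internal energy unit (nN um).}
#'   \item{nNs_um2_per_Pas}{Substrate friction density: 1 Pa s equals
#'     1e-3 nN s / um^2.}
#'   \item{Nsm_per_nNs_um}{Vertex friction: 1 nN s / um equals 1e-3 N s / m.}
#'   \item{s_per_min}{60 seconds in a minute.}
#' }
#' @export
az_units <- list(
  pN_per_nN       = 1e3,
  J_per_nN_um     = 1e-15,
  nNs_um2_per_Pas = 1e-3,
  Nsm_per_nNs_um  = 1e-3,
  s_per_min       = 60
)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(from, to) {
  d <- to - from
  n <- vnorm(d)
  if (n < .Machine$double.eps^0.5) {
    stop("degenerate geometry: coincident points", call. = FALSE)
  }
  d / n
}

# trapezoidal quadrature on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Read a key=value parameter file
#'
#' Parses the plain-text configuration format used by the command line
#' interface: one `key = value` pair per line, `#` comments allowed, values
#' numeric. Units are fixed by the package convention (um, nN, s) and may be
#' restated in comments only.
#'
#' @param path Path to the configuration file.
#' @return Named list of numeric values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    out[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  out
}
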