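#' Construct a soil profile
#'
#' A `soil_profile` bundles the 0--23 cm topsoil properties the simulator
#' needs: texture fractions, initial soil organic carbon (SOC), pH, bulk
#' density, and the potential (asymptotic) grain yield `y_pot` used by the
#' saturating yield-response curve.
#'
#' @param name character label, e.g. `"clay"`.
#' @param clay_frac,silt_frac,sand_frac texture mass fractions in `[0, 1]`;
#'   must sum to 1 (tolerance 1e-9).
#' @param soc_init initial SOC, % by mass; must be positive.
#' @param ph soil pH (carried as metadata; the surrogate has no pH dynamics).
#' @param bulk_density g/cm^3.
#' @param y_pot potential yield, t/ha; asymptote of the yield response.
#' @return an object of class `soil_profile`.
#' @export
soil_profile <- function(name, clay_frac, silt_frac, sand_frac,
                         soc_init, ph, bulk_density, y_pot) {
  stopifnot(is.character(name), length(name) == 1L)
  fr <- c(clay_frac, silt_frac, sand_frac)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("texture fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("texture fractions must sum to 1 (got ", sum(fr), ")")
  if (!is.finite(soc_init) || soc_init <= 0) stop("soc_init must be > 0")
  if (!is.finite(y_pot) || y_pot <= 0) stop("y_pot must be > 0")
  structure(
    list(name = name, clay_frac = clay_frac, silt_frac = silt_frac,
         sand_frac = sand_frac, soc_init = soc_init, ph = ph,
         bulk_density = bulk_density, y_pot = y_pot),
    class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf(
    "<soil_profile> %s: clay %.0f%% / silt %.0f%% / sand %.0f%%, SOC %.2f%%, pH %.2f, BD %.2f, y_pot %.1f t/ha\n",
    x$name, 100 * x$clay_frac, 100 * x$silt_frac, 100 * x$sand_frac,
    x$soc_init, x$ph, x$bulk_density, x$y_pot))
  invisible(x)
}

#' Read a soil-parameter table
#'
#' Reads a tab-delimited soil table (columns: `name`, `clay_pct`, `silt_pct`,
#' `sand_pct`, `soc_pct`, `ph`, `bulk_density`, `y_pot`) into a named list of
#' [soil_profile()] objects. The default file ships the three contrasting
#' arable soils (clay, sandy clay, sandy loam) the package is calibrated to.
#'
#' @param file path to the table; defaults to the packaged fixture.
#' @return named list of `soil_profile`s.
#' @export
read_soils <- function(file = system.file("extdata", "soils.tsv",
                                          package = "agroptim")) {
  if (!length(file) || !nzchar(file) || !file.exists(file))
    stop("soil table not found: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("name", "clay_pct", "silt_pct", "sand_pct", "soc_pct",
            "ph", "bulk_density", "y_pot")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("soil table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    soil_profile(tab$name[i],
                 clay_frac = tab$clay_pct[i] / 100,
                 silt_frac = tab$silt_pct[i] / 100,
                 sand_frac = tab$sand_pct[i] / 100,
                 soc_init = tab$soc_pct[i], ph = tab$ph[i],
                 bulk_density = tab$bulk_density[i], y_pot = tab$y_pot[i])
  })
  names(out) <- tab$name
  out
}

#' Surrogate calibration constants
#'
#' Reads the plain-text (DCF, `key: value`) calibration file holding every
#' constant of the surrogate response functions. See the packaged
#' `extdata/calibration.dcf` and the methods vignette for the meaning,
#' units and rationale of each constant.
#'
#' @param file path to a DCF calibration file.
#' @return named list of numeric constants.
#' @export
read_calibration <- function(file = system.file("extdata", "calibration.dcf",
                                                package = "agroptim")) {
  m <- read.dcf(file)
  vals <- as.numeric(m[1L, ])
  if (anyNA(vals)) stop("non-numeric value in calibration file: ",
                        paste(colnames(m)[is.na(vals)], collapse = ", "))
  stats::setNames(as.list(vals), colnames(m))
}
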