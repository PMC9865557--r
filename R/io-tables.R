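# Plain-text table formats: work lists, XVG-style lambda series, paired
# CSV datasets, density-scan CSV and ESP grid/charge tables.

.headerMeta <- function(lines) {
  hdr <- grep("^[#@;]", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, gregexpr("([A-Za-z_]+)[[:space:]]*=[[:space:]]*([^[:space:]]+)", h))[[1]]
    for (kv in m) {
      p <- strsplit(kv, "[[:space:]]*=[[:space:]]*")[[1]]
      meta[[tolower(p[1])]] <- p[2]
    }
  }
  meta
}

#' Read a work-list file
#'
#' Two-column text `realization_id work` with comment headers (`#`) carrying
#' `units=` (`kT` or `kcal/mol`), and optionally `temperature=` and `stage=`.
#'
#' @param path file path.
#' @param temperature fallback temperature (K) when the header has none.
#' @return a [WorkSet-class].
#' @export
readWorkFile <- function(path, temperature = 298) {
  lines <- readLines(path, warn = FALSE)
  meta <- .headerMeta(lines)
  units <- tolower(meta[["units"]] %||% "kt")
  if (!units %in% c("kt", "kcal/mol"))
    stop(sprintf("unsupported work units '%s'", units), call. = FALSE)
  if (!is.null(meta[["temperature"]]))
    temperature <- as.numeric(meta[["temperature"]])
  dat <- utils::read.table(text = grep("^[#@;]", lines, invert = TRUE,
                                       value = TRUE),
                           col.names = c("id", "work"),
                           colClasses = c("character", "numeric"))
  w <- dat$work
  if (units == "kcal/mol") w <- w / kT_kcal(temperature)
  workSet(w, stage = meta[["stage"]] %||% "total",
          temperature = temperature, ids = dat$id)
}

#' Write a work-list file
#'
#' @param workset a [WorkSet-class].
#' @param path output path.
#' @export
writeWorkFile <- function(workset, path) {
  stopifnot(is(workset, "WorkSet"))
  writeLines(c(sprintf("# units=kT temperature=%g stage=%s",
                       workset@temperature, workset@stage),
               sprintf("%s %.10g", workset@ids, workset@works)), path)
}

#' Read an XVG-style lambda series
#'
#' Two-column (lambda, dH/dlambda) text with `@` and `#` comment lines
#' tolerated, as produced by MD engines' dhdl output after reduction to the
#' switching coordinate.
#'
#' @param path file path.
#' @return data.frame (`lambda`, `dhdl`).
#' @export
readLambdaSeries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dat <- utils::read.table(text = grep("^[@#;]", lines, invert = TRUE,
                                       value = TRUE),
                           col.names = c("lambda", "dhdl"))
  dat
}

#' Read a paired calculation/experiment CSV
#'
#' Columns `label,calc,expt`.
#'
#' @param path file path.
#' @return paired data.frame (see [pairedData()]).
#' @export
readPairedData <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pairedData(d$label, d$calc, d$expt)
}

#' Read a density-scan CSV
#'
#' Columns `s,density,sd` preceded by comment headers carrying
#' `rho_exp=`, `temperature=` and `kind=`.
#'
#' @param path file path.
#' @return a [DensityScan-class].
#' @export
readDensityScan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .headerMeta(lines)
  d <- utils::read.csv(text = grep("^[#;]", lines, invert = TRUE, value = TRUE),
                       stringsAsFactors = FALSE)
  densityScan(d$s, d$density,
              sd = if ("sd" %in% names(d)) d$sd else numeric(),
              kind = meta[["kind"]] %||% "sigma",
              rhoExp = as.numeric(meta[["rho_exp"]] %||% NA),
              temperature = as.numeric(meta[["temperature"]] %||% 298))
}

#' Write a density-scan CSV
#'
#' @param scan a [DensityScan-class].
#' @param path output path.
#' @export
writeDensityScan <- function(scan, path) {
  stopifnot(is(scan, "DensityScan"))
  hdr <- sprintf("# kind=%s temperature=%g%s", scan@kind, scan@temperature,
                 if (is.finite(scan@rhoExp))
                   sprintf(" rho_exp=%.6g", scan@rhoExp) else "")
  body <- c("s,density,sd",
            sprintf("%.6g,%.8g,%.3g", scan@s, scan@density,
                    if (length(scan@sd)) scan@sd else rep(NA, length(scan@s))))
  writeLines(c(hdr, body), path)
}

#' Read an ESP grid file
#'
#' Whitespace-separated `x y z V` with a one-line comment header giving the
#' coordinate units, e.g. `# units=bohr` (potential is always atomic units).
#'
#' @param path file path.
#' @return an [EspGrid-class].
#' @export
readEspGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .headerMeta(lines)
  units <- tolower(meta[["units"]] %||% "bohr")
  d <- utils::read.table(text = grep("^[#;]", lines, invert = TRUE,
                                     value = TRUE),
                         col.names = c("x", "y", "z", "V"))
  espGrid(as.matrix(d[, 1:3]), d$V, units = units)
}

#' Read a point-charge model file
#'
#' Whitespace-separated `x y z q` with a `# units=` header for the
#' coordinates (charges in e).
#'
#' @param path file path.
#' @return a [ChargeModel-class].
#' @export
readChargeModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .headerMeta(lines)
  units <- tolower(meta[["units"]] %||% "bohr")
  d <- utils::read.table(text = grep("^[#;]", lines, invert = TRUE,
                                     value = TRUE),
                         col.names = c("x", "y", "z", "q"))
  chargeModel(as.matrix(d[, 1:3]), d$q, units = units)
}
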