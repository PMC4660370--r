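# File formats: delimited kinetics/ITC tables with fixed column names
# (units in the name), 3-column ASCII '.dat' scattering curves with '#'
# comments, YAML protocol blocks, JSON reports.

#' Read a kinetics table
#'
#' Delimited text with header columns `substrate_conc_uM`,
#' `inhibitor_conc_uM`, `velocity` and optional `inhibitor_id`, `replicate`.
#'
#' @param path file path (comma- or tab-delimited; autodetected).
#' @return a [kinetic_dataset()].
#' @export
read_kinetics_table <- function(path) {
  d <- utils::read.delim(path, sep = .detect_sep(path), check.names = FALSE)
  need <- c("substrate_conc_uM", "inhibitor_conc_uM", "velocity")
  if (!all(need %in% names(d)))
    stop("kinetics table must have columns: ", paste(need, collapse = ", "))
  kinetic_dataset(d$substrate_conc_uM, d$inhibitor_conc_uM, d$velocity,
                  replicate = if ("replicate" %in% names(d)) d$replicate else 1L,
                  inhibitor_id = if ("inhibitor_id" %in% names(d))
                    as.character(d$inhibitor_id[1]) else "inhibitor")
}

#' Write a kinetics table
#' @param data a [kinetic_dataset()].
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_kinetics_table <- function(data, path) {
  d <- as.data.frame(data)
  out <- data.frame(substrate_conc_uM = d$substrate,
                    inhibitor_conc_uM = d$inhibitor,
                    inhibitor_id = attr(data, "inhibitor_id") %||% "inhibitor",
                    velocity = d$velocity,
                    replicate = d$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ITC heats table plus YAML protocol
#'
#' The table has columns `injection_index`, `volume_uL`, `heat_ucal`; the
#' protocol YAML has keys `cell_volume_uL`, `cell_conc_uM`,
#' `syringe_conc_uM`, `temperature_C`.
#'
#' @param path heats table path.
#' @param protocol_path YAML protocol path.
#' @return an [itc_titration()].
#' @export
read_itc_table <- function(path, protocol_path) {
  d <- utils::read.delim(path, sep = .detect_sep(path))
  need <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(need %in% names(d)))
    stop("ITC table must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$injection_index), ]
  p <- yaml::read_yaml(protocol_path)
  proto <- itc_protocol(cell_volume_uL = p$cell_volume_uL,
                        cell_conc_uM = p$cell_conc_uM,
                        syringe_conc_uM = p$syringe_conc_uM,
                        injection_volumes_uL = d$volume_uL,
                        temperature_C = p$temperature_C %||% 25)
  itc_titration(proto, d$heat_ucal)
}

#' Write an ITC heats table (and optionally its protocol YAML)
#' @param titration an [itc_titration()].
#' @param path output heats table path (CSV).
#' @param protocol_path optional YAML path for the protocol block.
#' @return `path`, invisibly.
#' @export
write_itc_table <- function(titration, path, protocol_path = NULL) {
  p <- titration$protocol
  out <- data.frame(injection_index = seq_along(titration$heats),
                    volume_uL = p$injection_volumes_uL,
                    heat_ucal = titration$heats)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(protocol_path))
    yaml::write_yaml(list(cell_volume_uL = p$cell_volume_uL,
                          cell_conc_uM = p$cell_conc_uM,
                          syringe_conc_uM = p$syringe_conc_uM,
                          temperature_C = p$temperature_C), protocol_path)
  invisible(path)
}

#' Read a 3-column ASCII scattering curve
#'
#' Standard `q I sigma` whitespace-separated format; lines starting with `#`
#' are comments. A header comment `# conc_mg_ml=<x>` sets the concentration
#' attribute.
#'
#' @param path file path.
#' @return a [scattering_curve()].
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(trimws(lines), "#")]
  conc <- NULL
  m <- regmatches(com, regexpr("conc_mg_ml=\\s*[0-9.eE+-]+", com))
  if (length(m)) conc <- as.numeric(sub("conc_mg_ml=\\s*", "", m[1]))
  d <- utils::read.table(text = lines[!startsWith(trimws(lines), "#") &
                                        nzchar(trimws(lines))])
  scattering_curve(d[[1]], d[[2]],
                   sigma = if (ncol(d) >= 3) d[[3]] else NULL,
                   concentration = conc)
}

#' Write a 3-column ASCII scattering curve
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cc <- attr(curve, "concentration")
  if (!is.null(cc)) writeLines(sprintf("# conc_mg_ml=%.6g", cc), con)
  writeLines("# q(1/A) I sigma", con)
  sig <- if (is.null(curve$sigma)) rep(0, nrow(curve)) else curve$sigma
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, sig), con)
  invisible(path)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
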