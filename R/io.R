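#' Read and write Z-spectrum tables
#'
#' Z-spectra are stored as two-column delimited text (`offset_ppm`, `z`)
#' with a header line; provenance metadata travels in a JSON sidecar
#' `<path>.json` when present.
#'
#' @param zspec A Z-spectrum tibble.
#' @param path Output table path.
#' @param sep Field separator.
#' @return `write_zspec()` the path, invisibly; `read_zspec()` the spectrum.
#' @export
write_zspec <- function(zspec, path, sep = "\t") {
  stopifnot(is_zspec(zspec))
  utils::write.table(zspec[, c("offset_ppm", "z")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  meta <- zspec_meta(zspec)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_zspec
#' @export
read_zspec <- function(path, sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("offset_ppm", "z") %in% names(tab)))
    abort("Z-spectrum table needs a header with columns `offset_ppm`, `z`.")
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  zspectrum(tab$offset_ppm, tab$z, meta = as.list(meta))
}

#' Read and write pool-system configurations
#'
#' Pool systems (and optionally a saturation scheme) are stored as YAML:
#' one block per pool with the fields `delta_ppm`, `kex_hz`, `f_h`, `t1_s`,
#' `t2_s`, `lineshape`, plus an optional `scheme` block mirroring
#' [sat_scheme()] fields.
#'
#' @param system A pool-system tibble.
#' @param path File path.
#' @param scheme Optional [sat_scheme()] stored alongside.
#' @return `write_pool_config()` the path invisibly; `read_pool_config()` a
#'   list with `system` and (possibly NULL) `scheme`.
#' @export
write_pool_config <- function(system, path, scheme = NULL) {
  validate_pool_system(system)
  cfg <- list(
    region = attr(system, "region"),
    pools = purrr::transpose(as.list(system[, c(
      "pool", "delta_ppm", "kex_hz", "f_h", "t1_s", "t2_s", "lineshape"
    )]))
  )
  if (!is.null(scheme)) cfg$scheme <- unclass(scheme)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_pool_config
#' @export
read_pool_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pools)) abort("config has no `pools` block.")
  pools <- dplyr::bind_rows(lapply(cfg$pools, as_tibble))
  system <- pool_system(pools, region = cfg$region)
  scheme <- if (!is.null(cfg$scheme)) do.call(sat_scheme, cfg$scheme) else NULL
  list(system = system, scheme = scheme)
}
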