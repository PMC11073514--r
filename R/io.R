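# Output writers: tidy CSV traces, JSON biomarker reports, run manifests.

#' Write simulation outputs to disk
#'
#' Writes the tidy trace (`trace.csv`: time + states + currents + tension +
#' OCR), the biomarker report (`biomarkers.json`) and a reproducibility
#' manifest (`manifest.json`: configuration hash, package version, solver
#' settings).  Identical runs produce identical biomarker and trace files;
#' the manifest hash changes iff the configuration changes.
#'
#' @param sim a `cardiox_sim` object.
#' @param dir output directory (created if missing).
#' @param report optional precomputed biomarker report; computed from `sim`
#'   if `NULL`.
#' @param trace_downsample keep every n-th trace row in the CSV (1 = all).
#' @return Invisibly, the named vector of written paths.
#' @export
cdx_write_outputs <- function(sim, dir, report = NULL,
                              trace_downsample = 1L) {
  stopifnot(inherits(sim, "cardiox_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) rlang::abort(paste0("cannot create output directory: ", dir))
  paths <- c(trace = file.path(dir, "trace.csv"),
             report = file.path(dir, "biomarkers.json"),
             manifest = file.path(dir, "manifest.json"))
  tr <- sim$trace
  if (trace_downsample > 1L)
    tr <- tr[seq(1, nrow(tr), by = trace_downsample), ]
  tryCatch(
    utils::write.csv(tr, paths[["trace"]], row.names = FALSE),
    error = function(e) rlang::abort(
      paste0("failed writing ", paths[["trace"]], ": ", conditionMessage(e))))
  if (is.null(report)) report <- cdx_biomarkers(sim)
  jsonlite::write_json(as.list(report), paths[["report"]],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cdx_run_manifest(sim), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run manifest
#'
#' @param sim a `cardiox_sim` object.
#' @return List with the protocol name, drug dose, solver settings, package
#'   version and a hash of the full configuration (protocol environment,
#'   breaks, parameters, solver settings, initial state).
#' @export
cdx_run_manifest <- function(sim) {
  cfg <- list(protocol = sim$protocol$name,
              env = unname(sim$protocol$env),
              breaks = sim$protocol$breaks,
              params = as.list(sim$params),
              solver = sim$solver,
              y0 = unname(sim$y0))
  hash <- digest_config(cfg)
  list(protocol = sim$protocol$name,
       drug_dose = if (is.null(sim$protocol$drug)) 0 else
         sim$protocol$drug$dose,
       solver = sim$solver,
       package_version = as.character(utils::packageVersion("cardiox")),
       config_hash = hash)
}

# dependency-free configuration hash: serialize deterministically and crc
digest_config <- function(cfg) {
  raw <- serialize(cfg, connection = NULL, version = 2)
  # drop the serialization header (R version stamps) for stability
  raw <- raw[-seq_len(14)]
  fmt <- sprintf("%02x", as.integer(raw))
  # fold into a short digest
  idx <- seq_along(fmt)
  acc <- 0
  for (i in idx) acc <- (acc * 31 + as.integer(raw[i])) %% 2147483647
  sprintf("%08x-%d", acc, length(raw))
}
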