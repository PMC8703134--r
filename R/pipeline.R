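#' Run the aberration-correction pipeline
#'
#' Wires the package's modules into the canonical order
#' `simulate -> detect -> measure -> fit -> power -> correct`, exchanging
#' plain files (TIFF / CSV / JSON / YAML) between steps so every
#' intermediate stays inspectable. Only the requested steps run; each step
#' reads the artifacts of earlier steps (from this run or from disk) and
#' writes its own next to the configured output prefix, together with a
#' `*.provenance.json` sidecar recording the tool version and MD5 hashes of
#' the inputs it consumed.
#'
#' The configuration is a named list (or a YAML file path) with blocks:
#' \describe{
#'   \item{acquisition}{sidecar fields of [read_acquisition_config()].}
#'   \item{paths}{`input` (TIFF), `rois`, `samples`, `model`, `output`,
#'     `out_prefix` (directory/prefix for generated artifacts).}
#'   \item{phantom}{arguments of [phantom_spec()] plus `guide_star = TRUE`
#'     and `neurite_length` for tube phantoms (`simulate` step).}
#'   \item{detection}{arguments of [detection_params()].}
#'   \item{measurement}{`source`, `k_sigma`.}
#'   \item{fit}{`alpha`, `power_threshold`.}
#'   \item{power}{`r2` (or `f2`), `n`, `alpha`, `target_power`.}
#'   \item{correct}{`force`, `first_order`.}
#' }
#'
#' @param config named list or YAML path.
#' @param steps character subset of
#'   `c("simulate", "detect", "measure", "fit", "power", "correct")`.
#' @return invisibly, a named list of artifact paths (and, for `power`, the
#'   computed table).
#' @export
run_pipeline <- function(config,
                         steps = c("detect", "measure", "fit", "correct")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  canonical <- c("simulate", "detect", "measure", "fit", "power", "correct")
  steps <- match.arg(steps, canonical, several.ok = TRUE)
  steps <- canonical[canonical %in% steps]
  prefix <- cfg$paths$out_prefix %||% "chromaxial_run"
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  art <- list()
  p <- function(name, default) cfg$paths[[name]] %||% default

  if ("simulate" %in% steps) {
    ph <- cfg$phantom
    if (is.null(ph)) stop("simulate step requires a 'phantom' config block")
    guide <- isTRUE(ph$guide_star)
    nl <- ph$neurite_length %||% 10
    ph$guide_star <- NULL; ph$neurite_length <- NULL
    spec <- do.call(phantom_spec, ph)
    sim <- if (guide) generate_guide_star_phantom(spec, nl)
           else generate_phantom(spec)
    art$input <- paste0(prefix, "_phantom.tif")
    art$acquisition_config <- paste0(prefix, "_config.yaml")
    write_stack(sim$stack, art$input, config_path = art$acquisition_config)
    art$truth <- paste0(prefix, "_truth.csv")
    utils::write.csv(sim$truth, art$truth, row.names = FALSE)
    art$rois <- paste0(prefix, "_rois.csv")
    write_rois(sim$rois, art$rois)
    write_provenance(art$input, character(), cfg)
  }

  input <- art$input %||% cfg$paths$input
  acq <- art$acquisition_config %||% cfg$acquisition

  if ("detect" %in% steps) {
    stack <- read_stack(input, acq)
    params <- do.call(detection_params, as.list(cfg$detection %||% list()))
    rois <- detect_beads(stack$channels[[stack$reference_channel]], params)
    art$rois <- p("rois", paste0(prefix, "_rois.csv"))
    write_rois(rois, art$rois)
    write_provenance(art$rois, input, cfg)
  }

  if ("measure" %in% steps) {
    stack <- read_stack(input, acq)
    rois_path <- art$rois %||% cfg$paths$rois
    if (is.null(rois_path)) stop("measure step needs ROIs (run detect ",
                                 "first or set paths$rois)")
    mcfg <- cfg$measurement %||% list()
    samples <- measure_batch(stack, read_rois(rois_path),
                             source = mcfg$source %||% "bead",
                             k_sigma = mcfg$k_sigma %||% 10)
    art$samples <- p("samples", paste0(prefix, "_samples.csv"))
    utils::write.csv(samples, art$samples, row.names = FALSE)
    fails <- attr(samples, "failures")
    if (nrow(fails)) message("measure: ", nrow(fails), " ROI(s) rejected")
    write_provenance(art$samples, c(input, rois_path), cfg)
  }

  if ("fit" %in% steps) {
    samples_path <- art$samples %||% cfg$paths$samples
    if (is.null(samples_path)) stop("fit step needs a samples table")
    samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE,
                               colClasses = c(channel = "character"))
    fcfg <- cfg$fit %||% list()
    acq_cfg <- read_acquisition_config(acq)
    model <- build_model(samples, ref = acq_cfg$reference_channel,
                         alpha = fcfg$alpha %||% 0.05,
                         power_threshold = fcfg$power_threshold %||% 0.7,
                         lateral_warn_pitch = max(acq_cfg$dx, acq_cfg$dy))
    art$model <- p("model", paste0(prefix, "_model.json"))
    write_model(model, art$model)
    write_provenance(art$model, samples_path, cfg)
    low <- names(Filter(function(r) "insufficient_power" %in% r$flags,
                        model$regressions))
    if (length(low))
      warning("power gate failed for channel(s): ",
              paste(low, collapse = ", "), call. = FALSE)
  }

  if ("power" %in% steps) {
    pc <- cfg$power
    if (is.null(pc) || (is.null(pc$r2) && is.null(pc$f2)))
      stop("power step needs power$r2 or power$f2")
    f2 <- pc$f2 %||% cohens_f2(pc$r2)
    alpha <- pc$alpha %||% 0.05
    tab <- list(f2 = f2)
    if (!is.null(pc$n)) tab$power <- regression_power(f2, pc$n, alpha)
    if (!is.null(pc$target_power))
      tab$required_n <- required_n(f2, pc$target_power, alpha)
    art$power <- tab
    message(paste(sprintf("%s = %.6g", names(tab), unlist(tab)),
                  collapse = ", "))
  }

  if ("correct" %in% steps) {
    model_path <- art$model %||% cfg$paths$model
    if (is.null(model_path)) stop("correct step needs a model")
    stack <- read_stack(input, acq)
    ccfg <- cfg$correct %||% list()
    res <- apply_correction(stack, read_model(model_path),
                            force = isTRUE(ccfg$force),
                            first_order = isTRUE(ccfg$first_order))
    art$output <- p("output", paste0(prefix, "_corrected.tif"))
    write_stack(res$stack, art$output)
    art$report <- paste0(tools::file_path_sans_ext(art$output),
                         "_report.json")
    jsonlite::write_json(res$report, art$report, auto_unbox = TRUE,
                         digits = NA)
    write_provenance(art$output, c(input, model_path), cfg)
  }

  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# provenance sidecar: tool version, input hashes, effective config echo
write_provenance <- function(artifact, inputs, cfg) {
  inputs <- inputs[file.exists(inputs)]
  jsonlite::write_json(list(
    tool = paste0("chromaxial ",
                  as.character(utils::packageVersion("chromaxial"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(stats::setNames(
      as.character(tools::md5sum(inputs)), basename(inputs))),
    config = cfg),
    paste0(artifact, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
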