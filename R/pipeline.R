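# Configuration, volume I/O and the end-to-end pipeline.
#
# NIfTI is the sole volumetric format (slice axis = third array axis); all
# times are seconds in configs, with *_ms keys accepted as explicit
# millisecond variants. Configs are validated against a declared schema
# before any compute; unknown keys are rejected by name.

config_schema <- list(
  seed = NULL, stages = NULL, output_dir = NULL, model = NULL,
  phantom = list(nx = NULL, ny = NULL, nslices = NULL, slice_spacing = NULL,
                 snr = NULL),
  protocol = list(pulse = list(shape = NULL, t_pulse = NULL, bwt = NULL,
                               sigma = NULL, dt = NULL),
                  alpha_deg = NULL, g_slice = NULL, te = NULL, te_ms = NULL,
                  tr = NULL, t1 = NULL),
  inputs = list(volume = NULL, gz_map = NULL, xi_map = NULL, b1_map = NULL,
                b1_nominal = NULL, phase = NULL, slice_spacing = NULL),
  options = list(xi_range = NULL, gz_step = NULL, mwf_floor = NULL,
                 mwf_cutoff = NULL, n_echoes_fieldmap = NULL)
)

check_keys <- function(cfg, schema, path = "") {
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad) > 0) {
    abort(sprintf("unknown config key%s: %s", if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")),
          class = "dephasr_config_error")
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && is.list(cfg[[k]])) {
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML run configuration and validates it against the package
#' schema; unknown keys are rejected with their names before any compute.
#'
#' @param path YAML file path, or a named list (validated in place).
#' @return The validated config list, with `te_ms` converted to `te`
#'   seconds and `alpha_deg` to `alpha` radians inside `protocol`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  check_keys(cfg, config_schema)
  if (!is.null(cfg$protocol)) {
    p <- cfg$protocol
    if (!is.null(p$te_ms)) {
      p$te <- unlist(p$te_ms) / 1e3
      p$te_ms <- NULL
    }
    if (!is.null(p$te)) p$te <- unlist(p$te)
    if (!is.null(p$alpha_deg)) p$alpha <- p$alpha_deg * pi / 180
    cfg$protocol <- p
  }
  cfg
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti; arrays come back stripped to plain R arrays.
#'
#' @param x Numeric array.
#' @param path File path (`.nii`; uncompressed so reruns are byte-identical).
#' @param pixdim Optional voxel dimensions.
#' @return `write_volume_nifti()` the path invisibly; `read_volume_nifti()`
#'   an array.
#' @export
write_volume_nifti <- function(x, path, pixdim = NULL) {
  img <- RNifti::asNifti(x)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

write_provenance <- function(path, cfg, extra = list()) {
  meta <- c(list(config_hash = rlang::hash(cfg),
                 seed = cfg$seed %||% NA,
                 package = "dephasr",
                 version = as.character(utils::packageVersion("dephasr"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the processing pipeline described by a configuration
#'
#' Executes the requested stages over the configured inputs and writes all
#' artifacts (NIfTI volumes, provenance JSON) into `output_dir`. Supported
#' stages:
#'
#' * `"phantom"`: generate the synthetic phantom (echo stack + truth maps +
#'   manifest);
#' * `"fieldmaps"`: field-offset fit from a 4D phase stack and the derived
#'   through-slice gradient map, plus B1 normalization;
#' * `"r2star"`: voxel-wise R2* fit under the configured model;
#' * `"mwf"`: voxel-wise myelin-water-fraction fit with F-correction.
#'
#' Outputs are deterministic given the config (the phantom stage draws its
#' noise under the configured seed), and each artifact is accompanied by a
#' provenance JSON with the config hash.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_run_config()]).
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% "r2star"
  written <- list()
  pth <- function(...) file.path(out_dir, paste0(...))
  proto <- cfg$protocol %||% list()

  vols <- list()
  if ("phantom" %in% stages) {
    ph_args <- cfg$phantom %||% list()
    spec <- do.call(phantom_spec, c(ph_args, list(
      protocol = proto[intersect(names(proto),
                                 c("pulse", "alpha", "g_slice", "te"))],
      seed = cfg$seed %||% 1L)))
    ph <- forward_signal(spec)
    write_volume_nifti(ph$signal, pth("phantom_echoes.nii"))
    write_volume_nifti(ph$truth$r2star, pth("truth_r2star.nii"))
    write_volume_nifti(ph$truth$gz, pth("truth_gz.nii"))
    write_volume_nifti(ph$truth$xi, pth("truth_xi.nii"))
    write_volume_nifti(ph$truth$mask * 1, pth("truth_mask.nii"))
    yaml::write_yaml(list(seed = spec$seed, snr = spec$snr,
                          dims = spec$dims, te = spec$protocol$te,
                          alpha = spec$protocol$alpha,
                          g_slice = spec$protocol$g_slice),
                     pth("phantom_manifest.yaml"))
    write_provenance(pth("phantom_provenance.json"), cfg,
                     list(sigma = ph$sigma))
    written$phantom <- pth("phantom_echoes.nii")
    vols <- list(volume = ph$signal,
                 gz = ph$truth$gz, xi = ph$truth$xi,
                 mask = ph$truth$mask, te = spec$protocol$te)
  }

  need_inputs <- function(key) {
    if (!is.null(vols[[key]])) return(vols[[key]])
    p <- cfg$inputs[[if (key == "volume") "volume" else paste0(key, "_map")]]
    if (is.null(p)) {
      abort(sprintf("no input available for '%s'.", key),
            class = "dephasr_path_error")
    }
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p),
            class = "dephasr_path_error")
    }
    read_volume_nifti(p)
  }

  if ("fieldmaps" %in% stages) {
    phase <- read_volume_nifti(cfg$inputs$phase)
    te <- proto$te
    n_fm <- cfg$options$n_echoes_fieldmap %||% 6
    dw0 <- fit_delta_omega0(unwrap_echo_phase(phase), te, n_echoes = n_fm)
    gz <- gz_map_from_fieldmap(dw0, cfg$inputs$slice_spacing)
    write_volume_nifti(dw0, pth("delta_omega0.nii"))
    write_volume_nifti(gz, pth("gz_map.nii"))
    written$gz_map <- pth("gz_map.nii")
    vols$gz <- gz
    if (!is.null(cfg$inputs$b1_map)) {
      xi <- normalize_b1(read_volume_nifti(cfg$inputs$b1_map),
                         cfg$inputs$b1_nominal)
      write_volume_nifti(xi, pth("xi_map.nii"))
      vols$xi <- xi
    }
    write_provenance(pth("fieldmaps_provenance.json"), cfg)
  }

  if ("r2star" %in% stages) {
    vol <- need_inputs("volume")
    model <- cfg$model %||% "S4"
    maps <- field_maps(gz = if (model != "S1") need_inputs("gz") else NULL,
                       xi = if (model == "S4") need_inputs("xi") else NULL,
                       slice_spacing = cfg$inputs$slice_spacing %||% NA)
    fit <- fit_r2star_map(
      vol, maps, model = model,
      protocol = list(pulse = proto$pulse, alpha = proto$alpha,
                      g_slice = proto$g_slice, te = vols$te %||% proto$te),
      mask = vols$mask,
      xi_range = unlist(cfg$options$xi_range) %||% c(0.5, 1.5),
      gz_step = cfg$options$gz_step %||% 5)
    write_volume_nifti(fit$r2star, pth("r2star_", model, ".nii"))
    write_volume_nifti(fit$s0, pth("s0_", model, ".nii"))
    write_provenance(pth("r2star_", model, "_provenance.json"), cfg,
                     list(model = model, n_masked = fit$n_masked,
                          n_singular = fit$n_singular))
    written$r2star <- pth("r2star_", model, ".nii")
  }

  if ("mwf" %in% stages) {
    vol <- need_inputs("volume")
    te <- vols$te %||% proto$te
    model <- cfg$model %||% "S4"
    lk <- NULL
    maps <- NULL
    if (model != "S1") {
      gz <- need_inputs("gz"); xi <- need_inputs("xi")
      maps <- field_maps(gz = gz, xi = xi,
                         slice_spacing = cfg$inputs$slice_spacing %||% NA)
      pulse <- rf_pulse_from_config(proto$pulse)
      src <- if (model == "S4") {
        xi_profile_grid(pulse, proto$g_slice, proto$alpha,
                        xi_range = unlist(cfg$options$xi_range) %||% c(0.5, 1.5))
      } else {
        simulate_profile(rf_scale_to_flip(pulse, proto$alpha), proto$g_slice)
      }
      lk <- dephasing_lookup(src, range(gz, na.rm = TRUE), te, model = model,
                             gz_step = cfg$options$gz_step %||% 5)
    }
    mw <- fit_mwf_map(vol, maps, lk, te, mask = vols$mask,
                      cutoff = (cfg$options$mwf_cutoff %||% 0.025),
                      floor = cfg$options$mwf_floor %||% 0.05)
    write_volume_nifti(mw$mwf, pth("mwf_", model, ".nii"))
    write_provenance(pth("mwf_", model, "_provenance.json"), cfg,
                     list(model = model, n_flagged = mw$n_flagged))
    written$mwf <- pth("mwf_", model, ".nii")
  }

  invisible(written)
}
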