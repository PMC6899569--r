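#' Bundled phantom fixture specifications
#'
#' The package ships YAML fixture configs describing synthetic study
#' conditions: three cortical CT phantoms whose ground-truth lacuna/canal
#' volume partitions encode the wild-type female, wild-type male and
#' knockout male compositions, and two Raman fixtures (one per sex) whose
#' band areas encode the corresponding fold changes between wild-type-like
#' and knockout-like groups.
#'
#' @return `list_fixtures()` returns the available fixture names.
#' @export
list_fixtures <- function() {
  files <- list.files(system.file("extdata", "fixtures",
                                  package = "dimorphbone"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

fixture_path <- function(name) {
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "dimorphbone")
  if (path == "") stop(sprintf("no fixture named '%s'", name))
  path
}

#' @rdname list_fixtures
#' @param name Fixture name (see [list_fixtures()]) or a path to a YAML
#'   file of the same layout.
#' @param seed Optional seed overriding the fixture's default (e.g. for
#'   replicate phantoms).
#' @export
load_ct_fixture <- function(name, seed = NULL) {
  path <- if (file.exists(name)) name else fixture_path(name)
  y <- yaml::read_yaml(path)
  cortex_phantom_spec(
    outer_radius_um = y$outer_radius_um,
    inner_radius_um = y$inner_radius_um,
    length_slices = y$length_slices,
    voxel_size_um = y$voxel_size_um,
    lacunae = y$lacunae, canals = y$canals,
    osteoid = if (is.null(y$osteoid)) list() else y$osteoid,
    intensity = if (is.null(y$intensity)) list() else y$intensity,
    seed = if (is.null(seed)) y$seed else seed)
}

#' @rdname list_fixtures
#' @export
load_raman_fixture <- function(name, seed = NULL) {
  path <- if (file.exists(name)) name else fixture_path(name)
  y <- yaml::read_yaml(path)
  base_seed <- if (is.null(seed)) y$seed else seed
  wn <- seq(y$wavenumber$from, y$wavenumber$to, by = y$wavenumber$step)
  groups <- lapply(seq_along(y$groups), function(i) {
    g <- y$groups[[i]]
    bands <- do.call(rbind, lapply(g$bands, as.data.frame))
    raman_phantom_spec(
      bands = bands, baseline_coef = unlist(y$baseline),
      noise_sd = y$noise_sd, spike_count = y$spike_count,
      spike_amplitude = y$spike_amplitude, n_spectra = y$n_spectra,
      area_cv = y$area_cv, wavenumber = wn,
      seed = base_seed + i)
  })
  names(groups) <- names(y$groups)
  groups
}
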