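# Shared, lazily computed fixtures. The small run uses 3 species specs and
# reduced curve sampling to keep unit tests fast; the default run uses the
# full 9-spec x 2-specimen study design and is shared by the acceptance
# checks.

.run_cache <- new.env(parent = emptyenv())

small_config <- function(outdir = file.path(tempdir(), "cm_small")) {
  pipeline_config(
    generator = list(species = NULL, n_per_species = 2L, seed = 11L,
                     n_points = 192L),
    output = list(dir = outdir))
}

small_specs <- function() default_species_specs()[c(1L, 5L, 8L)]

get_small_run <- function() {
  if (is.null(.run_cache$small)) {
    cfg <- small_config()
    cfg$generator$species <- lapply(small_specs(), function(s) {
      list(name = s$name, region = s$region,
           intraspecific_cv = s$intraspecific_cv,
           landmark_noise_sd = s$landmark_noise_sd,
           params = unclass(s$mean_params))
    })
    manifest <- suppressMessages(run_pipeline(cfg, verbose = FALSE))
    .run_cache$small <- list(config = cfg, manifest = manifest,
                             outdir = cfg$output$dir)
  }
  .run_cache$small
}

get_default_run <- function() {
  if (is.null(.run_cache$default)) {
    outdir <- file.path(tempdir(), "cm_default")
    cfg <- pipeline_config(output = list(dir = outdir))
    manifest <- suppressMessages(run_pipeline(cfg, verbose = FALSE))
    .run_cache$default <- list(config = cfg, manifest = manifest,
                               outdir = outdir)
  }
  .run_cache$default
}

zero_noise_spec <- function(...) {
  species_spec("Z_test", "nowhere",
               shell_params(angle_noise_sd = 0, ...),
               intraspecific_cv = 0, landmark_noise_sd = 0)
}
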