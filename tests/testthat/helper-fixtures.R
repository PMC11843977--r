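# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

mouse_physiology <- function() {
  if (is.null(.fixtures$sp)) .fixtures$sp <- load_species_physiology("mouse")
  .fixtures$sp
}

mouse_system <- function() {
  if (is.null(.fixtures$sys)) .fixtures$sys <- build_pbpk_system(mouse_physiology())
  .fixtures$sys
}

mouse_context <- function() {
  if (is.null(.fixtures$ctx)) .fixtures$ctx <- model_context(mouse_physiology())
  .fixtures$ctx
}

# default mouse simulation on the study schedule (exact linear propagation)
mouse_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_pbpk(system = mouse_system(), method = "expm")
  }
  .fixtures$sim
}

# write a temporary MRT physiology CSV, optionally dropping organs
write_mrt_subset <- function(drop = character()) {
  src <- read.csv(system.file("extdata", "mrt_physiology.csv", package = "mrtpbpk"),
                  stringsAsFactors = FALSE)
  src <- src[!(src$species == "mouse" & src$organ %in% drop), ]
  path <- tempfile(fileext = ".csv")
  write.csv(src, path, row.names = FALSE, quote = FALSE)
  path
}
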