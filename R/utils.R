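#' @keywords internal
"_PACKAGE"

#' Trait and biome vocabularies
#'
#' `trait_names()` returns the ten functional traits carried through the
#' analysis; `biome_levels()` the six forest biome labels; `main_biomes()`
#' the five biomes retained for inference (tropical conifer forest is set
#' aside because of its small plot count).
#'
#' @return Character vectors.
#' @export
trait_names <- function() {
  c("height", "rooting_depth", "sla", "conduit_diameter", "crown_diameter",
    "wood_density", "bark_thickness", "leaf_n", "leaf_np", "seed_mass")
}

#' @rdname trait_names
#' @export
biome_levels <- function() {
  c("tropical_moist", "tropical_dry", "tropical_conifer",
    "temperate", "temperate_conifer", "boreal")
}

#' @rdname trait_names
#' @export
main_biomes <- function() {
  setdiff(biome_levels(), "tropical_conifer")
}

# Deterministic 32-bit sub-seed derived from a master seed and an index.
# Keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  x <- (s * 48271) %% m
  x <- (x + (as.double(index) * 69621)) %% m
  as.integer(x %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domrare <- function(msg, class) {
  stop(structure(class = c(class, "domrare_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
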