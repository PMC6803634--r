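# Seed handling: functions taking a seed use it locally and restore the
# caller's RNG state afterwards.
.localSeed <- function(seed) {
  if (is.null(seed)) return(NULL) # no seeding, no restore
  saved <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (is.null(saved)) list(remove = TRUE) else saved
}

.restoreSeed <- function(saved) {
  if (is.null(saved)) return(invisible())
  if (is.list(saved) && isTRUE(saved$remove)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
  invisible()
}

# derive a bounded child seed from a base seed (keeps within 32-bit range)
.childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1000003 * k) %% 2147483647)
}
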