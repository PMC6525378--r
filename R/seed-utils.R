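# Local seeding for permutation tests and simulators: setting a seed
# inside a function must not clobber the caller's random stream (or
# replicate() loops around these functions would silently reuse data).
# Returns a restore function to be registered with on.exit(); a NULL seed
# leaves the ambient stream untouched.
local_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
    invisible()
  }
}
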