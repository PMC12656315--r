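# seed the RNG for the rest of the calling function, restoring the
# caller's stream on exit so seeded operations do not disturb user code
local_seed <- function(seed, env = parent.frame()) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  restore <- if (had) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
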